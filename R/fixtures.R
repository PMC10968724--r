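# Deterministic synthetic-data generators: toy quadripartite plastomes,
# allele locus pairs, planted variants, and the bundled trnL-UAA InDel assay
# reconstructed on a synthetic locus. All generators are pure functions of
# their parameters + seed.

#' Random DNA under a GC model
#'
#' Draws bases independently with the given GC fraction (default 0.37, the
#' typical plastome composition). Uses the current RNG stream; wrap in a
#' seeded generator for reproducibility.
#'
#' @param n length (bp).
#' @param gc GC fraction.
#' @return character scalar.
#' @export
randomDna <- function(n, gc = 0.37) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Specification for a synthetic quadripartite plastome
#'
#' @param lscLen,irLen,sscLen region lengths (bp); defaults give a small
#'   820-bp toy with the canonical LSC > SSC ordering.
#' @param gc background GC fraction.
#' @param seed RNG seed; fully determines the output.
#' @param genes optional data.frame of planted genes with columns
#'   \code{name}, \code{region} (LSC/IRb/SSC/IRa), \code{offset} (0-based
#'   from region start), \code{length}, \code{strand}; a gene whose length
#'   runs past its region end deliberately straddles the junction.
#' @return a list spec for \code{\link{makeToyPlastome}}.
#' @export
plastomeSpec <- function(lscLen = 500L, irLen = 120L, sscLen = 80L, gc = 0.37,
                         seed = 1L, genes = NULL) {
  stopifnot(lscLen >= 1L, irLen >= 1L, sscLen >= 1L, sscLen <= lscLen)
  list(lscLen = as.integer(lscLen), irLen = as.integer(irLen),
       sscLen = as.integer(sscLen), gc = gc, seed = as.integer(seed),
       genes = genes)
}

#' Generate a synthetic circular quadripartite plastome
#'
#' Builds LSC + IRb + SSC + revcomp(IRb) from random sequence and plants the
#' requested gene features. The output always satisfies the quadripartite
#' partition invariants (identical IR copies, SSC <= LSC) and is bit-identical
#' across calls with the same spec.
#'
#' @param spec from \code{\link{plastomeSpec}}.
#' @param id record identifier.
#' @return a circular \linkS4class{GenomeRecord}.
#' @export
makeToyPlastome <- function(spec, id = "toy_plastome") {
  withSeed(spec$seed, {
    lsc <- randomDna(spec$lscLen, spec$gc)
    ir <- randomDna(spec$irLen, spec$gc)
    ssc <- randomDna(spec$sscLen, spec$gc)
  })
  # pin the four bases flanking the repeat copies to A so the planted IR can
  # never extend into the single-copy regions by coincidence (A pairs with T)
  if (spec$lscLen >= 2L) {
    substr(lsc, 1L, 1L) <- "A"
    substr(lsc, spec$lscLen, spec$lscLen) <- "A"
  }
  if (spec$sscLen >= 2L) {
    substr(ssc, 1L, 1L) <- "A"
    substr(ssc, spec$sscLen, spec$sscLen) <- "A"
  }
  s <- paste0(lsc, ir, ssc, as.character(revComp(ir)))
  n <- nchar(s)
  starts <- c(LSC = 1L, IRb = spec$lscLen + 1L,
              SSC = spec$lscLen + spec$irLen + 1L,
              IRa = spec$lscLen + spec$irLen + spec$sscLen + 1L)
  ft <- emptyFeatures()
  if (!is.null(spec$genes) && nrow(spec$genes)) {
    rows <- list()
    for (i in seq_len(nrow(spec$genes))) {
      g <- spec$genes[i, ]
      if (!g$region %in% names(starts))
        toolError("E_INPUT", paste("unknown region", g$region))
      gs <- starts[[g$region]] + g$offset
      ge <- gs + g$length - 1L
      if (gs < 1L || ge > n)
        toolError("E_INPUT", sprintf("gene %s does not fit in the genome", g$name))
      rows[[i]] <- data.frame(name = g$name, kind = "gene",
                              strand = if (is.null(g$strand)) "+" else g$strand,
                              start = as.integer(gs), end = as.integer(ge),
                              part = 1L, stringsAsFactors = FALSE)
    }
    ft <- do.call(rbind, rows)
  }
  GenomeRecord(id, s, circular = TRUE, features = ft)
}

#' Embed two allele windows in a shared random locus
#'
#' Produces two sequences identical except at the embedded windows (the
#' gap-stripped allele strings), with random flanks drawn from the seed.
#'
#' @param flank5,flank3 flank lengths (bp).
#' @param refWindow,altWindow the two allele strings (gaps stripped).
#' @param seed RNG seed.
#' @param gc flank GC fraction.
#' @return named character vector c(ref=, alt=).
#' @export
makeAlleleLocus <- function(flank5 = 100L, flank3 = 100L, refWindow, altWindow,
                            seed = 1L, gc = 0.37) {
  refWindow <- gsub("-", "", toupper(refWindow))
  altWindow <- gsub("-", "", toupper(altWindow))
  withSeed(seed, {
    f5 <- randomDna(flank5, gc)
    f3 <- randomDna(flank3, gc)
  })
  c(ref = paste0(f5, refWindow, f3), alt = paste0(f5, altWindow, f3))
}

#' Apply variant events to a genome
#'
#' Events are applied right-to-left so that earlier coordinates stay valid.
#' An insertion of allele \code{x} at \code{start} places \code{x} so that
#' it begins at position \code{start} of the mutated sequence; a deletion
#' removes \code{[start, start+length-1]}; a substitution replaces that
#' interval with \code{allele} (same length).
#'
#' @param record a \linkS4class{GenomeRecord} (features are dropped).
#' @param events data.frame with columns \code{kind}, \code{start},
#'   \code{length}, \code{allele}.
#' @return the edited \linkS4class{GenomeRecord}.
#' @export
mutateGenome <- function(record, events) {
  s <- asDnaChar(record)
  if (!nrow(events)) return(GenomeRecord(genomeId(record), s,
                                         circular = isCircular(record)))
  events <- events[order(events$start), , drop = FALSE]
  ends <- ifelse(events$kind == "insertion", events$start - 1L,
                 events$start + events$length - 1L)
  if (any(events$start[-1] <= ends[-nrow(events)]))
    toolError("E_INPUT", "overlapping variant events")
  if (max(ends) > nchar(s)) toolError("E_INPUT", "event outside the sequence")
  for (i in rev(seq_len(nrow(events)))) {
    ev <- events[i, ]
    pre <- substr(s, 1L, ev$start - 1L)
    if (ev$kind == "insertion") {
      s <- paste0(pre, ev$allele, substr(s, ev$start, nchar(s)))
    } else if (ev$kind == "deletion") {
      s <- paste0(pre, substr(s, ev$start + ev$length, nchar(s)))
    } else if (ev$kind == "substitution") {
      stopifnot(nchar(ev$allele) == ev$length)
      s <- paste0(pre, ev$allele, substr(s, ev$start + ev$length, nchar(s)))
    } else toolError("E_INPUT", paste("unknown event kind", ev$kind))
  }
  GenomeRecord(paste0(genomeId(record), "_mut"), s,
               circular = isCircular(record))
}

#' Draw random, well-separated variant events
#'
#' Generates \code{n} non-overlapping events (substitution / 1-5 bp
#' insertion / 1-5 bp deletion) spaced at least \code{minGap} bp apart and
#' away from the sequence ends, for inject-and-recover testing.
#'
#' @param record template \linkS4class{GenomeRecord}.
#' @param n number of events.
#' @param seed RNG seed.
#' @param maxIndel largest InDel length.
#' @param minGap minimum spacing between events (bp).
#' @return events data.frame as for \code{\link{mutateGenome}}.
#' @export
randomVariantEvents <- function(record, n, seed = 1L, maxIndel = 5L,
                                minGap = 25L) {
  s <- asDnaChar(record)
  len <- nchar(s)
  need <- n * (minGap + maxIndel + 2L) + 2L * minGap + maxIndel
  if (len < need)
    toolError("E_INPUT", sprintf("sequence too short for %d spaced events", n))
  withSeed(seed, {
    # one event per equal-width bin guarantees the spacing deterministically
    binw <- (len - 2L * minGap - maxIndel) %/% n
    jitter <- sample.int(max(1L, binw - minGap - maxIndel), n, replace = TRUE) - 1L
    slots <- minGap + (seq_len(n) - 1L) * binw + jitter + 1L
    kinds <- sample(c("substitution", "insertion", "deletion"), n, replace = TRUE)
    lens <- ifelse(kinds == "substitution", 1L, sample(seq_len(maxIndel), n,
                                                       replace = TRUE))
    alleles <- vapply(seq_len(n), function(i) {
      if (kinds[i] == "deletion") return("")
      if (kinds[i] == "substitution") {
        orig <- substr(s, slots[i], slots[i])
        sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      } else randomDna(lens[i], 0.5)
    }, character(1))
  })
  data.frame(kind = kinds, start = slots, length = lens, allele = alleles,
             stringsAsFactors = FALSE)
}

# ---- bundled trnL-UAA InDel assay ------------------------------------------

# Published assay constants: the printed primer pair and the two printed
# allele windows of the trnL-UAA intron P8 region.
HS_FWD_PRIMER <- "ATGCAAAATCTATTTATATGAAAAATAAAAAGC"
HS_REV_PRIMER <- "AATCAGTTTTTCAAAAGATTTATCAGACA"
HS_WINDOW_NOINS <- "CACTCCATAGTCTGATA"
HS_WINDOW_INS <- "CACTCCATAATAGTCTGATA"

#' Bundled cultivar panel (43 trnL-UAA windows)
#'
#' The packaged 43-cultivar Hibiscus syriacus panel: cultivar name, breeding
#' metadata, and the printed trnL-UAA intron sequence window (gapped for
#' non-carriers of the 3-bp ATA insertion).
#'
#' @return data.frame from \code{\link{readAlleleTable}}.
#' @export
hibiscusPanel <- function() {
  readAlleleTable(system.file("extdata", "hs_trnl_panel.tsv",
                              package = "plastomeDCAPS", mustWork = TRUE))
}

#' Bundled dCAPS primer pair
#'
#' @return data.frame with columns \code{name}, \code{sequence}.
#' @export
hibiscusPrimers <- function() {
  utils::read.delim(system.file("extdata", "hs_dcaps_primers.tsv",
                                package = "plastomeDCAPS", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Synthetic trnL-UAA locus pair carrying the published assay
#'
#' Reconstructs, on a synthetic backbone, the locus interrogated by the
#' bundled primer pair: the primer binding sites (each with the single
#' documented 3'-terminal primer-template mismatch), the printed allele
#' windows, and flanking/filler sequence drawn from the seed and sanitized
#' so the amplicon carries no constitutive MluCI site. The product
#' arithmetic is fixed by the published assay: 134 bp on the non-insertion
#' allele, 137 bp on the insertion allele, whose single junction AATT site
#' cuts at 105 bp (duplex semantics), or 105/28/4 counting both strand
#' nicks. Flanks are synthetic; only the primer footprints and windows
#' reproduce the real locus.
#'
#' @param seed RNG seed for flank/filler sequence.
#' @param flank extra genomic context (bp) outside the primer footprints.
#' @return named character vector c(no_insertion=, insertion=).
#' @export
hibiscusTrnlLocus <- function(seed = 101L, flank = 40L) {
  # template under the forward primer: terminal base A (primer carries C);
  # the following ATT completes a genomic AATT that the primer edit destroys
  fwdTemplate <- paste0(substr(HS_FWD_PRIMER, 1L, nchar(HS_FWD_PRIMER) - 1L), "A")
  # template under the reverse primer: plus-strand A before GTCTGATA where
  # the primer encodes T (revComp(rev) = TGTCTGATA...)
  revFoot <- as.character(revComp(HS_REV_PRIMER))
  revTemplate <- paste0("A", substr(revFoot, 2L, nchar(revFoot)))
  # fixed by product arithmetic: 33 + 3 + middle + 8 + 29 = 134
  middleLen <- 134L - nchar(HS_FWD_PRIMER) - 3L - 8L - nchar(revTemplate)
  withSeed(seed, {
    repeat {
      f5 <- randomDna(flank)
      f3 <- randomDna(flank)
      middle <- randomDna(middleLen)
      noins <- paste0(f5, fwdTemplate, "ATT", middle, "CACTCCAT",
                      revTemplate, f3)
      ins <- paste0(f5, fwdTemplate, "ATT", middle, "CACTCCAT", "AAT",
                    revTemplate, f3)
      # the simulated amplicons must carry no accidental AATT
      ampNoins <- paste0(HS_FWD_PRIMER, "ATT", middle, "CACTCCAT",
                         substr(as.character(revComp(HS_REV_PRIMER)), 1L, 29L))
      if (!grepl("AATT", ampNoins, fixed = TRUE) &&
          length(gregexpr(HS_WINDOW_NOINS, noins, fixed = TRUE)[[1]]) == 1L)
        break
    }
  })
  c(no_insertion = noins, insertion = ins)
}

#' The bundled dCAPS marker for the trnL-UAA ATA insertion
#'
#' Assembles the published assay (printed primer pair, MluCI) into a
#' \linkS4class{DcapsMarker}, with per-allele fragment predictions obtained
#' by simulating PCR and digestion on the synthetic locus pair of
#' \code{\link{hibiscusTrnlLocus}}: a single uncut 134-bp product for the
#' non-insertion allele, and a cut 137-bp product for the insertion allele
#' (fragments 105 + 32 under duplex semantics; 105 + 28 + 4 counting both
#' strand nicks of the AATT 5' overhang, of which 105 and 28 are visible on
#' a 2\% gel).
#'
#' @param seed passed to \code{\link{hibiscusTrnlLocus}}.
#' @param bothStrands store fragment predictions counting both strand nicks.
#' @return a \linkS4class{DcapsMarker} whose cut allele is the insertion.
#' @export
hibiscusDcapsMarker <- function(seed = 101L, bothStrands = FALSE) {
  locus <- hibiscusTrnlLocus(seed)
  mlucI <- builtinEnzymes()[["MluCI"]]
  ampNo <- insilicoPcr(locus[["no_insertion"]], HS_FWD_PRIMER, HS_REV_PRIMER)
  ampIns <- insilicoPcr(locus[["insertion"]], HS_FWD_PRIMER, HS_REV_PRIMER)
  frags <- list(
    no_insertion = digestAmplicon(ampNo, mlucI, bothStrands = bothStrands),
    insertion = digestAmplicon(ampIns, mlucI, bothStrands = bothStrands))
  vt <- locateAlleleDifference(locus[["no_insertion"]], locus[["insertion"]])
  flen <- nchar(HS_FWD_PRIMER); rlen <- nchar(HS_REV_PRIMER)
  fstart <- attr(ampIns, "fwd_start")
  rend <- attr(ampIns, "rev_end")
  fwd <- PrimerDesign(HS_FWD_PRIMER, "+", c(fstart, fstart + flen - 1L),
                      data.frame(position = flen, templateBase = "A",
                                 primerBase = "C", stringsAsFactors = FALSE))
  rev <- PrimerDesign(HS_REV_PRIMER, "-", c(rend - rlen + 1L, rend),
                      data.frame(position = rlen, templateBase = "T",
                                 primerBase = "A", stringsAsFactors = FALSE))
  r <- 8L
  cp <- vt$refStart - 1L
  winNo <- substr(locus[["no_insertion"]], cp - r + 1L, vt$refEnd + r)
  winIns <- substr(locus[["insertion"]], cp - r + 1L,
                   cp + nchar(vt$altAllele) + r)
  new("DcapsMarker", forward = fwd, reverse = rev, enzyme = mlucI,
      variant = vt, predictedFragments = frags,
      alleleWindows = c(no_insertion = winNo, insertion = winIns),
      cutAllele = "insertion")
}
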