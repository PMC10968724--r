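# Restriction enzymes, IUPAC site scanning, and digestion.

#' Built-in restriction enzyme set
#'
#' A small curated panel of frequent-cutter enzymes useful for dCAPS work.
#' Cut notation: \code{^} marks the top-strand scission within the
#' recognition site. Additional enzymes can be loaded with
#' \code{\link{readEnzymeTable}}; there is no live REBASE dependency.
#'
#' @return named list of \linkS4class{RestrictionEnzyme}.
#' @examples
#' builtinEnzymes()[["MluCI"]]
#' @export
builtinEnzymes <- function() {
  defs <- c(MluCI = "^AATT", Tsp509I = "^AATT", EcoRI = "G^AATTC",
            DpnII = "^GATC", MboI = "^GATC", TaqI = "T^CGA",
            HinfI = "G^ANTC", RsaI = "GT^AC", AluI = "AG^CT",
            HaeIII = "GG^CC", MseI = "T^TAA", DdeI = "C^TNAG",
            Hpy188I = "TC^NGA", NlaIII = "CATG^")
  out <- lapply(names(defs), function(nm) RestrictionEnzyme(nm, defs[[nm]]))
  setNames(out, names(defs))
}

#' Load enzymes from a two-column TSV
#'
#' @param path TSV with columns \code{name} and \code{site} (caret cut
#'   notation, e.g. \code{G^AATTC}).
#' @return named list of \linkS4class{RestrictionEnzyme}.
#' @export
readEnzymeTable <- function(path) {
  if (!file.exists(path)) toolError("E_INPUT", paste("no such file:", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("name", "site") %in% names(tab)))
    toolError("E_PARSE", "enzyme table needs columns 'name' and 'site'")
  out <- lapply(seq_len(nrow(tab)), function(i)
    RestrictionEnzyme(tab$name[i], tab$site[i]))
  setNames(out, tab$name)
}

#' Scan a sequence for restriction sites
#'
#' Finds all occurrences of the recognition site on both strands under IUPAC
#' matching and converts each to a top-strand cut position, expressed as the
#' number of bases 5' of the scission (so a cut between bases 2 and 3 is
#' position 2). Positions are deduplicated and sorted. For palindromic sites
#' the two strand scans coincide.
#'
#' @param seq linear DNA text or \code{DNAString}.
#' @param enzyme a \linkS4class{RestrictionEnzyme}.
#' @return integer vector of cut positions (possibly empty).
#' @examples
#' scanSites("AAAATTCCCCAATTGG", builtinEnzymes()[["MluCI"]])  # 2, 10
#' @export
scanSites <- function(seq, enzyme) {
  s <- DNAString(asDnaChar(seq))
  site <- enzyme@site
  plus <- matchPattern(DNAString(site), s, fixed = c(pattern = FALSE, subject = TRUE))
  cuts <- IRanges::start(plus) - 1L + enzyme@cutOffsetTop
  rcsite <- as.character(revComp(site))
  if (!identical(rcsite, site)) {
    minus <- matchPattern(DNAString(rcsite), s,
                          fixed = c(pattern = FALSE, subject = TRUE))
    cuts <- c(cuts, IRanges::end(minus) - enzyme@cutOffsetTop)
  }
  sort(unique(as.integer(cuts)))
}

# Bottom-strand scission positions (top-strand coordinates) for the same hits.
scanSitesBottom <- function(seq, enzyme) {
  s <- DNAString(asDnaChar(seq))
  site <- enzyme@site
  plus <- matchPattern(DNAString(site), s, fixed = c(pattern = FALSE, subject = TRUE))
  cuts <- IRanges::start(plus) - 1L + enzyme@cutOffsetBottom
  rcsite <- as.character(revComp(site))
  if (!identical(rcsite, site)) {
    minus <- matchPattern(DNAString(rcsite), s,
                          fixed = c(pattern = FALSE, subject = TRUE))
    cuts <- c(cuts, IRanges::end(minus) - enzyme@cutOffsetBottom)
  }
  sort(unique(as.integer(cuts)))
}

#' Digest an amplicon and report fragment lengths
#'
#' Fragment lengths are the distances between consecutive cut positions and
#' the molecule ends, reported in descending order; k cuts give k+1
#' fragments, and fragment lengths always sum to the amplicon length. By
#' default only top-strand scissions define fragment boundaries (duplex
#' length semantics: gel mobility reflects duplex length, and overhang
#' geometry does not change it). With \code{bothStrands = TRUE} the
#' bottom-strand scissions are counted as boundaries too, so an enzyme
#' leaving 5' overhangs (such as MluCI, ^AATT) additionally yields the short
#' single-stranded overhang stretch as its own "fragment" -- the accounting
#' under which a single junction site in a 137-bp amplicon reads as
#' 105 + 28 + 4 rather than 105 + 32.
#'
#' @param amplicon linear DNA text or \code{DNAString}.
#' @param enzyme a \linkS4class{RestrictionEnzyme}.
#' @param bothStrands count bottom-strand scissions as fragment boundaries.
#' @return integer vector of fragment lengths, descending.
#' @export
digestAmplicon <- function(amplicon, enzyme, bothStrands = FALSE) {
  s <- asDnaChar(amplicon)
  n <- nchar(s)
  cuts <- scanSites(s, enzyme)
  if (bothStrands) cuts <- sort(unique(c(cuts, scanSitesBottom(s, enzyme))))
  cuts <- cuts[cuts > 0L & cuts < n]
  frags <- diff(c(0L, cuts, n))
  sort(as.integer(frags), decreasing = TRUE)
}

#' Visible gel bands from a fragment list
#'
#' Fragments below \code{minVisible} (default 20 bp, the practical detection
#' floor on a 2\% agarose gel) are dropped; the rest are returned in
#' descending order.
#'
#' @param fragments integer vector of fragment lengths.
#' @param minVisible smallest detectable fragment (bp).
#' @return integer vector of visible band sizes, descending.
#' @examples
#' predictGel(c(105, 28, 4))  # 105, 28
#' @export
predictGel <- function(fragments, minVisible = 20L) {
  sort(as.integer(fragments[fragments >= minVisible]), decreasing = TRUE)
}
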