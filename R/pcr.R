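# In-silico PCR with primer-sequence propagation into the product (the
# essential dCAPS mechanism: deliberate primer mismatches end up in the
# amplicon).

#' Default in-silico PCR parameters
#'
#' @param maxMismatch maximum mismatches between a primer and its best
#'   binding site over the full primer length.
#' @param seedLen length of the exact-ish 3'-terminal seed.
#' @param seedMismatch mismatches tolerated within the seed.
#' @param uniquenessMargin the best site per primer must beat the runner-up
#'   by at least this many mismatches, else binding is called ambiguous.
#' @param productRange allowed amplicon length range (bp).
#' @return list of parameters.
#' @export
pcrParams <- function(maxMismatch = 3L, seedLen = 12L, seedMismatch = 1L,
                      uniquenessMargin = 2L, productRange = c(40L, 5000L)) {
  list(maxMismatch = as.integer(maxMismatch), seedLen = as.integer(seedLen),
       seedMismatch = as.integer(seedMismatch),
       uniquenessMargin = as.integer(uniquenessMargin),
       productRange = as.integer(productRange))
}

countMismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Candidate binding sites of `primer` on the plus strand of `subject`:
# the primer's 3'-terminal seed must match with <= seedMismatch mismatches,
# the full footprint with <= maxMismatch. Returns data.frame(start, end, mm)
# with 1-based plus-strand footprint coordinates, 3' end at `end`.
.forwardHits <- function(primer, subject, params) {
  plen <- nchar(primer)
  seed <- substr(primer, plen - params$seedLen + 1L, plen)
  hits <- matchPattern(DNAString(seed), DNAString(subject),
                       max.mismatch = params$seedMismatch,
                       fixed = c(pattern = TRUE, subject = TRUE))
  ends <- IRanges::end(hits)
  ends <- ends[ends >= plen]
  if (!length(ends)) return(data.frame(start = integer(), end = integer(),
                                       mm = integer()))
  mm <- vapply1i(as.list(ends), function(e) {
    win <- substr(subject, e - plen + 1L, e)
    as.integer(countMismatches(win, primer))
  })
  ok <- mm <= params$maxMismatch
  data.frame(start = as.integer(ends[ok] - plen + 1L),
             end = as.integer(ends[ok]), mm = mm[ok])
}

.bestUniqueHit <- function(hits, what, params) {
  if (!nrow(hits))
    toolError("E_NO_SITE", sprintf("no binding site for the %s primer", what))
  hits <- hits[order(hits$mm, hits$start), , drop = FALSE]
  if (nrow(hits) > 1L && hits$mm[2] - hits$mm[1] < params$uniquenessMargin)
    toolError("E_MULTI_SITE",
              sprintf("multiple near-equivalent binding sites for the %s primer",
                      what))
  hits[1, , drop = FALSE]
}

#' Simulate PCR on a template
#'
#' Locates the best binding site for each primer on opposite strands (3'
#' seed match, then full-primer mismatch count) and returns the amplicon
#' spanned by the two primer 5' ends. The primer footprints in the product
#' carry the \emph{primer} sequences, so deliberate primer-template
#' mismatches propagate into the amplicon. Circular templates are searched
#' across the origin. Failure modes raise conditions with distinct classes:
#' \code{E_NO_SITE}, \code{E_MULTI_SITE}, \code{E_PRODUCT_SIZE},
#' \code{E_PRIMER_OVERLAP}, \code{E_INPUT}.
#'
#' @param template a \linkS4class{GenomeRecord} or DNA text.
#' @param fwd,rev primer sequences 5'->3' (15-40 nt).
#' @param params see \code{\link{pcrParams}}.
#' @return character scalar: the amplicon (plus strand, starting with the
#'   forward primer), with attributes \code{fwd_start} and \code{rev_end}
#'   (template coordinates of the footprints) and \code{orientation}.
#' @export
insilicoPcr <- function(template, fwd, rev, params = pcrParams()) {
  s <- asDnaChar(template)
  fwd <- toupper(asDnaChar(fwd)); rev <- toupper(asDnaChar(rev))
  if (nchar(fwd) < 15L || nchar(fwd) > 40L || nchar(rev) < 15L || nchar(rev) > 40L)
    toolError("E_INPUT", "primers must be 15-40 nt")
  circular <- is(template, "GenomeRecord") && isCircular(template)
  n <- nchar(s)
  subj <- if (circular) paste0(s, substr(s, 1L, min(n, params$productRange[2]))) else s

  tryOrientation <- function(fp, rp) {
    fhits <- .forwardHits(fp, subj, params)
    # reverse primer anneals the plus strand; its footprint is revComp(rev)
    # and its 3'-terminal seed sits at the footprint *start*:
    rcp <- as.character(revComp(rp))
    plen <- nchar(rcp)
    seed <- substr(rcp, 1L, params$seedLen)
    hh <- matchPattern(DNAString(seed), DNAString(subj),
                       max.mismatch = params$seedMismatch,
                       fixed = c(pattern = TRUE, subject = TRUE))
    st <- IRanges::start(hh)
    st <- st[st + plen - 1L <= nchar(subj)]
    rmm <- vapply1i(as.list(st), function(b) {
      win <- substr(subj, b, b + plen - 1L)
      as.integer(countMismatches(win, rcp))
    })
    okr <- rmm <= params$maxMismatch
    rhits <- data.frame(start = as.integer(st[okr]),
                        end = as.integer(st[okr] + plen - 1L), mm = rmm[okr])
    if (circular) {
      fhits <- fhits[!duplicated(circIndex(fhits$start, n)), , drop = FALSE]
      rhits <- rhits[!duplicated(circIndex(rhits$start, n)), , drop = FALSE]
    }
    fbest <- .bestUniqueHit(fhits, "forward", params)
    rbest <- .bestUniqueHit(rhits, "reverse", params)
    list(f = fbest, r = rbest)
  }

  hit <- tryCatch(tryOrientation(fwd, rev), E_NO_SITE = function(e) e)
  orientation <- "+"
  if (inherits(hit, "condition")) {
    # try the swapped orientation (product on the other strand)
    hit2 <- tryCatch(tryOrientation(rev, fwd), E_NO_SITE = function(e) NULL,
                     E_MULTI_SITE = function(e) NULL)
    if (is.null(hit2)) stop(hit)
    hit <- hit2
    orientation <- "-"
    tmp <- fwd; fwd <- rev; rev <- tmp
  }
  fstart <- hit$f$start; fend <- hit$f$end
  rstart <- hit$r$start; rend <- hit$r$end
  if (circular && rstart < fstart) {  # product wraps the origin
    rstart <- rstart + n
    rend <- rend + n
  }
  if (rstart <= fend)
    toolError("E_PRIMER_OVERLAP", "primer footprints overlap or are inverted")
  plen <- rend - fstart + 1L
  if (plen < params$productRange[1] || plen > params$productRange[2])
    toolError("E_PRODUCT_SIZE",
              sprintf("product length %d outside allowed range [%d, %d]",
                      plen, params$productRange[1], params$productRange[2]))
  mid <- substr(subj, fend + 1L, rstart - 1L)
  amp <- paste0(fwd, mid, as.character(revComp(rev)))
  structure(amp,
            fwd_start = circIndex(fstart, n), rev_end = circIndex(rend, n),
            orientation = orientation,
            fwd_mismatches = hit$f$mm, rev_mismatches = hit$r$mm)
}
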