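# Pairwise whole-plastome comparison and specimen-specific variant calling
# from a multiple alignment.

unitCostMatrix <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(ab, ab))
  diag(m) <- 0
  m["N", ] <- -1; m[, "N"] <- -1; m["N", "N"] <- 0
  m
}

# Global unit-cost alignment of two (short) chunks via dynamic programming.
.dpAlign <- function(a, b) {
  if (!nchar(a) && !nchar(b)) return(list(a = "", b = "", cost = 0))
  if (!nchar(a)) return(list(a = strrep("-", nchar(b)), b = b, cost = nchar(b)))
  if (!nchar(b)) return(list(a = a, b = strrep("-", nchar(a)), cost = nchar(a)))
  # the 1e-3 gap-opening term only breaks ties among minimal unit-cost
  # alignments, preferring contiguous gap runs (canonical InDel form)
  pa <- pairwiseAlignment(a, b, substitutionMatrix = unitCostMatrix(),
                          gapOpening = 1e-3, gapExtension = 1, type = "global")
  list(a = as.character(alignedPattern(pa)),
       b = as.character(alignedSubject(pa)),
       cost = round(-score(pa)))
}

# Shared unique k-mer anchors between two sequences, chained colinearly.
.anchorChain <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(NULL)
  sa <- seq_len(na - k + 1L); sb <- seq_len(nb - k + 1L)
  ka <- substring(a, sa, sa + k - 1L)
  kb <- substring(b, sb, sb + k - 1L)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  mm <- match(ka, kb)
  ok <- ua & !is.na(mm) & ub[pmin(pmax(mm, 1L), length(ub))]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NULL)
  pa <- sa[ok]; pb <- mm[ok]
  # longest increasing subsequence on pb (pa already increasing)
  lis <- function(x) {
    tails <- integer(0); prev <- integer(length(x)); tailIdx <- integer(0)
    for (i in seq_along(x)) {
      pos <- findInterval(x[i] - 1L, x[tailIdx]) + 1L
      prev[i] <- if (pos > 1L) tailIdx[pos - 1L] else 0L
      tailIdx[pos] <- i
      length(tailIdx) <- max(length(tailIdx), pos)
    }
    out <- integer(0); i <- tailIdx[length(tailIdx)]
    while (i > 0L) { out <- c(i, out); i <- prev[i] }
    out
  }
  sel <- lis(pb)
  pa <- pa[sel]; pb <- pb[sel]
  # greedy thinning to anchors that do not overlap the previous kept anchor
  keep <- logical(length(pa))
  lastA <- -k; lastB <- -k
  for (i in seq_along(pa)) {
    if (pa[i] >= lastA + k && pb[i] >= lastB + k) {
      keep[i] <- TRUE
      lastA <- pa[i]; lastB <- pb[i]
    }
  }
  cbind(a = pa[keep], b = pb[keep])
}

#' Global alignment of two (long, near-identical) sequences
#'
#' For short inputs a full unit-cost (match 0, mismatch 1, gap 1 per column)
#' global alignment is computed directly. Long near-identical sequences are
#' aligned by anchoring on shared unique k-mers and running the full dynamic
#' program only between consecutive anchors, which is exact whenever the true
#' differences fall between anchors (always the case for >99\% identical
#' plastomes). Circular records should be canonicalized first (see
#' \code{\link{canonicalRotation}}) so that origin placement cannot create
#' spurious terminal gaps.
#'
#' @param a,b \linkS4class{GenomeRecord}s, \code{DNAString}s or DNA text.
#' @param k anchor k-mer length (default 31).
#' @param fullLimit total length (bp) below which the unrestricted dynamic
#'   program is used directly, and the anchor-free fallback is allowed
#'   (default 20000).
#' @return an \linkS4class{AlignedPair}.
#' @export
alignPair <- function(a, b, k = 31L, fullLimit = 20000L) {
  ida <- if (is(a, "GenomeRecord")) genomeId(a) else "a"
  idb <- if (is(b, "GenomeRecord")) genomeId(b) else "b"
  sa <- asDnaChar(a); sb <- asDnaChar(b)
  if (!nchar(sa) || !nchar(sb)) toolError("E_INPUT", "empty sequence")
  if (nchar(sa) + nchar(sb) <= fullLimit) {
    al <- .dpAlign(sa, sb)
    return(new("AlignedPair", ids = c(ida, idb), a = al$a, b = al$b,
               cost = al$cost))
  }
  anchors <- .anchorChain(sa, sb, k)
  if (is.null(anchors) || nrow(anchors) < 1L)
    toolError("E_NO_ANCHOR", paste(
      "no shared unique anchor k-mer between the sequences;",
      "decrease k or align shorter regions"))
  outA <- character(); outB <- character(); cost <- 0
  prevA <- 1L; prevB <- 1L
  for (i in seq_len(nrow(anchors))) {
    ga <- substr(sa, prevA, anchors[i, "a"] - 1L)
    gb <- substr(sb, prevB, anchors[i, "b"] - 1L)
    if (nchar(ga) + nchar(gb) > fullLimit)
      toolError("E_SEGMENT", "inter-anchor segment too long; decrease k")
    al <- .dpAlign(ga, gb)
    outA <- c(outA, al$a, substr(sa, anchors[i, "a"], anchors[i, "a"] + k - 1L))
    outB <- c(outB, al$b, substr(sb, anchors[i, "b"], anchors[i, "b"] + k - 1L))
    cost <- cost + al$cost
    prevA <- anchors[i, "a"] + k
    prevB <- anchors[i, "b"] + k
  }
  al <- .dpAlign(substr(sa, prevA, nchar(sa)), substr(sb, prevB, nchar(sb)))
  outA <- c(outA, al$a); outB <- c(outB, al$b)
  cost <- cost + al$cost
  new("AlignedPair", ids = c(ida, idb),
      a = paste(outA, collapse = ""), b = paste(outB, collapse = ""),
      cost = cost)
}

#' Column statistics of a pairwise alignment
#'
#' Gap columns are columns where exactly one row has \code{-}; mismatch
#' columns are gap-free columns with differing bases. The identity percent is
#' gap-excluded: \code{100 * match / (match + mismatch)}, rounded half-up to
#' two decimals (so two plastomes differing by 12 substitutions and 20 gap
#' positions over 161 kb report 99.99, not the gap-inclusive 99.98).
#'
#' @param alignment an \linkS4class{AlignedPair}.
#' @return data.frame with one row: \code{aligned_columns},
#'   \code{match_columns}, \code{mismatch_columns}, \code{gap_columns},
#'   \code{gap_events} (gap openings), \code{identity_pct}.
#' @export
pairwiseStats <- function(alignment) {
  ca <- strsplit(alignment@a, "")[[1]]
  cb <- strsplit(alignment@b, "")[[1]]
  gap <- xor(ca == "-", cb == "-")
  both <- ca == "-" & cb == "-"
  if (any(both)) toolError("E_INPUT", "alignment has all-gap columns")
  mat <- !gap & ca == cb
  mis <- !gap & !mat
  runs <- rle(gap)
  stats <- data.frame(
    aligned_columns = length(ca),
    match_columns = sum(mat),
    mismatch_columns = sum(mis),
    gap_columns = sum(gap),
    gap_events = sum(runs$values),
    identity_pct = roundHalfUp(100 * sum(mat) / max(1L, sum(mat) + sum(mis)), 2L))
  stopifnot(stats$match_columns + stats$mismatch_columns + stats$gap_columns ==
            stats$aligned_columns)
  stats
}

#' Specimen-specific variants from a multiple alignment
#'
#' A column contributes to an event when exactly one row disagrees with the
#' unanimous consensus of all other rows; maximal runs of adjacent columns
#' with the same dissenting specimen and event kind are merged into one
#' event. One row carrying bases where all others have gaps is an insertion
#' for that row; one row carrying gaps is a deletion. Columns where two or
#' more rows disagree with the rest are not specimen-specific: they are
#' counted in the \code{ambiguous_sites} attribute, never silently dropped.
#'
#' @param msa named character vector of equal-width gapped rows (aligned
#'   FASTA semantics), a \code{DNAStringSet}, or a list of such; at least 3
#'   rows.
#' @return data.frame of events with columns \code{specimen}, \code{kind}
#'   (substitution/insertion/deletion), \code{column_start} (1-based
#'   alignment column), \code{length}, \code{allele},
#'   \code{background_allele}; attribute \code{ambiguous_sites} holds the
#'   count of non-specimen-specific polymorphic columns.
#' @export
msaSpecimenVariants <- function(msa) {
  if (is(msa, "DNAStringSet") || is(msa, "list"))
    msa <- vapply(msa, as.character, character(1))
  msa <- toupper(msa)
  if (length(msa) < 3L) toolError("E_INPUT", "need at least 3 aligned rows")
  if (length(unique(nchar(msa))) != 1L)
    toolError("E_INPUT", "aligned rows must have equal width")
  if (is.null(names(msa)) || any(!nzchar(names(msa))))
    names(msa) <- paste0("seq", seq_along(msa))
  mat <- do.call(rbind, strsplit(msa, ""))
  nc <- ncol(mat); nr <- nrow(mat)
  specimen <- character(nc); kind <- character(nc)
  ambiguous <- 0L
  for (j in seq_len(nc)) {
    col <- mat[, j]
    tab <- table(col)
    if (length(tab) == 1L) next
    if (length(tab) == 2L && any(tab == 1L)) {
      dis <- which(col == names(tab)[tab == 1L][1])
      rest <- names(tab)[tab == nr - 1L]
      specimen[j] <- rownames(mat)[dis] %||% names(msa)[dis]
      kind[j] <- if (col[dis] == "-") "deletion"
                 else if (rest == "-") "insertion"
                 else "substitution"
    } else {
      ambiguous <- ambiguous + 1L
    }
  }
  events <- list()
  j <- 1L
  while (j <= nc) {
    if (!nzchar(specimen[j])) { j <- j + 1L; next }
    j2 <- j
    while (j2 < nc && specimen[j2 + 1L] == specimen[j] &&
           kind[j2 + 1L] == kind[j]) j2 <- j2 + 1L
    dis <- which(names(msa) == specimen[j])[1]
    others <- setdiff(seq_len(nr), dis)
    allele <- paste(mat[dis, j:j2], collapse = "")
    background <- paste(mat[others[1], j:j2], collapse = "")
    events[[length(events) + 1L]] <- data.frame(
      specimen = specimen[j], kind = kind[j], column_start = j,
      length = j2 - j + 1L,
      allele = gsub("-", "", allele),
      background_allele = gsub("-", "", background),
      stringsAsFactors = FALSE)
    j <- j2 + 1L
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(specimen = character(), kind = character(),
               column_start = integer(), length = integer(),
               allele = character(), background_allele = character(),
               stringsAsFactors = FALSE)
  attr(out, "ambiguous_sites") <- ambiguous
  out
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x) || !nzchar(x)) y else x
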