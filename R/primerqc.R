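# Primer quality metrics: GC, nearest-neighbor melting temperature,
# hairpin-stem and 3'-anchored dimer complementarity runs.

# Unified nearest-neighbor parameters (duplex formation, 1 M NaCl):
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set,
#' terminal initiation terms, an entropic salt correction of
#' \code{0.368 (N-1) ln[Na+]}, and the CT/4 symmetry term for
#' non-self-complementary oligos.
#'
#' @param seq primer 5'->3' (ACGT only).
#' @param na monovalent cation concentration, mol/L (default 0.05).
#' @param ct total oligo concentration, mol/L (default 2.5e-7, i.e. 250 nM).
#' @return melting temperature in degrees C.
#' @export
primerTm <- function(seq, na = 0.05, ct = 2.5e-7) {
  s <- asDnaChar(seq)
  if (grepl("[^ACGT]", s)) toolError("E_INPUT", "Tm requires an ACGT-only primer")
  n <- nchar(s)
  if (n < 2L) toolError("E_INPUT", "primer too short for the NN model")
  pos <- seq_len(n - 1L)
  nn <- substring(s, pos, pos + 1L)
  dH <- sum(NN_DH[nn])
  dS <- sum(NN_DS[nn])
  ends <- c(substr(s, 1L, 1L), substr(s, n, n))
  for (b in ends) {
    if (b %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  selfComp <- identical(as.character(revComp(s)), s)
  if (selfComp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(na)
  x <- if (selfComp) 1 else 4
  dH * 1000 / (dS + 1.987 * log(ct / x)) - 273.15
}

# Longest reverse-complementary run between two non-overlapping segments.
hairpinStem <- function(seq) {
  s <- asDnaChar(seq)
  n <- nchar(s)
  rc <- as.character(revComp(s))
  best <- 0L
  for (L in seq_len(n %/% 2L)) {
    found <- FALSE
    for (i in seq_len(n - 2L * L + 1L)) {
      stem <- as.character(revComp(substr(s, i, i + L - 1L)))
      # search for the complementary copy strictly downstream
      rest <- substr(s, i + L, n)
      if (grepl(stem, rest, fixed = TRUE)) { found <- TRUE; break }
    }
    if (found) best <- L else break
  }
  best
}

# Longest complementary run anchored at either 3' terminus against the
# partner (or self).
dimerRun <- function(seq, partner = NULL) {
  a <- asDnaChar(seq)
  b <- if (is.null(partner)) a else asDnaChar(partner)
  run <- function(p, q) {   # 3' end of p against anywhere in q
    np <- nchar(p)
    for (L in seq(min(np, nchar(q)), 1L)) {
      tail3 <- substr(p, np - L + 1L, np)
      if (grepl(as.character(revComp(tail3)), q, fixed = TRUE)) return(L)
    }
    0L
  }
  max(run(a, b), run(b, a))
}

#' Primer quality-control metrics
#'
#' Length, exact GC percent, nearest-neighbor Tm (see \code{\link{primerTm}}),
#' longest self-complementary hairpin stem between two non-overlapping primer
#' segments, and the longest 3'-anchored complementary run against the
#' partner primer (or against itself when no partner is given).
#'
#' @param seq primer 5'->3' (10-50 nt).
#' @param partner optional partner primer for cross-dimer assessment.
#' @param na,ct see \code{\link{primerTm}}.
#' @return one-row data.frame: \code{length}, \code{gc_pct}, \code{tm},
#'   \code{hairpin_stem}, \code{dimer_run}.
#' @examples
#' primerQc("ATGCAAAATCTATTTATATGAAAAATAAAAAGC")
#' @export
primerQc <- function(seq, partner = NULL, na = 0.05, ct = 2.5e-7) {
  s <- asDnaChar(seq)
  n <- nchar(s)
  if (n < 10L || n > 50L) toolError("E_INPUT", "primer length must be 10-50 nt")
  gc <- 100 * lengths(regmatches(s, gregexpr("[GC]", s))) / n
  data.frame(length = n, gc_pct = gc, tm = primerTm(s, na, ct),
             hairpin_stem = hairpinStem(s), dimer_run = dimerRun(s, partner))
}

#' GC percent of a sequence
#'
#' @param seq DNA text or \code{DNAString}.
#' @param digits rounding digits (half-up).
#' @return percent GC.
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(seq, digits = 2L) {
  s <- asDnaChar(seq)
  roundHalfUp(100 * lengths(regmatches(s, gregexpr("[GCgc]", s))) / nchar(s),
              digits)
}
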