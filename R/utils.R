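# Internal helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupacMatches <- function(base, code) base %in% IUPAC_SETS[[code]]

asDnaChar <- function(x) {
  if (is(x, "GenomeRecord")) return(as.character(x@sequence))
  if (is(x, "DNAString") || is(x, "DNAStringSet")) return(as.character(x))
  toupper(chartr("uU", "tT", as.character(x)))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Round half away from zero (GenBank/report convention), vectorized.
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Circular index arithmetic, 1-based.
circIndex <- function(pos, n) ((pos - 1L) %% n) + 1L

# Extract a (possibly wrapping) substring of length len starting at 1-based
# start on a circular sequence given as a character scalar.
circSubstr <- function(s, start, len) {
  n <- nchar(s)
  start <- circIndex(start, n)
  if (start + len - 1L <= n) return(substr(s, start, start + len - 1L))
  paste0(substr(s, start, n), substr(s, 1L, len - (n - start + 1L)))
}

# Signed circular offset of pos relative to ref, mapped into (-n/2, n/2].
circOffset <- function(pos, ref, n) {
  d <- (pos - ref) %% n
  ifelse(d > n / 2, d - n, d)
}

# Condition constructor for machine-parsable tool errors.
toolError <- function(code, msg, class2 = "plastomeDCAPS_error") {
  stop(structure(class = c(code, class2, "error", "condition"),
                 list(message = sprintf("[%s] %s", code, msg), call = sys.call(-1))))
}

vapply1c <- function(x, f) vapply(x, f, character(1), USE.NAMES = FALSE)
vapply1i <- function(x, f) vapply(x, f, integer(1), USE.NAMES = FALSE)
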