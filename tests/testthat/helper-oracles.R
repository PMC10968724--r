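# Independent oracles used by the property tests. These deliberately avoid
# the implementation's code paths: diagonal scanning instead of k-mer
# hashing, regex-based IUPAC matching instead of Biostrings, utils::adist
# instead of the aligner.

# Simple base-by-base reverse complement (ACGT only).
oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# IUPAC-aware reverse complement by explicit lookup of code/complement pairs.
oracleRevComp2 <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Quadratic longest-inverted-repeat search on a LINEAR sequence: compares
# every diagonal of s against its reverse complement and keeps the longest
# run whose two copies do not overlap. Returns the length (0 if none).
oracleLongestInvertedRepeat <- function(s, minLen) {
  n <- nchar(s)
  sv <- strsplit(s, "")[[1]]
  rv <- strsplit(oracleRevComp(s), "")[[1]]
  best <- 0L
  for (d in (-(n - 1L)):(n - 1L)) {
    i <- max(1L, 1L - d):min(n, n - d)
    eq <- sv[i] == rv[i + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= max(minLen, best + 1L))) {
      L <- r$lengths[k]
      i0 <- i[ends[k] - L + 1L]
      j0 <- i0 + d
      # try all sub-runs? the maximal run suffices for the longest pair,
      # but overlap can truncate: shrink until the copies are disjoint
      while (L >= minLen) {
        bStart <- n - (j0 + L - 1L) + 1L
        bEnd <- n - j0 + 1L
        if (i0 + L - 1L < bStart || bEnd < i0) { best <- max(best, L); break }
        L <- L - 1L
      }
    }
  }
  best
}

# Regex with IUPAC character classes for a recognition site.
iupacRegex <- function(site) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(cls[strsplit(site, "")[[1]]], collapse = "")
}

# All site start positions (both strands) by regex scanning.
oracleSitePositions <- function(seq, site) {
  hits <- function(pat) {
    m <- gregexpr(sprintf("(?=%s)", pat), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  sort(unique(c(hits(iupacRegex(site)), hits(iupacRegex(oracleRevComp(site))))))
}

# Brute-force existence check for a dCAPS/CAPS design with <= 1 primer base
# change: enumerates both template orientations, every allowed primer 3'
# end, every in-footprint change position and base (or none), builds both
# allele amplicon prefixes by string surgery, and asks whether a recognition
# site overlapping the footprint and the variant appears in exactly one
# allele.
oracleDcapsExists <- function(refS, altS, site, max3PrimeDist = 10L,
                              minPrimer = 18L) {
  L <- nchar(site)
  for (orient in 1:2) {
    sx <- if (orient == 1L) refS else oracleRevComp(refS)
    sy <- if (orient == 1L) altS else oracleRevComp(altS)
    nmin <- min(nchar(sx), nchar(sy))
    xv <- strsplit(sx, "")[[1]]; yv <- strsplit(sy, "")[[1]]
    neq <- which(xv[seq_len(nmin)] != yv[seq_len(nmin)])
    cp <- if (length(neq)) neq[1] - 1L else nmin
    eLo <- max(minPrimer, cp - max3PrimeDist)
    if (eLo > cp) next
    for (e in eLo:cp) {
      for (q in max(1L, e - L + 2L):e) {
        for (b in c(NA, "A", "C", "G", "T")) {
          if (!is.na(b) && xv[q] == b) next
          pre <- xv[1:e]
          if (!is.na(b)) pre[q] <- b
          preS <- paste(pre, collapse = "")
          ampX <- paste0(preS, substr(sx, e + 1L, nchar(sx)))
          ampY <- paste0(preS, substr(sy, e + 1L, nchar(sy)))
          near <- function(amp) {
            p <- oracleSitePositions(amp, site)
            any(p <= e & p + L - 1L >= cp + 1L)
          }
          if (xor(near(ampX), near(ampY))) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Deterministic random DNA for tests (uniform base composition).
testDna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
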