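# A random locus pair with one planted variant and generous shared flanks.
plantedLocus <- function(seed, kind = c("snp", "indel"), flank = 90L) {
  kind <- match.arg(kind)
  set.seed(seed)
  f5 <- testDna(flank, seed + 1000L)
  f3 <- testDna(flank, seed + 2000L)
  if (kind == "snp") {
    base <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    list(ref = paste0(f5, base, f3), alt = paste0(f5, alt, f3))
  } else {
    ins <- testDna(sample(1:5, 1), seed + 3000L)
    list(ref = paste0(f5, f3), alt = paste0(f5, ins, f3))
  }
}
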