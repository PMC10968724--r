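test_that("identical sequences align with no gaps and full identity", {
  s <- testDna(1000L, 5L)
  al <- alignPair(s, s)
  st <- pairwiseStats(al)
  expect_equal(st$aligned_columns, 1000L)
  expect_equal(st$gap_columns, 0L)
  expect_equal(st$mismatch_columns, 0L)
  expect_equal(st$identity_pct, 100)
})

test_that("alignment cost equals the unit-cost edit distance (oracle)", {
  al <- alignPair("ACGTACGT", "ACGACGT")
  expect_equal(al@cost, 1)
  st <- pairwiseStats(al)
  expect_equal(st$gap_columns, 1L)
  expect_equal(st$mismatch_columns, 0L)
  # random mutated pairs, full-DP regime
  for (seed in 1:10) {
    a <- testDna(400L, seed)
    rec <- GenomeRecord("a", a)
    ev <- randomVariantEvents(rec, 4L, seed = seed + 50L)
    b <- as.character(genomeSeq(mutateGenome(rec, ev)))
    al <- alignPair(a, b)
    expect_equal(al@cost, as.vector(utils::adist(a, b)),
                 info = paste("seed", seed))
  }
})

test_that("anchored alignment of long near-identical sequences matches the edit distance", {
  a <- testDna(8000L, 77L)
  rec <- GenomeRecord("a", a)
  ev <- randomVariantEvents(rec, 12L, seed = 78L, minGap = 200L)
  b <- as.character(genomeSeq(mutateGenome(rec, ev)))
  al <- alignPair(a, b, fullLimit = 2000L)  # forces the anchored path
  expect_equal(nchar(al@a), nchar(al@b))
  expect_equal(gsub("-", "", al@a), a)
  expect_equal(gsub("-", "", al@b), b)
  expect_equal(al@cost, as.vector(utils::adist(a, b)))
})

test_that("column accounting sums and identity is gap-excluded, rounded half-up", {
  # 10 columns: 1 mismatch, 2 gap columns -> identity 100*7/8 = 87.50
  al <- new("AlignedPair", ids = c("a", "b"),
            a = "AACCATGGTA", b = "AAC-TTGG-A", cost = 3)
  st <- pairwiseStats(al)
  expect_equal(st$aligned_columns, 10L)
  expect_equal(st$gap_columns, 2L)
  expect_equal(st$mismatch_columns, 1L)
  expect_equal(st$identity_pct, 87.50)
  expect_equal(st$match_columns + st$mismatch_columns + st$gap_columns,
               st$aligned_columns)
  # half-up rounding at the 2nd decimal: 12 mismatches in 161,007 matches
  expect_equal(plastomeDCAPS:::roundHalfUp(100 * 160995 / 161007, 2), 99.99)
  expect_equal(plastomeDCAPS:::roundHalfUp(87.505, 2), 87.51)
})

test_that("no specimen variants are called on identical rows", {
  rows <- setNames(rep(testDna(120L, 2L), 4), paste0("s", 1:4))
  ev <- msaSpecimenVariants(rows)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "ambiguous_sites"), 0L)
})

test_that("a private run of inserted bases is one merged insertion event", {
  msa <- c(hsvm = "CACTCCATAATAGTCTGATA",
           o1   = "CACTCCATA---GTCTGATA",
           o2   = "CACTCCATA---GTCTGATA",
           o3   = "CACTCCATA---GTCTGATA")
  ev <- msaSpecimenVariants(msa)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$specimen, "hsvm")
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$length, 3L)
  expect_equal(ev$allele, "ATA")
  expect_equal(ev$column_start, 10L)
})

test_that("shared variants are ambiguous, not specimen-specific", {
  msa <- c(a = "AAAACAAAA",   # private substitution at column 5
           b = "AAAATAAGA",   # shares column 8 G with c
           c = "AAAATAAGA",
           d = "AAAATAAAA")
  ev <- msaSpecimenVariants(msa)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$specimen, "a")
  expect_equal(ev$kind, "substitution")
  expect_equal(attr(ev, "ambiguous_sites"), 1L)
})

test_that("variant calling is equivariant under row permutation", {
  msa <- c(a = "CACTCCATAATAGTCTGATA",
           b = "CACTCCATA---GTCTGATA",
           c = "CACTCCATA---GTCTGAGA",
           d = "CACTCCATA---GTCTGATA")
  ev1 <- msaSpecimenVariants(msa)
  ev2 <- msaSpecimenVariants(msa[c(3, 1, 4, 2)])
  key <- function(e) e[order(e$column_start), c("specimen", "kind", "length")]
  expect_equal(key(ev1), key(ev2), ignore_attr = TRUE)
})

test_that("planted private events are recovered with correct kinds and lengths", {
  for (seed in 1:12) {
    base <- testDna(900L, seed + 300L)
    rec <- GenomeRecord("bg", base)
    e <- 1L + (seed %% 5L)
    ev <- randomVariantEvents(rec, e, seed = seed, minGap = 40L)
    mut <- as.character(genomeSeq(mutateGenome(rec, ev)))
    al <- alignPair(mut, base)
    msa <- c(mut = al@a, bg1 = al@b, bg2 = al@b, bg3 = al@b)
    got <- msaSpecimenVariants(msa)
    expect_equal(nrow(got), e, info = paste("seed", seed))
    expect_true(all(got$specimen == "mut"))
    expect_equal(sort(paste(got$kind, got$length)),
                 sort(paste(ev$kind, ev$length)), info = paste("seed", seed))
  }
})
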