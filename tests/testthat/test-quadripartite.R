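toySpec <- function(seed = 7L, ...) plastomeSpec(seed = seed, ...)

test_that("planted inverted repeats are recovered at their positions", {
  rec <- makeToyPlastome(toySpec())
  ir <- findInvertedRepeat(rec, 50L)
  expect_equal(nrow(ir), 2L)
  expect_equal(ir$length, c(120L, 120L))
  expect_equal(sort(ir$start), c(501L, 701L))
})

test_that("no repeat is reported on repeat-free random sequence", {
  rec <- GenomeRecord("r", testDna(5000L, 11L), circular = TRUE)
  expect_equal(nrow(findInvertedRepeat(rec, 1000L)), 0L)
})

test_that("detection agrees with the quadratic oracle on random toys", {
  for (seed in 1:8) {
    n <- 300L + 37L * seed
    base <- testDna(n, seed)
    # plant an IR of varying length at varying positions
    set.seed(seed + 100L)
    irLen <- sample(60:90, 1)
    ir <- testDna(irLen, seed + 200L)
    p1 <- sample(10:(n %/% 3), 1)
    p2 <- sample((n %/% 2):(n - irLen - 10L), 1)
    s <- paste0(substr(base, 1, p1), ir,
                substr(base, p1 + 1, p2), oracleRevComp(ir),
                substr(base, p2 + 1, n))
    rec <- GenomeRecord("t", s, circular = FALSE)
    found <- findInvertedRepeat(rec, 50L)
    expect_equal(found$length[1], oracleLongestInvertedRepeat(s, 50L),
                 info = paste("seed", seed))
  }
})

test_that("partition labels regions, tiles the genome, and checks IR identity", {
  rec <- makeToyPlastome(toySpec())
  part <- partitionGenome(rec, findInvertedRepeat(rec, 50L))
  expect_equal(unname(regionLengths(part)), c(500L, 120L, 80L, 120L))
  expect_equal(sum(regionLengths(part)), genomeLength(rec))
  # detected IRb sequence is exactly the reverse complement of IRa
  s <- as.character(genomeSeq(rec))
  st <- regionStarts(part); ln <- regionLengths(part)
  irb <- substr(s, st[["IRb"]], st[["IRb"]] + ln[["IRb"]] - 1L)
  ira <- substr(s, st[["IRa"]], st[["IRa"]] + ln[["IRa"]] - 1L)
  expect_equal(irb, revComp(ira))
  # malformed pairs are rejected
  bad <- data.frame(start = c(501L, 560L), length = c(120L, 120L))
  expect_error(partitionGenome(rec, bad), class = "E_PARTITION")
})

test_that("equal single-copy segments are tie-broken with a warning", {
  # handcrafted so the single-copy segments are exactly equal
  ir <- testDna(80L, 5L)
  s <- paste0(strrep("A", 200), ir, strrep("C", 200), oracleRevComp(ir))
  rec <- GenomeRecord("tie", s, circular = TRUE)
  irPair <- data.frame(start = c(201L, 481L), length = c(80L, 80L))
  expect_warning(part <- partitionGenome(rec, irPair), "equal length")
  expect_equal(unname(regionLengths(part)[c("LSC", "SSC")]), c(200L, 200L))
})

test_that("partition lengths are invariant under rotation", {
  rec <- makeToyPlastome(toySpec())
  ref <- regionLengths(quadripartitePartition(rec, 50L))
  set.seed(99)
  for (off in sample(genomeLength(rec), 20L)) {
    rot <- plastomeDCAPS:::rotateRecord(rec, off)
    expect_equal(regionLengths(quadripartitePartition(rot, 50L)), ref,
                 info = paste("offset", off))
  }
})

test_that("canonical rotation is idempotent and rotation-invariant", {
  genes <- data.frame(name = "rps19", region = "LSC", offset = 480L,
                      length = 15L, strand = "+")
  rec <- makeToyPlastome(plastomeSpec(seed = 7L, genes = genes))
  cano <- canonicalRotation(rec, minLen = 50L)
  expect_equal(as.character(genomeSeq(canonicalRotation(cano, minLen = 50L))),
               as.character(genomeSeq(cano)))
  for (off in c(2L, 444L, 800L)) {
    rot <- plastomeDCAPS:::rotateRecord(rec, off)
    expect_equal(as.character(genomeSeq(canonicalRotation(rot, minLen = 50L))),
                 as.character(genomeSeq(cano)), info = paste("offset", off))
  }
  # canonical form starts at the LSC and keeps rps19 near the LSC/IRb junction
  part <- quadripartitePartition(cano, 50L)
  expect_equal(regionStarts(part)[["LSC"]], 1L)
})

test_that("junction distances follow the sign convention", {
  genes <- data.frame(
    name = c("atBoundary", "straddler", "inside"),
    region = c("IRb", "SSC", "SSC"),
    offset = c(100L, 55L, 10L),       # IRb len 120: gene ends at junction
    length = c(20L, 50L, 12L),        # straddler: 25 bp into IRa
    strand = c("+", "+", "+"))
  rec <- makeToyPlastome(plastomeSpec(seed = 7L, genes = genes))
  part <- quadripartitePartition(rec, 50L)
  rep <- junctionReport(rec, part, c("atBoundary", "straddler", "inside", "ghost"))
  irbSsc <- rep[rep$junction == "IRb/SSC" & rep$gene == "atBoundary", ]
  expect_equal(irbSsc$distance, 0L)
  sscIra <- rep[rep$junction == "SSC/IRa" & rep$gene == "straddler", ]
  expect_equal(sscIra$distance, -25L)
  inside <- rep[rep$junction == "IRb/SSC" & rep$gene == "inside", ]
  expect_equal(inside$distance, 10L)
  expect_true(all(is.na(rep$distance[rep$gene == "ghost"])))
  # default mode picks the nearest gene on each side
  auto <- junctionReport(rec, part)
  expect_true(all(auto$gene %in% genes$name))
  expect_true(all(abs(auto$distance) <= genomeLength(rec)))
})
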