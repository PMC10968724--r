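test_that("toy plastomes are deterministic and satisfy partition invariants", {
  spec <- plastomeSpec(seed = 7L)
  a <- makeToyPlastome(spec)
  b <- makeToyPlastome(spec)
  expect_identical(as.character(genomeSeq(a)), as.character(genomeSeq(b)))
  expect_equal(genomeLength(a), 820L)
  part <- quadripartitePartition(a, 50L)
  expect_equal(unname(regionLengths(part)), c(500L, 120L, 80L, 120L))
  expect_true(validObject(part))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(makeToyPlastome(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted junction genes land where requested", {
  genes <- data.frame(name = "gx", region = "SSC", offset = 55L,
                      length = 50L, strand = "+")
  rec <- makeToyPlastome(plastomeSpec(seed = 4L, genes = genes))
  part <- quadripartitePartition(rec, 50L)
  rep <- junctionReport(rec, part, "gx")
  expect_equal(rep$distance[rep$junction == "SSC/IRa"], -25L)
})

test_that("allele loci embed the windows and differ by the InDel length", {
  loc <- makeAlleleLocus(100L, 100L, "CACTCCATA---GTCTGATA",
                         "CACTCCATAATAGTCTGATA", seed = 9L)
  expect_equal(nchar(loc[["alt"]]) - nchar(loc[["ref"]]), 3L)
  expect_true(grepl("CACTCCATAGTCTGATA", loc[["ref"]], fixed = TRUE))
  expect_true(grepl("CACTCCATAATAGTCTGATA", loc[["alt"]], fixed = TRUE))
  same <- makeAlleleLocus(50L, 50L, "ACGT", "ACGT", seed = 1L)
  expect_identical(same[["ref"]], same[["alt"]])
  # alignment of the pair (plus two background copies) recovers one
  # 3-bp insertion event
  al <- alignPair(loc[["alt"]], loc[["ref"]])
  msa <- c(alt = al@a, ref1 = al@b, ref2 = al@b, ref3 = al@b)
  ev <- msaSpecimenVariants(msa)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$length, 3L)
  expect_equal(ev$allele, "ATA")
})

test_that("mutateGenome applies events coordinate-safely", {
  rec <- GenomeRecord("x", testDna(300L, 3L))
  expect_identical(as.character(genomeSeq(mutateGenome(rec,
    data.frame(kind = character(), start = integer(), length = integer(),
               allele = character())))), as.character(genomeSeq(rec)))
  ins <- data.frame(kind = "insertion", start = 50L, length = 3L, allele = "TTT")
  expect_equal(genomeLength(mutateGenome(rec, ins)), 303L)
  del <- data.frame(kind = "deletion", start = 50L, length = 5L, allele = "")
  expect_equal(genomeLength(mutateGenome(rec, del)), 295L)
  over <- data.frame(kind = c("deletion", "substitution"),
                     start = c(50L, 52L), length = c(5L, 1L),
                     allele = c("", "A"))
  expect_error(mutateGenome(rec, over), class = "E_INPUT")
})

test_that("the synthetic assay locus is reproducible and sanitized", {
  a <- hibiscusTrnlLocus()
  b <- hibiscusTrnlLocus()
  expect_identical(a, b)
  expect_false(identical(hibiscusTrnlLocus(seed = 7L), a))
  # windows present exactly once; insertion allele = +3 bp
  expect_equal(nchar(a[["insertion"]]) - nchar(a[["no_insertion"]]), 3L)
  expect_true(grepl("CACTCCATAGTCTGATA", a[["no_insertion"]], fixed = TRUE))
  expect_true(grepl("CACTCCATAATAGTCTGATA", a[["insertion"]], fixed = TRUE))
})
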