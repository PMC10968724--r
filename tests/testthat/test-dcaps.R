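test_that("a variant creating a native site yields a zero-mismatch CAPS design", {
  # EcoRI GAATTC completed by the variant itself, no primer edit needed
  f5 <- testDna(80L, 7L); f3 <- testDna(80L, 8L)
  ref <- paste0(f5, "GAATCC", f3)
  alt <- paste0(f5, "GAATTC", f3)
  ds <- designDcaps(ref, alt, enzymes = builtinEnzymes()["EcoRI"])
  expect_gt(length(ds), 0L)
  best <- ds[[1]]
  mm <- rbind(best@forward@introducedMismatches, best@reverse@introducedMismatches)
  expect_equal(nrow(mm), 0L)
  expect_equal(cutAllele(best), "alt")
})

test_that("the printed allele pair admits an MluCI design cutting the insertion", {
  locus <- hibiscusTrnlLocus()
  ds <- designDcaps(locus[["no_insertion"]], locus[["insertion"]],
                    enzymes = builtinEnzymes()["MluCI"],
                    alleleNames = c("no_insertion", "insertion"))
  expect_gt(length(ds), 0L)
  hit <- FALSE
  for (m in ds) {
    fr <- predictedFragments(m)
    if (cutAllele(m) == "insertion" && length(fr$no_insertion) == 1L &&
        length(fr$insertion) >= 2L) hit <- TRUE
  }
  expect_true(hit)
})

test_that("every returned design re-simulates to its own fragment predictions", {
  for (seed in 1:15) {
    kind <- if (seed %% 2) "snp" else "indel"
    loc <- plantedLocus(seed, kind)
    ds <- designDcaps(loc$ref, loc$alt)
    for (m in ds[seq_len(min(3L, length(ds)))]) {
      ampR <- insilicoPcr(loc$ref, m@forward@sequence, m@reverse@sequence)
      ampA <- insilicoPcr(loc$alt, m@forward@sequence, m@reverse@sequence)
      fr <- predictedFragments(m)
      expect_equal(digestAmplicon(ampR, m@enzyme), fr$ref,
                   info = paste("seed", seed))
      expect_equal(digestAmplicon(ampA, m@enzyme), fr$alt,
                   info = paste("seed", seed))
      expect_false(identical(sort(fr$ref), sort(fr$alt)))
      expect_equal(sum(fr$ref), nchar(ampR))
      expect_equal(sum(fr$alt), nchar(ampA))
    }
  }
})

test_that("design search is as complete as brute-force enumeration on small loci", {
  enzNames <- c("MluCI", "TaqI", "RsaI", "EcoRI")
  found <- 0L
  for (seed in 1:20) {
    loc <- plantedLocus(seed + 500L, if (seed %% 2) "snp" else "indel",
                        flank = 70L)  # locus <= 300 bp
    enz <- builtinEnzymes()[[enzNames[(seed %% 4L) + 1L]]]
    oracle <- oracleDcapsExists(loc$ref, loc$alt, enz@site)
    ds <- designDcaps(loc$ref, loc$alt, enzymes = setNames(list(enz), enz@name))
    if (oracle) {
      expect_gt(length(ds), 0L,
                label = sprintf("designs for seed %d enzyme %s (oracle found one)",
                                seed, enz@name))
      found <- found + 1L
    }
  }
  expect_gt(found, 3L)  # the comparison must actually exercise positives
})

test_that("ranking prefers fewer and non-terminal introduced mismatches", {
  for (seed in c(2L, 6L, 12L)) {
    loc <- plantedLocus(seed, "indel")
    ds <- designDcaps(loc$ref, loc$alt)
    if (length(ds) < 2L) next
    nmm <- vapply(ds, function(m)
      nrow(m@forward@introducedMismatches) + nrow(m@reverse@introducedMismatches),
      integer(1))
    expect_true(all(diff(nmm) >= 0))
  }
})

test_that("infeasible designs return empty with per-enzyme reasons", {
  # a substitution far from any completable GGCC context, single enzyme with
  # a site that cannot be completed: identical windows beyond the variant
  ref <- paste0(strrep("AT", 60), "A", strrep("TA", 60))
  alt <- paste0(strrep("AT", 60), "G", strrep("TA", 60))
  ds <- designDcaps(ref, alt, enzymes = builtinEnzymes()["HaeIII"])
  expect_length(ds, 0L)
  expect_true(nzchar(attr(ds, "rejectionReasons")[["HaeIII"]]))
})
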