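test_that("site scanning finds occurrences on both strands with IUPAC codes", {
  mlucI <- builtinEnzymes()[["MluCI"]]
  expect_equal(scanSites("GGGGGG", mlucI), integer())
  expect_equal(scanSites("AAAATTCCCCAATTGG", mlucI), c(2L, 10L))
  # palindromic site: top-strand cuts of the reverse complement mirror the
  # bottom-strand cuts of the original molecule
  s <- testDna(500L, 21L)
  expect_equal(scanSites(revComp(s), mlucI),
               sort(nchar(s) - plastomeDCAPS:::scanSitesBottom(s, mlucI)))
  # ... and the site occurrences themselves are strand-symmetric
  expect_equal(length(scanSites(s, mlucI)),
               length(scanSites(revComp(s), mlucI)))
  # degenerate site matches exactly its literal expansions
  hinfI <- builtinEnzymes()[["HinfI"]]
  for (mid in c("A", "C", "G", "T")) {
    s <- paste0("TTTTT", "G", "A", mid, "TC", "TTTTT")
    expect_equal(length(scanSites(s, hinfI)) > 0, TRUE, info = mid)
  }
})

test_that("IUPAC scanning agrees with regex-based enumeration", {
  for (seed in 1:5) {
    s <- testDna(400L, seed + 60L)
    for (enz in builtinEnzymes()[c("MluCI", "EcoRI", "HinfI", "DdeI", "TaqI")]) {
      starts <- oracleSitePositions(s, enz@site)
      got <- scanSites(s, enz)
      L <- nchar(enz@site)
      # every reported cut sits within an oracle occurrence, and cuts exist
      # exactly when occurrences exist
      expect_true(all(vapply(got, function(cut)
        any(starts - 1L <= cut & cut <= starts - 1L + L), TRUE)),
        info = enz@name)
      expect_equal(length(got) == 0L, length(starts) == 0L, info = enz@name)
    }
  }
})

test_that("digestion produces k+1 fragments that conserve mass", {
  mlucI <- builtinEnzymes()[["MluCI"]]
  expect_equal(digestAmplicon("GGGGGGGG", mlucI), 8L)
  expect_equal(digestAmplicon("AAAATTCCCCAATTGG", mlucI), c(8L, 6L, 2L))
  set.seed(31)
  for (i in 1:40) {
    amp <- paste(sample(c("A", "C", "G", "T"), sample(30:400, 1),
                        replace = TRUE), collapse = "")
    enz <- sample(builtinEnzymes(), 1)[[1]]
    for (both in c(FALSE, TRUE)) {
      fr <- digestAmplicon(amp, enz, bothStrands = both)
      expect_equal(sum(fr), nchar(amp), info = enz@name)
      expect_true(all(diff(fr) <= 0))
      cuts <- scanSites(amp, enz)
      if (!both) expect_length(fr, length(cuts[cuts > 0 & cuts < nchar(amp)]) + 1L)
    }
  }
})

test_that("both-strand accounting exposes 5'-overhang slivers", {
  # one AATT site 10 bp into a 30-mer: duplex fragments 10/20, with the
  # bottom-strand nick 4 bp later adding the 4-base overhang stretch
  amp <- paste0(strrep("G", 10), "AATT", strrep("G", 16))
  mlucI <- builtinEnzymes()[["MluCI"]]
  expect_equal(digestAmplicon(amp, mlucI), c(20L, 10L))
  expect_equal(digestAmplicon(amp, mlucI, bothStrands = TRUE), c(16L, 10L, 4L))
})

test_that("enzyme construction validates sites and caret notation", {
  ecoRI <- RestrictionEnzyme("EcoRI", "G^AATTC")
  expect_equal(ecoRI@cutOffsetTop, 1L)
  expect_equal(ecoRI@cutOffsetBottom, 5L)
  expect_error(RestrictionEnzyme("bad", "^AAT"))       # too short
  expect_error(RestrictionEnzyme("bad", "AATT"))       # no cut position
  tab <- readEnzymeTable(system.file("extdata", "enzymes.tsv",
                                     package = "plastomeDCAPS"))
  expect_true("MluCI" %in% names(tab))
  expect_equal(tab[["MluCI"]]@cutOffsetTop, 0L)
})

test_that("gel prediction hides sub-visible fragments", {
  expect_equal(predictGel(c(105L, 28L, 4L)), c(105L, 28L))
  expect_equal(predictGel(c(134L)), 134L)
  expect_equal(predictGel(integer()), integer())
  expect_equal(predictGel(c(19L, 3L)), integer())
})
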