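test_that("FASTA round-trips, normalizes case/U, and flags circular headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y circular plastome", "ACGUACGU", "ACGT"), f)
  recs <- readFastaGenomes(f)
  expect_length(recs, 2L)
  expect_equal(genomeId(recs[[1]]), "x")
  expect_equal(as.character(genomeSeq(recs[[1]])), "ACGT")
  expect_equal(genomeLength(recs[[1]]), 4L)
  expect_false(isCircular(recs[[1]]))
  expect_true(isCircular(recs[[2]]))
  expect_equal(as.character(genomeSeq(recs[[2]])), "ACGTACGTACGT")

  out <- withr::local_tempfile(fileext = ".fa")
  writeFastaGenomes(recs, out)
  back <- readFastaGenomes(out)
  expect_equal(vapply(back, genomeId, ""), vapply(recs, genomeId, ""))
  expect_equal(vapply(back, function(r) as.character(genomeSeq(r)), ""),
               vapply(recs, function(r) as.character(genomeSeq(r)), ""))
  expect_equal(vapply(back, isCircular, TRUE), vapply(recs, isCircular, TRUE))
})

test_that("FASTA parse errors name the problem", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGJ"), f)
  expect_error(readFastaGenomes(f), class = "E_PARSE")
  writeLines(character(), f)
  expect_error(readFastaGenomes(f), class = "E_PARSE")
  expect_error(readFastaGenomes(file.path(tempdir(), "nope.fa")),
               class = "E_INPUT")
})

test_that("GenBank coordinates, strands and joins parse and round-trip", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 40 bp    DNA     circular PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     gene            10..20",
    '                     /gene="abc"',
    "     tRNA            complement(5..8)",
    '                     /gene="trnX"',
    "     gene            join(25..30,35..38)",
    '                     /gene="spliced"',
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  rec <- readGenBank(gb)
  expect_equal(genomeLength(rec), 40L)
  expect_true(isCircular(rec))
  ft <- genomeFeatures(rec)
  abc <- ft[ft$name == "abc", ]
  expect_equal(c(abc$start, abc$end), c(10L, 20L))
  trn <- ft[ft$name == "trnX", ]
  expect_equal(trn$strand, "-")
  expect_equal(trn$kind, "tRNA")
  expect_equal(c(trn$start, trn$end), c(5L, 8L))
  spl <- ft[ft$name == "spliced", ]
  expect_equal(nrow(spl), 2L)
  expect_equal(spl$start, c(25L, 35L))
  # location strings regenerate exactly
  expect_equal(plastomeDCAPS:::formatGenbankLocation(abc), "10..20")
  expect_equal(plastomeDCAPS:::formatGenbankLocation(trn), "complement(5..8)")
  expect_equal(plastomeDCAPS:::formatGenbankLocation(spl), "join(25..30,35..38)")
  # writer output re-reads to the same record
  out <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(rec, out)
  rec2 <- readGenBank(out)
  expect_equal(as.character(genomeSeq(rec2)), as.character(genomeSeq(rec)))
  expect_equal(sort(genomeFeatures(rec2)$name), sort(ft$name))
})

test_that("GenBank reader rejects records without ORIGIN", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       toy 10 bp", "FEATURES", "//"), gb)
  expect_error(readGenBank(gb), class = "E_PARSE")
})

test_that("allele tables keep gaps, strip markup, and warn on duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("no\tname\tsequence",
               "1\tA\tCACTCCATA**ATA**GTCTGATA",
               "2\tB\tCACTCCATA---GTCTGATA",
               "3\tB\tCACTCCATA---GTCTGATA"), f)
  expect_warning(tab <- readAlleleTable(f), "duplicate")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$sequence_window[1], "CACTCCATAATAGTCTGATA")
  expect_equal(nchar(tab$sequence_window[1]), 20L)
  expect_equal(lengths(regmatches(tab$sequence_window[2],
                                  gregexpr("-", tab$sequence_window[2]))), 3L)
  writeLines(c("no\tname", "1\tA"), f)
  expect_error(readAlleleTable(f), class = "E_PARSE")
})

test_that("the packaged panel has 43 rows with the printed windows", {
  tab <- hibiscusPanel()
  expect_equal(nrow(tab), 43L)
  expect_equal(tab$sequence_window[tab$name == "HSVM"], "CACTCCATAATAGTCTGATA")
  expect_equal(sum(grepl("-", tab$sequence_window)), 32L)
})

test_that("revComp handles IUPAC codes and is an involution", {
  expect_equal(revComp("AATT"), "AATT")
  expect_equal(revComp("ACGTN"), "NACGT")
  expect_equal(revComp("RYSWKM"), "KMWSRY")
  expect_error(revComp("ACGJ"), class = "E_ALPHABET")
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A","C","G","T","N","R","Y","W","S"), 30,
                      replace = TRUE), collapse = "")
    expect_equal(revComp(revComp(s)), s)
    expect_equal(nchar(revComp(s)), nchar(s))
    expect_equal(revComp(s), oracleRevComp2(s))
  }
})
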