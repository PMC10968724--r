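#!/usr/bin/env Rscript
# One-time download of the three deposited Hibiscus syriacus chloroplast
# genome records used by the accession-dependent acceptance tests. The
# package itself never touches the network; this helper writes the GenBank
# flat files under inst/accessions/ where the tests look for them.
#
#   Rscript scripts/fetch_accessions.R
#
# Requires internet access and curl.

accs <- c("OM687473", "OM687472", "OM541594")
dir.create("inst/accessions", recursive = TRUE, showWarnings = FALSE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gbwithparts&retmode=text&id=")
for (acc in accs) {
  dest <- file.path("inst/accessions", paste0(acc, ".gb"))
  if (file.exists(dest)) {
    message(acc, " already present, skipping")
    next
  }
  message("fetching ", acc, " ...")
  status <- system2("curl", c("-sf", shQuote(paste0(base, acc)),
                              "-o", shQuote(dest)))
  if (status != 0L || !file.size(dest)) {
    unlink(dest)
    stop("download failed for ", acc)
  }
}
message("done; re-run the test suite to exercise the accession checks")
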