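#!/usr/bin/env Rscript

# Fetch the two deposited pseudoscorpion mitogenome records from NCBI and
# store them as GenBank flat files under inst/extdata/genbank/, enabling the
# published-value reproduction checks. Requires network access; nothing in
# the test suite or acceptance script performs downloads itself.
#
#   Rscript scripts/fetch_genbank.R

accessions <- c("JQ040543", "JQ040544")
dest <- file.path("inst", "extdata", "genbank")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (acc in accessions) {
  url <- sprintf("%s?db=nuccore&id=%s&rettype=gb&retmode=text", base, acc)
  out <- file.path(dest, paste0(acc, ".gb"))
  message("fetching ", acc, " -> ", out)
  utils::download.file(url, out, quiet = TRUE, mode = "wb")
  Sys.sleep(1)
}
message("done")
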