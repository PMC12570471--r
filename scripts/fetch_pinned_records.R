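#!/usr/bin/env Rscript
# Optional, network-requiring companion script: downloads the pinned
# Pseudomonas putida KT2440 assembly feature tables (GenBank
# GCA_000007565.2 / RefSeq GCF_000007565.2) from the NCBI FTP mirror and
# runs the full comparison on the real records.
#
# The test suite never requires this script. Note that RefSeq re-annotates
# records on a rolling schedule: counts computed from a freshly downloaded
# RefSeq table may drift from any previously published tally, which is why
# the provenance block records the retrieval date alongside the accession.
#
# Usage: Rscript scripts/fetch_pinned_records.R [--out DIR] [--cog PATH]

suppressPackageStartupMessages({
  library(optparse)
  library(annodiff)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "kt2440_compare"),
  make_option("--cog", type = "character", default = NULL,
              help = "optional COG assignment TSV (locus_tag, cog_letters)")
)))

base <- "https://ftp.ncbi.nlm.nih.gov/genomes/all"
urls <- c(
  genbank = file.path(base, "GCA/000/007/565/GCA_000007565.2_ASM756v2",
                      "GCA_000007565.2_ASM756v2_feature_table.txt.gz"),
  refseq = file.path(base, "GCF/000/007/565/GCF_000007565.2_ASM756v2",
                     "GCF_000007565.2_ASM756v2_feature_table.txt.gz")
)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
paths <- vapply(names(urls), function(src) {
  dest <- file.path(opts$out, basename(urls[[src]]))
  if (!file.exists(dest)) {
    message("downloading ", urls[[src]])
    utils::download.file(urls[[src]], dest, mode = "wb", quiet = TRUE)
  }
  dest
}, character(1))

today <- as.character(Sys.Date())
diff <- run_compare(paths[["genbank"]], paths[["refseq"]],
                    file.path(opts$out, "compare"),
                    label_a = "GenBank", label_b = "RefSeq",
                    retrieval_date_a = today, retrieval_date_b = today)
print(diff)
cat("\nProtein-coding totals:\n")
print(jsonlite::read_json(file.path(opts$out, "compare", "summary.json"),
                          simplifyVector = TRUE)[c("counts_a", "counts_b")])

if (!is.null(opts$cog)) {
  enr <- run_enrich(file.path(opts$out, "compare", "diff_records.tsv"),
                    opts$cog, file.path(opts$out, "enrich"))
  print(enr)
}
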