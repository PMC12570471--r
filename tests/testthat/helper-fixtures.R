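# Fixture builders and independent oracles shared across the suite.

toy_annotation <- function(df, source_label = "toy", ...) {
  genome_annotation(tibble::as_tibble(df), source_label = source_label, ...)
}

# one-row feature helper for classify_pair tests
feat <- function(tag, start, end, strand = "+", seq = "chr") {
  tibble::tibble(locus_tag = tag, feature_class = "protein_coding",
                 start = start, end = end, strand = strand,
                 sequence_id = seq)
}

# A 3-row toy NCBI feature table: one protein-coding gene/CDS pair plus one
# rRNA row, written to a temp file.
write_toy_feature_table <- function(path = tempfile(fileext = ".txt")) {
  header <- paste("# feature", "class", "assembly", "assembly_unit",
                  "seq_type", "chromosome", "genomic_accession", "start",
                  "end", "strand", "product_accession",
                  "non-redundant_refseq", "related_accession", "name",
                  "symbol", "GeneID", "locus_tag",
                  "feature_interval_length", "product_length", "attributes",
                  sep = "\t")
  row <- function(feature, class, start, end, strand, name, symbol, tag,
                  attrs = "") {
    paste(feature, class, "GCA_TOY", "Primary Assembly", "chromosome",
          "chr", "TOY_1", start, end, strand, "", "", "", name, symbol, "",
          tag, end - start + 1, "", attrs, sep = "\t")
  }
  writeLines(c(
    header,
    row("gene", "protein_coding", 1, 1371, "+", "", "dnaA", "PP_0001"),
    row("CDS", "with_protein", 1, 1371, "+",
        "chromosomal replication initiator protein DnaA", "dnaA", "PP_0001"),
    row("rRNA", "rRNA", 2000, 2110, "-", "5S ribosomal RNA", "", "PP_r01")
  ), path)
  path
}

write_toy_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Exhaustive hypergeometric upper-tail oracle: direct enumeration of the
# 2x2 tables with fixed margins, summing binomial-coefficient masses.
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c              # in-category genes
  n <- a + b              # shifted genes
  ks <- seq.int(max(0L, n - (N - K)), min(n, K))
  ks <- ks[ks >= a]
  if (length(ks) == 0L) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Independent strand-aware classification oracle: enumerates candidate
# codon start positions of the A gene and checks membership of the B ends.
classify_oracle <- function(a, b) {
  bio_ends <- function(start, end, strand) {
    if (strand == "+") c(start = start, stop = end)
    else c(start = end, stop = start)
  }
  ea <- bio_ends(a$start, a$end, a$strand)
  eb <- bio_ends(b$start, b$end, b$strand)
  dir <- if (a$strand == "+") 1L else -1L
  start_delta <- dir * (eb[["start"]] - ea[["start"]])
  stop_delta <- dir * (eb[["stop"]] - ea[["stop"]])
  same_strand <- a$strand == b$strand
  codon_grid <- function(anchor) anchor + dir * 3L * (-500L:500L)
  frame <- same_strand &&
    eb[["start"]] %in% codon_grid(ea[["start"]]) &&
    eb[["stop"]] %in% codon_grid(ea[["stop"]])
  category <- if (!same_strand) "both_shifted"
  else if (start_delta == 0 && stop_delta == 0) "identical"
  else if (stop_delta == 0) "start_shifted"
  else if (start_delta == 0) "stop_shifted"
  else "both_shifted"
  list(category = category, start_delta = start_delta,
       stop_delta = stop_delta, frame_preserved = frame && same_strand)
}

# Reflect an annotation through genome length L: c -> L - c + 1, strand
# flipped. Used for the strand-invariance property.
reflect_annotation <- function(ann, L) {
  f <- ann$features
  new_start <- L - f$end + 1L
  new_end <- L - f$start + 1L
  f$start <- new_start
  f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  ann$features <- f[order(f$sequence_id, f$start), ]
  ann
}

# Compare a diff against the generator truth ledger; returns a list of
# logical scalars, all of which must be TRUE for exact recovery.
check_recovery <- function(sim, diff, overlaps) {
  truth <- sim$truth
  shared <- truth[!is.na(truth$tag_a) & !is.na(truth$tag_b), ]
  rec <- diff$records
  m <- dplyr::inner_join(shared, rec, by = c("tag_a", "tag_b"),
                         suffix = c("_truth", "_obs"))
  planted_hazards <- sort(truth$tag_a[truth$hazard & !is.na(truth$tag_a)])
  list(
    all_pairs_found = nrow(m) == nrow(shared) && nrow(rec) == nrow(shared),
    classes_match = all(m$class == m$category),
    start_deltas_match = all(m$start_delta_bp_truth == m$start_delta_bp_obs),
    stop_deltas_match = all(m$stop_delta_bp_truth == m$stop_delta_bp_obs),
    frame_flags_match = all(m$frame_preserved_truth == m$frame_preserved_obs),
    exclusives_a_match = setequal(
      diff$pairing$only_a$locus_tag,
      truth$tag_a[truth$class == "exclusive_a" & !is.na(truth$tag_a)]),
    exclusives_b_match = setequal(
      diff$pairing$only_b$locus_tag,
      truth$tag_b[truth$class == "exclusive_b" & !is.na(truth$tag_b)]),
    hazards_match = identical(sort(overlaps$focal_tag[overlaps$hazard]),
                              planted_hazards),
    no_spurious_hazards = sum(overlaps$hazard) ==
      sum(truth$hazard, na.rm = TRUE)
  )
}

truth_cog_assignments <- function(truth) {
  keep <- !is.na(truth$tag_a)
  cog_assignments(
    truth$tag_a[keep],
    vapply(truth$cog_letters[keep], paste, character(1), collapse = "")
  )
}
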