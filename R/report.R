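# Stage orchestrators: each run_* function drives one analysis stage end to
# end, writes the stage's tabular outputs plus a machine-readable
# provenance block, and returns the in-memory result invisibly. A thin
# command-line wrapper over these lives in inst/cli/annodiff.R.

write_provenance <- function(out_dir, inputs, params, extra = list()) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  prov <- c(list(
    tool = "annodiff",
    version = as.character(packageVersion("annodiff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = purrr::imap(inputs, function(path, name) {
      list(path = path, md5 = unname(tools::md5sum(path)))
    }),
    parameters = params
  ), extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

flatten_old_tags <- function(tbl) {
  if ("old_locus_tags" %in% names(tbl)) {
    tbl$old_locus_tags <- vapply(tbl$old_locus_tags, paste, character(1),
                                 collapse = ",")
  }
  tbl
}

#' Compare two annotation files and write the diff outputs
#'
#' Parses both inputs (format sniffed per file), runs [diff_annotations()]
#' and [detect_overlap_changes()], and writes `diff_records.tsv`,
#' `exclusive_a.tsv`, `exclusive_b.tsv`, `conflicts.tsv`,
#' `overlap_changes.tsv`, `summary.json` and `provenance.json` under
#' `out_dir`. The provenance block records input hashes, source labels,
#' accessions and retrieval dates, since rolling re-annotation means an
#' undated accession does not pin an annotation.
#'
#' @param ann_a_path,ann_b_path Annotation files (feature table or GFF3).
#' @param out_dir Output directory (created if needed).
#' @param label_a,label_b Source labels for the two inputs.
#' @param include_pseudo Diff pseudogenes too (default `FALSE`).
#' @param overlap_window Neighborhood radius in bp for overlap-change
#'   detection (default 1000).
#' @param retrieval_date_a,retrieval_date_b Optional ISO dates recording
#'   when each input was obtained.
#' @return The [diff_annotations()] result, with the overlap-change table
#'   attached as `$overlap_changes`, invisibly.
#' @export
run_compare <- function(ann_a_path, ann_b_path, out_dir,
                        label_a = "A", label_b = "B",
                        include_pseudo = FALSE, overlap_window = 1000,
                        retrieval_date_a = NA_character_,
                        retrieval_date_b = NA_character_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann_a <- parse_annotation(ann_a_path, label_a,
                            retrieval_date = retrieval_date_a)
  ann_b <- parse_annotation(ann_b_path, label_b,
                            retrieval_date = retrieval_date_b)

  diff <- diff_annotations(ann_a, ann_b, include_pseudo = include_pseudo)
  keep <- if (include_pseudo) c("protein_coding", "pseudo") else "protein_coding"
  sub <- function(ann) {
    ann$features <- ann$features[ann$features$feature_class %in% keep, ]
    ann
  }
  overlaps <- detect_overlap_changes(sub(ann_a), sub(ann_b), diff$pairing,
                                     window = overlap_window)
  diff$overlap_changes <- overlaps

  readr::write_tsv(diff$records, file.path(out_dir, "diff_records.tsv"),
                   progress = FALSE)
  readr::write_tsv(flatten_old_tags(diff$pairing$only_a),
                   file.path(out_dir, "exclusive_a.tsv"), progress = FALSE)
  readr::write_tsv(flatten_old_tags(diff$pairing$only_b),
                   file.path(out_dir, "exclusive_b.tsv"), progress = FALSE)
  readr::write_tsv(diff$pairing$conflicts,
                   file.path(out_dir, "conflicts.tsv"), progress = FALSE)
  readr::write_tsv(overlaps, file.path(out_dir, "overlap_changes.tsv"),
                   progress = FALSE)
  summary_out <- diff$summary
  summary_out$n_overlap_hazards <- sum(overlaps$hazard)
  summary_out$counts_a <- as.list(annotation_counts(ann_a))
  summary_out$counts_b <- as.list(annotation_counts(ann_b))
  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(
    out_dir,
    inputs = list(ann_a = ann_a_path, ann_b = ann_b_path),
    params = list(include_pseudo = include_pseudo,
                  overlap_window = overlap_window),
    extra = list(sources = list(
      a = list(label = label_a, accession = ann_a$accession,
               retrieval_date = retrieval_date_a),
      b = list(label = label_b, accession = ann_b$accession,
               retrieval_date = retrieval_date_b)))
  )
  invisible(diff)
}

#' Run COG enrichment on a written diff and write its outputs
#'
#' Reads `diff_records.tsv` (as written by [run_compare()]) and a COG
#' assignment TSV, runs [enrich_categories()] and [treemap_table()], and
#' writes `enrichment.tsv`, `treemap.tsv` and `provenance.json`.
#'
#' @param diff_path Path to `diff_records.tsv`.
#' @param cog_path Path to the COG assignment TSV.
#' @param out_dir Output directory.
#' @param level `"supercategory"` or `"letter"`.
#' @return The enrichment tibble, invisibly.
#' @export
run_enrich <- function(diff_path, cog_path, out_dir,
                       level = c("supercategory", "letter")) {
  level <- match.arg(level)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_tsv_quiet(diff_path)
  assignments <- load_cog_assignments(cog_path)
  enr <- enrich_categories(records, assignments, level = level)
  tre <- treemap_table(records, assignments)
  readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(tre, file.path(out_dir, "treemap.tsv"), progress = FALSE)
  write_provenance(
    out_dir,
    inputs = list(diff = diff_path, cog = cog_path),
    params = list(level = level),
    extra = list(excluded_no_cog = list(
      shifted = attr(enr, "n_shifted_no_cog"),
      unshifted = attr(enr, "n_unshifted_no_cog")))
  )
  invisible(enr)
}

#' Compare paired DE tables across references and write the outputs
#'
#' Rebuilds the locus join from a written `diff_records.tsv`, runs
#' [compare_expression()] and [concordance_stats()], and writes
#' `expression_concordance.tsv`, `flagged.tsv`, `unjoined.tsv`,
#' `concordance_summary.json` and `provenance.json`.
#'
#' @param table_a_path,table_b_path DE result tables (TSV/CSV) keyed in the
#'   A and B annotation namespaces.
#' @param diff_path Path to `diff_records.tsv` from [run_compare()].
#' @param out_dir Output directory.
#' @param lfc_threshold Absolute log2FC difference flagging threshold.
#' @param alpha Significance level for status flips.
#' @param gene_col,lfc_col,padj_col Column names in the DE tables.
#' @return The [compare_expression()] report, invisibly.
#' @export
run_expr_compare <- function(table_a_path, table_b_path, diff_path, out_dir,
                             lfc_threshold = 2.5, alpha = 0.05,
                             gene_col = "gene_id",
                             lfc_col = "log2FoldChange", padj_col = "padj") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_tsv_quiet(diff_path)
  pairing <- structure(
    list(pairs = tibble::tibble(tag_a = records$tag_a, tag_b = records$tag_b,
                                match_basis = records$match_basis %||%
                                  NA_character_),
         only_a = empty_features(), only_b = empty_features(),
         conflicts = tibble::tibble()),
    class = "locus_pairing"
  )
  table_a <- load_de_table(table_a_path, gene_col, lfc_col, padj_col)
  table_b <- load_de_table(table_b_path, gene_col, lfc_col, padj_col)
  rep <- compare_expression(table_a, table_b, pairing, records,
                            threshold = lfc_threshold, alpha = alpha)
  readr::write_tsv(rep$records,
                   file.path(out_dir, "expression_concordance.tsv"),
                   progress = FALSE)
  flagged <- dplyr::bind_rows(
    dplyr::mutate(rep$flagged_effect, flag = "effect"),
    dplyr::mutate(rep$flagged_status, flag = "status")
  )
  readr::write_tsv(flagged, file.path(out_dir, "flagged.tsv"),
                   progress = FALSE)
  readr::write_tsv(rep$unjoined, file.path(out_dir, "unjoined.tsv"),
                   progress = FALSE)
  stats_tbl <- concordance_stats(rep$records)
  jsonlite::write_json(
    list(groups = stats_tbl, summary = rep$summary,
         n_flagged_effect = nrow(rep$flagged_effect),
         n_flagged_status = nrow(rep$flagged_status)),
    file.path(out_dir, "concordance_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  write_provenance(
    out_dir,
    inputs = list(table_a = table_a_path, table_b = table_b_path,
                  diff = diff_path),
    params = list(lfc_threshold = lfc_threshold, alpha = alpha)
  )
  invisible(rep)
}

#' Generate a synthetic data set on disk
#'
#' Runs [generate_annotation_pair()] and [simulate_de_tables()] and writes
#' the pair in both formats the parsers read (feature-table dialect and
#' GFF3), the truth ledger, the two DE tables, the configuration used and a
#' provenance block.
#'
#' @param cfg A [simulation_config()]; `seed` overrides its seed if given.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return The [generate_annotation_pair()] result, invisibly.
#' @export
run_simulate <- function(cfg = simulation_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_annotation_pair(cfg)
  de <- simulate_de_tables(sim)

  write_feature_table(sim$ann_a,
                      file.path(out_dir, "ann_a_feature_table.txt"))
  write_feature_table(sim$ann_b,
                      file.path(out_dir, "ann_b_feature_table.txt"))
  write_annotation(sim$ann_a, file.path(out_dir, "ann_a.gff3"), "gff3")
  write_annotation(sim$ann_b, file.path(out_dir, "ann_b.gff3"), "gff3")

  truth_flat <- de$truth
  truth_flat$cog_letters <- vapply(truth_flat$cog_letters, paste,
                                   character(1), collapse = "")
  readr::write_tsv(truth_flat, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  cog_tbl <- truth_flat[!is.na(truth_flat$tag_a),
                        c("tag_a", "cog_letters")]
  names(cog_tbl) <- c("locus_tag", "cog_letters")
  readr::write_tsv(cog_tbl, file.path(out_dir, "cog_assignments.tsv"),
                   progress = FALSE)
  readr::write_tsv(de$table_a, file.path(out_dir, "de_table_a.tsv"),
                   progress = FALSE)
  readr::write_tsv(de$table_b, file.path(out_dir, "de_table_b.tsv"),
                   progress = FALSE)

  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  write_provenance(out_dir, inputs = list(),
                   params = list(seed = cfg$seed, n_genes = cfg$n_genes))
  sim$de <- de
  invisible(sim)
}
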