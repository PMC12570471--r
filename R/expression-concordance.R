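# Paired differential-expression concordance across the two references.
# The DE computation itself (trimming, quantification, negative-binomial
# testing) is upstream of this package; these functions consume the tabular
# results it produces against either annotation.

#' Load a differential-expression result table
#'
#' Reads a TSV or CSV (sniffed from the first line) with one row per gene.
#' Column names are configurable; the defaults match common DE output
#' (`gene_id`, `log2FoldChange`, `padj`). Rows with non-finite log2FC or
#' adjusted p are kept with `NA` markers so joins stay complete.
#'
#' @param path Path to the table.
#' @param gene_col,lfc_col,padj_col Column names to use.
#' @return Tibble with `locus_tag`, `log2fc`, `padj`.
#' @export
load_de_table <- function(path, gene_col = "gene_id",
                          lfc_col = "log2FoldChange", padj_col = "padj") {
  raw <- readr::read_delim(path, delim = sniff_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(gene_col, lfc_col, padj_col), names(raw))
  if (length(missing) > 0L) {
    stop_annodiff("DE table %s lacks expected column(s): %s", path,
                  paste(missing, collapse = ", "))
  }
  dup <- unique(raw[[gene_col]][duplicated(raw[[gene_col]])])
  if (length(dup) > 0L) {
    stop_annodiff("duplicated gene id(s) in %s: %s", path,
                  paste(head(dup, 10L), collapse = ", "))
  }
  lfc <- as.numeric(raw[[lfc_col]])
  padj <- as.numeric(raw[[padj_col]])
  tibble::tibble(
    locus_tag = as.character(raw[[gene_col]]),
    log2fc = ifelse(is.finite(lfc), lfc, NA_real_),
    padj = ifelse(is.finite(padj), padj, NA_real_)
  )
}

#' Compare paired differential-expression results across two references
#'
#' Joins the two DE tables through the locus pairing (each table is keyed
#' in its own annotation's namespace), attaches the shifted/unshifted label
#' from the diff records, and flags genes whose result depends on the
#' reference: `flagged_effect` collects genes with
#' `|log2fc_a - log2fc_b| > threshold`, and `flagged_status` genes called
#' significant (adjusted p <= `alpha`) under exactly one reference. A
#' missing adjusted p is treated as not significant.
#'
#' @param table_a,table_b Tibbles from [load_de_table()], keyed in the A and
#'   B namespaces respectively.
#' @param pairing A [pair_loci()] result supplying the join.
#' @param records Diff records from [diff_annotations()] (for the shifted
#'   label); pass `NULL` to leave `shifted` as `NA`.
#' @param threshold Absolute log2FC difference above which a gene is
#'   flagged (default 2.5).
#' @param alpha Significance level for the status comparison (default 0.05).
#' @return An object of class `discordance_report`: list with `records`
#'   (tibble: `tag_a`, `tag_b`, `log2fc_a`, `log2fc_b`, `padj_a`, `padj_b`,
#'   `shifted`, `delta_lfc`, `sig_a`, `sig_b`), `flagged_effect`,
#'   `flagged_status`, `unjoined` (loci present in only one table or
#'   unpaired), `threshold`, `alpha` and `summary` (per-group count,
#'   median and max `delta_lfc`).
#' @export
compare_expression <- function(table_a, table_b, pairing, records = NULL,
                               threshold = 2.5, alpha = 0.05) {
  stopifnot(inherits(pairing, "locus_pairing"), threshold > 0,
            alpha > 0, alpha < 1)
  table_a <- normalize_de_table(table_a)
  table_b <- normalize_de_table(table_b)
  p <- pairing$pairs
  ia <- match(p$tag_a, table_a$locus_tag)
  ib <- match(p$tag_b, table_b$locus_tag)
  joined <- !is.na(ia) & !is.na(ib)
  if (!any(joined)) stop_annodiff("no paired locus occurs in both DE tables")

  shifted <- if (is.null(records)) {
    rep(NA, nrow(p))
  } else {
    (records$category != "identical")[match(p$tag_a, records$tag_a)]
  }
  rec <- tibble::tibble(
    tag_a = p$tag_a[joined],
    tag_b = p$tag_b[joined],
    log2fc_a = table_a$log2fc[ia[joined]],
    log2fc_b = table_b$log2fc[ib[joined]],
    padj_a = table_a$padj[ia[joined]],
    padj_b = table_b$padj[ib[joined]],
    shifted = shifted[joined]
  )
  rec$delta_lfc <- abs(rec$log2fc_a - rec$log2fc_b)
  rec$sig_a <- !is.na(rec$padj_a) & rec$padj_a <= alpha
  rec$sig_b <- !is.na(rec$padj_b) & rec$padj_b <= alpha

  unjoined <- dplyr::bind_rows(
    tibble::tibble(locus_tag = p$tag_a[!joined], namespace = "A",
                   reason = as.character(ifelse(is.na(ia[!joined]),
                                                "absent_from_table_a",
                                                "absent_from_table_b"))),
    tibble::tibble(locus_tag = setdiff(table_a$locus_tag, p$tag_a),
                   namespace = "A", reason = "unpaired_locus"),
    tibble::tibble(locus_tag = setdiff(table_b$locus_tag, p$tag_b),
                   namespace = "B", reason = "unpaired_locus")
  )

  grp_summary <- rec |>
    dplyr::mutate(group = dplyr::case_when(
      is.na(.data$shifted) ~ "unknown",
      .data$shifted ~ "shifted",
      TRUE ~ "unshifted")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_delta_lfc = median(.data$delta_lfc, na.rm = TRUE),
      max_delta_lfc = max(c(.data$delta_lfc, -Inf), na.rm = TRUE),
      n_flagged_effect = sum(.data$delta_lfc > threshold, na.rm = TRUE),
      .groups = "drop"
    )

  structure(
    list(
      records = rec,
      flagged_effect = rec[!is.na(rec$delta_lfc) & rec$delta_lfc > threshold, ],
      flagged_status = rec[xor(rec$sig_a, rec$sig_b), ],
      unjoined = unjoined,
      threshold = threshold,
      alpha = alpha,
      summary = grp_summary
    ),
    class = "discordance_report"
  )
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf(
    "<discordance_report> %d paired loci; %d flagged by effect (|dLFC| > %g), %d by status (alpha %g)\n",
    nrow(x$records), nrow(x$flagged_effect), x$threshold,
    nrow(x$flagged_status), x$alpha))
  print(x$summary)
  invisible(x)
}

#' Concordance statistics of paired log2 fold changes
#'
#' Per group (shifted / unshifted / unknown): Pearson and Spearman
#' correlation of `(log2fc_a, log2fc_b)`, and the median and 95th percentile
#' of `delta_lfc`. Correlations are `NA` when a group has zero variance on
#' either axis or fewer than 3 complete observations.
#'
#' @param records The `records` tibble of a [compare_expression()] report.
#' @return Tibble with one row per group.
#' @export
concordance_stats <- function(records) {
  if (nrow(records) < 3L) {
    stop_annodiff("need at least 3 paired records, got %d", nrow(records))
  }
  records |>
    dplyr::mutate(group = dplyr::case_when(
      is.na(.data$shifted) ~ "unknown",
      .data$shifted ~ "shifted",
      TRUE ~ "unshifted")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      pearson = safe_cor(.data$log2fc_a, .data$log2fc_b, "pearson"),
      spearman = safe_cor(.data$log2fc_a, .data$log2fc_b, "spearman"),
      median_delta_lfc = median(.data$delta_lfc, na.rm = TRUE),
      q95_delta_lfc = quantile(.data$delta_lfc, 0.95, na.rm = TRUE,
                               names = FALSE),
      .groups = "drop"
    )
}

# accept either the internal (locus_tag/log2fc/padj) or the DESeq2-style
# (gene_id/log2FoldChange/padj) column names
normalize_de_table <- function(tbl) {
  ren <- c(locus_tag = "gene_id", log2fc = "log2FoldChange")
  for (want in names(ren)) {
    if (!want %in% names(tbl) && ren[[want]] %in% names(tbl)) {
      names(tbl)[names(tbl) == ren[[want]]] <- want
    }
  }
  missing <- setdiff(c("locus_tag", "log2fc", "padj"), names(tbl))
  if (length(missing) > 0L) {
    stop_annodiff("DE table lacks column(s): %s",
                  paste(missing, collapse = ", "))
  }
  tbl
}

safe_cor <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = method)
}
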