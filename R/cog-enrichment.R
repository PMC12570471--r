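# COG functional categories and overrepresentation testing.

#' COG single-letter categories and their functional supercategories
#'
#' The fixed lookup relating the 26 single-letter COG functional categories
#' to their four supercategories (cellular processes and signaling;
#' information storage and processing; metabolism; poorly characterized),
#' with the standard category descriptions.
#'
#' @return Tibble with `letter`, `supercategory`, `description`.
#' @export
cog_categories <- function() {
  tibble::tribble(
    ~letter, ~supercategory, ~description,
    "J", "information_storage_and_processing", "Translation, ribosomal structure and biogenesis",
    "A", "information_storage_and_processing", "RNA processing and modification",
    "K", "information_storage_and_processing", "Transcription",
    "L", "information_storage_and_processing", "Replication, recombination and repair",
    "B", "information_storage_and_processing", "Chromatin structure and dynamics",
    "D", "cellular_processes_and_signaling", "Cell cycle control, cell division, chromosome partitioning",
    "Y", "cellular_processes_and_signaling", "Nuclear structure",
    "V", "cellular_processes_and_signaling", "Defense mechanisms",
    "T", "cellular_processes_and_signaling", "Signal transduction mechanisms",
    "M", "cellular_processes_and_signaling", "Cell wall/membrane/envelope biogenesis",
    "N", "cellular_processes_and_signaling", "Cell motility",
    "Z", "cellular_processes_and_signaling", "Cytoskeleton",
    "W", "cellular_processes_and_signaling", "Extracellular structures",
    "U", "cellular_processes_and_signaling", "Intracellular trafficking, secretion, and vesicular transport",
    "O", "cellular_processes_and_signaling", "Posttranslational modification, protein turnover, chaperones",
    "X", "cellular_processes_and_signaling", "Mobilome: prophages, transposons",
    "C", "metabolism", "Energy production and conversion",
    "G", "metabolism", "Carbohydrate transport and metabolism",
    "E", "metabolism", "Amino acid transport and metabolism",
    "F", "metabolism", "Nucleotide transport and metabolism",
    "H", "metabolism", "Coenzyme transport and metabolism",
    "I", "metabolism", "Lipid transport and metabolism",
    "P", "metabolism", "Inorganic ion transport and metabolism",
    "Q", "metabolism", "Secondary metabolites biosynthesis, transport and catabolism",
    "R", "poorly_characterized", "General function prediction only",
    "S", "poorly_characterized", "Function unknown"
  )
}

COG_SUPERCATEGORIES <- c("cellular_processes_and_signaling",
                         "information_storage_and_processing",
                         "metabolism", "poorly_characterized")

#' Load per-locus COG assignments from a TSV file
#'
#' Expects columns `locus_tag` and `cog_letters` (a string of single-letter
#' categories, e.g. `"KT"`; empty or missing means no assignment). Letters
#' are mapped to supercategories through [cog_categories()]. A letter
#' outside the fixed alphabet is kept verbatim, mapped to no supercategory,
#' and reported with a warning.
#'
#' @param path Path to the TSV.
#' @return Tibble with `locus_tag`, `cog_letters` (list of character
#'   vectors), `supercategories` (list of distinct supercategories) and
#'   `unassigned` (`TRUE` when no letters).
#' @export
load_cog_assignments <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!all(c("locus_tag", "cog_letters") %in% names(raw))) {
    stop_annodiff("COG table %s must have columns locus_tag and cog_letters",
                  path)
  }
  dup <- unique(raw$locus_tag[duplicated(raw$locus_tag)])
  if (length(dup) > 0L) {
    stop_annodiff("duplicate locus_tag(s) in COG table: %s",
                  paste(head(dup, 10L), collapse = ", "))
  }
  cog_assignments(raw$locus_tag, raw$cog_letters)
}

#' Build a COG assignment table from vectors
#'
#' @param locus_tag Character vector of locus tags.
#' @param letters Character vector of letter strings (`"DU"` etc.), `NA` or
#'   `""` for unassigned loci.
#' @return Same shape as [load_cog_assignments()].
#' @export
cog_assignments <- function(locus_tag, letters) {
  map <- cog_categories()
  letter_list <- purrr::map(letters, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else unique(strsplit(s, "")[[1L]])
  })
  unknown <- setdiff(unique(unlist(letter_list)), map$letter)
  if (length(unknown) > 0L) {
    warning(sprintf("unknown COG letter(s) kept without supercategory: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    locus_tag = as.character(locus_tag),
    cog_letters = letter_list,
    supercategories = purrr::map(letter_list, function(l) {
      unique(map$supercategory[match(l, map$letter)][
        !is.na(match(l, map$letter))])
    }),
    unassigned = lengths(letter_list) == 0L
  )
}

#' One-tailed (upper) Fisher's exact test for a 2x2 table
#'
#' Tests overrepresentation in the cell `a` of the table
#' \preformatted{          in category   not in category
#'   shifted        a             b
#'   unshifted      c             d}
#' The p-value is the upper hypergeometric tail
#' \eqn{p = \sum_{k \ge a} P(k \mid a+b, c+d, a+c)} and the odds ratio is
#' the sample estimate \eqn{(ad)/(bc)} (`Inf` when `b*c == 0` and the
#' numerator is positive). Degenerate margins give `p = 1`.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @return Tibble with columns `odds_ratio` and `p`.
#' @export
#' @examples
#' fisher_one_tailed_greater(1, 0, 0, 1)  # p = 0.5
fisher_one_tailed_greater <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_annodiff("cell counts must be non-negative integers")
  }
  # draw a+b genes from a+c in-category and b+d out-of-category; upper tail
  p <- phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
  or <- (a * d) / (b * c)  # Inf when b*c == 0 and ad > 0; NaN on 0/0
  tibble::tibble(odds_ratio = as.numeric(or), p = pmin(1, as.numeric(p)))
}

#' Test COG categories for overrepresentation among shifted genes
#'
#' Splits paired loci into the shifted set (diff category other than
#' `identical`) and the unshifted background, drops loci without COG
#' assignments from both, and runs [fisher_one_tailed_greater()] per
#' category. A gene with several letters counts as a member of each letter
#' at `level = "letter"` and of each distinct supercategory at
#' `level = "supercategory"`. No multiple-testing correction is applied to
#' `p`; a Bonferroni column is emitted alongside for transparency.
#'
#' @param records Diff records from [diff_annotations()] (needs `tag_a` and
#'   `category`).
#' @param assignments COG assignments from [load_cog_assignments()] /
#'   [cog_assignments()], keyed in the A-annotation namespace.
#' @param level `"supercategory"` (default) or `"letter"`.
#' @return Tibble sorted by `p` with `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `p_bonferroni`; attributes `n_shifted_no_cog`,
#'   `n_unshifted_no_cog` count loci excluded for lacking assignments.
#' @export
enrich_categories <- function(records, assignments,
                              level = c("supercategory", "letter")) {
  level <- match.arg(level)
  memb_col <- if (level == "supercategory") "supercategories" else "cog_letters"

  idx <- match(records$tag_a, assignments$locus_tag)
  memb <- assignments[[memb_col]][idx]
  memb[is.na(idx)] <- list(character(0))
  has_cog <- lengths(memb) > 0L
  shifted <- records$category != "identical"

  n_shift <- sum(shifted & has_cog)
  n_back <- sum(!shifted & has_cog)
  if (n_shift == 0L || n_back == 0L) {
    stop_annodiff(
      "enrichment undefined: %d shifted and %d unshifted loci carry COG annotations",
      n_shift, n_back)
  }

  cats <- sort(unique(unlist(memb[has_cog])))
  in_cat <- vapply(cats, function(cat) {
    vapply(memb, function(m) cat %in% m, logical(1))
  }, logical(length(memb)))
  a <- colSums(in_cat & shifted & has_cog)
  c_ <- colSums(in_cat & !shifted & has_cog)
  b <- n_shift - a
  d <- n_back - c_
  res <- fisher_one_tailed_greater(a, b, c_, d)
  out <- tibble::tibble(
    category = cats, a = as.integer(a), b = as.integer(b),
    c = as.integer(c_), d = as.integer(d),
    odds_ratio = res$odds_ratio, p = res$p,
    p_bonferroni = pmin(1, res$p * length(cats))
  )
  out <- out[order(out$p, out$category), ]
  attr(out, "n_shifted_no_cog") <- sum(shifted & !has_cog)
  attr(out, "n_unshifted_no_cog") <- sum(!shifted & !has_cog)
  out
}

#' Aggregate shifted genes into a treemap-ready table
#'
#' One row per (supercategory, COG category description) with the number of
#' shifted genes carrying that letter; a gene with several letters
#' contributes to each of its rows, so counts sum to the number of
#' (gene, letter) incidences. The TSV written from this table can be fed to
#' any treemap renderer.
#'
#' @param shifted_records Diff records restricted to, or filterable to,
#'   shifted pairs (rows with `category == "identical"` are dropped here).
#' @param assignments COG assignments keyed in the A namespace.
#' @return Tibble with `supercategory`, `letter`, `description`, `n_genes`.
#' @export
treemap_table <- function(shifted_records, assignments) {
  shifted <- shifted_records[shifted_records$category != "identical", ]
  idx <- match(shifted$tag_a, assignments$locus_tag)
  letters <- assignments$cog_letters[idx]
  letters[is.na(idx)] <- list(character(0))
  incidence <- tibble::tibble(
    locus_tag = rep(shifted$tag_a, lengths(letters)),
    letter = unlist(letters)
  )
  map <- cog_categories()
  incidence |>
    dplyr::count(.data$letter, name = "n_genes") |>
    dplyr::left_join(map, by = "letter") |>
    dplyr::mutate(
      supercategory = dplyr::coalesce(.data$supercategory, "unassigned"),
      description = dplyr::coalesce(.data$description, .data$letter)
    ) |>
    dplyr::arrange(.data$supercategory, dplyr::desc(.data$n_genes)) |>
    dplyr::select("supercategory", "letter", "description", "n_genes")
}
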