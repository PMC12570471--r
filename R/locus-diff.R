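# Locus pairing and strand-aware shift classification.
#
# All deltas are "biological": the start of a minus-strand gene is its
# higher genomic coordinate, and a positive delta means the position moved
# downstream (in the direction of translation) in annotation B relative to
# annotation A. Raw genomic deltas are kept alongside for plotting.

#' Pair loci between two annotations via locus tags
#'
#' A pair is formed when the two features carry string-identical locus tags,
#' or when either feature lists the other's locus tag among its
#' `old_locus_tags` (the cross-reference PGAP writes when it re-annotates a
#' record, e.g. PP_RS00005 carrying old_locus_tag PP_0001). Matching is
#' symmetric and deterministic. Tags claimed by more than one counterpart
#' are never paired silently: all such edges are surfaced in `conflicts` and
#' the features involved fall back to the exclusive lists.
#'
#' @param ann_a,ann_b [genome_annotation()] objects, normally already
#'   filtered with [protein_coding_subset()].
#' @return An object of class `locus_pairing`: a list with
#'   * `pairs` — tibble with `tag_a`, `tag_b`, `match_basis`
#'     (`"old_locus_tag"` or `"identical_tag"`), ordered by A coordinate;
#'   * `only_a`, `only_b` — feature tibbles with no counterpart;
#'   * `conflicts` — tibble of ambiguous candidate edges.
#' @export
pair_loci <- function(ann_a, ann_b) {
  stopifnot(inherits(ann_a, "genome_annotation"),
            inherits(ann_b, "genome_annotation"))
  fa <- ann_a$features
  fb <- ann_b$features

  e_old_b <- tibble::tibble(
    tag_a = unlist(fb$old_locus_tags),
    tag_b = rep(fb$locus_tag, lengths(fb$old_locus_tags)),
    match_basis = "old_locus_tag"
  )
  e_old_a <- tibble::tibble(
    tag_a = rep(fa$locus_tag, lengths(fa$old_locus_tags)),
    tag_b = unlist(fa$old_locus_tags),
    match_basis = "old_locus_tag"
  )
  e_ident <- tibble::tibble(
    tag_a = intersect(fa$locus_tag, fb$locus_tag),
    tag_b = intersect(fa$locus_tag, fb$locus_tag),
    match_basis = "identical_tag"
  )
  edges <- dplyr::bind_rows(e_old_b, e_old_a, e_ident)
  edges <- edges[edges$tag_a %in% fa$locus_tag &
                   edges$tag_b %in% fb$locus_tag, ]
  edges <- dplyr::distinct(edges, .data$tag_a, .data$tag_b,
                           .keep_all = TRUE)

  deg_a <- table(edges$tag_a)
  deg_b <- table(edges$tag_b)
  unique_edge <- deg_a[edges$tag_a] == 1L & deg_b[edges$tag_b] == 1L
  pairs <- edges[unique_edge, ]
  conflicts <- edges[!unique_edge, ]

  ord <- order(match(pairs$tag_a, fa$locus_tag))
  pairs <- pairs[ord, ]
  pos_a <- fa[match(pairs$tag_a, fa$locus_tag), c("sequence_id", "start")]
  pairs <- pairs[order(pos_a$sequence_id, pos_a$start, pairs$tag_a), ]

  structure(
    list(
      pairs = pairs,
      only_a = fa[!fa$locus_tag %in% pairs$tag_a, ],
      only_b = fb[!fb$locus_tag %in% pairs$tag_b, ],
      conflicts = conflicts
    ),
    class = "locus_pairing"
  )
}

#' @export
print.locus_pairing <- function(x, ...) {
  cat(sprintf(
    "<locus_pairing> %d pairs, %d only in A, %d only in B, %d conflict edges\n",
    nrow(x$pairs), nrow(x$only_a), nrow(x$only_b), nrow(x$conflicts)))
  invisible(x)
}

#' Convert a locus tag to its counterpart in the other annotation
#'
#' @param tag Character vector of locus tags.
#' @param pairing A [pair_loci()] result.
#' @param direction `"a_to_b"` or `"b_to_a"`.
#' @return Character vector of counterpart tags; `NA` marks tags with no
#'   counterpart (never an empty string).
#' @export
convert_locus_tag <- function(tag, pairing, direction = c("a_to_b", "b_to_a")) {
  stopifnot(inherits(pairing, "locus_pairing"))
  direction <- match.arg(direction)
  from <- if (direction == "a_to_b") pairing$pairs$tag_a else pairing$pairs$tag_b
  to <- if (direction == "a_to_b") pairing$pairs$tag_b else pairing$pairs$tag_a
  amb <- intersect(tag, from[duplicated(from)])
  if (length(amb) > 0L) {
    stop_annodiff("ambiguous mapping for tag(s): %s",
                  paste(amb, collapse = ", "))
  }
  unname(to[match(tag, from)])
}

#' Classify the coordinate differences of one matched locus pair
#'
#' Deltas are computed in biological orientation: for a plus-strand gene the
#' start is its `start` coordinate, for a minus-strand gene its `end`
#' coordinate (and conversely for the stop). Positive deltas point
#' downstream in B relative to A. A pair is `frame_preserved` when both
#' features share a strand and both deltas are multiples of 3, i.e. the
#' re-annotation moved codon boundaries without changing the reading frame.
#' A strand mismatch yields `strand_consistent = FALSE`, category
#' `both_shifted` and `frame_preserved = FALSE`.
#'
#' @param a,b Single features: one-row data frames (or lists) with `start`,
#'   `end`, `strand` and `locus_tag`.
#' @return A one-row tibble with `tag_a`, `tag_b`, `category` (one of
#'   `identical`, `start_shifted`, `stop_shifted`, `both_shifted`),
#'   `start_delta_bp`, `stop_delta_bp`, `length_delta_bp`,
#'   `genomic_start_delta_bp`, `genomic_end_delta_bp`, `frame_preserved`,
#'   `strand_consistent`.
#' @export
classify_pair <- function(a, b) {
  classify_pairs_impl(
    tibble::tibble(tag_a = a$locus_tag, start_a = as.integer(a$start),
                   end_a = as.integer(a$end), strand_a = a$strand),
    tibble::tibble(tag_b = b$locus_tag, start_b = as.integer(b$start),
                   end_b = as.integer(b$end), strand_b = b$strand)
  )
}

# vectorized core shared by classify_pair and diff_annotations
classify_pairs_impl <- function(da, db) {
  stopifnot(nrow(da) == nrow(db))
  x <- dplyr::bind_cols(da, db)
  plus <- x$strand_a == "+"
  start_delta <- ifelse(plus, x$start_b - x$start_a, x$end_a - x$end_b)
  stop_delta <- ifelse(plus, x$end_b - x$end_a, x$start_a - x$start_b)
  strand_ok <- x$strand_a == x$strand_b
  category <- dplyr::case_when(
    !strand_ok ~ "both_shifted",
    start_delta == 0L & stop_delta == 0L ~ "identical",
    start_delta != 0L & stop_delta == 0L ~ "start_shifted",
    start_delta == 0L & stop_delta != 0L ~ "stop_shifted",
    TRUE ~ "both_shifted"
  )
  tibble::tibble(
    tag_a = x$tag_a,
    tag_b = x$tag_b,
    category = category,
    start_delta_bp = as.integer(start_delta),
    stop_delta_bp = as.integer(stop_delta),
    length_delta_bp = as.integer((x$end_b - x$start_b) - (x$end_a - x$start_a)),
    genomic_start_delta_bp = as.integer(x$start_b - x$start_a),
    genomic_end_delta_bp = as.integer(x$end_b - x$end_a),
    frame_preserved = strand_ok & start_delta %% 3L == 0L &
      stop_delta %% 3L == 0L,
    strand_consistent = strand_ok
  )
}

#' Diff two genome annotations
#'
#' Runs [pair_loci()] on the protein-coding subsets, classifies every pair
#' with the strand-aware rules of [classify_pair()], and summarizes the
#' partition (shared-identical / shifted / exclusive to either source).
#'
#' Because published tallies differ in whether a gene shifted at both ends
#' counts once or twice, the summary reports start/stop shifts under both
#' conventions: `n_start_shifted_any` counts every pair whose start moved
#' (regardless of the stop), while `n_start_shifted_only` counts pairs in
#' the exclusive `start_shifted` category (likewise for stops).
#'
#' @param ann_a,ann_b [genome_annotation()] objects.
#' @param include_pseudo Also diff pseudogenes (default `FALSE`: the
#'   comparison concerns protein-coding gene models).
#' @return An object of class `annotation_diff`: list with `pairing`
#'   ([pair_loci()] result), `records` (tibble of per-pair classifications,
#'   sorted by A coordinate) and `summary` (list; see Details).
#' @details `summary` carries `n_pairs`, `n_identical`, `n_shifted`,
#'   `n_start_shifted_any`, `n_stop_shifted_any`, `n_start_shifted_only`,
#'   `n_stop_shifted_only`, `n_both_shifted`, `n_only_a`, `n_only_b`,
#'   `n_conflicts`, `n_frame_broken`, `frame_broken_tags`, and
#'   `shift_magnitudes` (absolute bp offsets, start and stop pooled over
#'   non-zero values).
#' @export
diff_annotations <- function(ann_a, ann_b, include_pseudo = FALSE) {
  keep <- if (include_pseudo) c("protein_coding", "pseudo") else "protein_coding"
  sub_a <- ann_a
  sub_a$features <- sub_a$features[sub_a$features$feature_class %in% keep, ]
  sub_b <- ann_b
  sub_b$features <- sub_b$features[sub_b$features$feature_class %in% keep, ]

  pairing <- pair_loci(sub_a, sub_b)
  fa <- sub_a$features
  fb <- sub_b$features
  ia <- match(pairing$pairs$tag_a, fa$locus_tag)
  ib <- match(pairing$pairs$tag_b, fb$locus_tag)
  records <- classify_pairs_impl(
    tibble::tibble(tag_a = fa$locus_tag[ia], start_a = fa$start[ia],
                   end_a = fa$end[ia], strand_a = fa$strand[ia]),
    tibble::tibble(tag_b = fb$locus_tag[ib], start_b = fb$start[ib],
                   end_b = fb$end[ib], strand_b = fb$strand[ib])
  )
  records$match_basis <- pairing$pairs$match_basis

  shifted <- records$category != "identical"
  mags <- c(abs(records$start_delta_bp), abs(records$stop_delta_bp))
  summary <- list(
    n_pairs = nrow(records),
    n_identical = sum(!shifted),
    n_shifted = sum(shifted),
    n_start_shifted_any = sum(records$start_delta_bp != 0L |
                                !records$strand_consistent),
    n_stop_shifted_any = sum(records$stop_delta_bp != 0L |
                               !records$strand_consistent),
    n_start_shifted_only = sum(records$category == "start_shifted"),
    n_stop_shifted_only = sum(records$category == "stop_shifted"),
    n_both_shifted = sum(records$category == "both_shifted"),
    n_only_a = nrow(pairing$only_a),
    n_only_b = nrow(pairing$only_b),
    n_conflicts = nrow(pairing$conflicts),
    n_frame_broken = sum(!records$frame_preserved),
    frame_broken_tags = records$tag_a[!records$frame_preserved],
    shift_magnitudes = mags[mags > 0L]
  )
  structure(list(pairing = pairing, records = records, summary = summary),
            class = "annotation_diff")
}

#' @export
print.annotation_diff <- function(x, ...) {
  s <- x$summary
  cat("<annotation_diff>\n")
  cat(sprintf("  pairs: %d (identical %d, shifted %d)\n",
              s$n_pairs, s$n_identical, s$n_shifted))
  cat(sprintf("  start shifted: %d any / %d only; stop shifted: %d any / %d only; both: %d\n",
              s$n_start_shifted_any, s$n_start_shifted_only,
              s$n_stop_shifted_any, s$n_stop_shifted_only, s$n_both_shifted))
  cat(sprintf("  exclusive: %d only in A, %d only in B; conflicts: %d\n",
              s$n_only_a, s$n_only_b, s$n_conflicts))
  cat(sprintf("  frame broken: %d%s\n", s$n_frame_broken,
              if (s$n_frame_broken > 0L && s$n_frame_broken <= 10L)
                paste0(" (", paste(s$frame_broken_tags, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Detect gene pairs whose overlap status flips between annotations
#'
#' For every paired focal gene, computes the genomic-interval overlap with
#' each neighboring paired gene within `window` bp in both annotations. A
#' record is a *hazard* when the two genes overlap in exactly one
#' annotation: a deletion designed to be internal to the focal gene in one
#' reference may then unintentionally truncate its neighbor in the other.
#' Overlap is computed on genomic intervals regardless of strand, since a
#' deletion removes DNA from both strands.
#'
#' @param ann_a,ann_b [genome_annotation()] objects.
#' @param pairing A [pair_loci()] result for the two annotations.
#' @param window Neighborhood radius in bp around the focal gene in
#'   annotation A (default 1000).
#' @param include_size_changes Also emit records where both annotations
#'   overlap but by different amounts (default `FALSE`: only status flips).
#' @return Tibble with `focal_tag`, `neighbor_tag` (A-side tags),
#'   `focal_tag_b`, `neighbor_tag_b`, `overlap_a_bp`, `overlap_b_bp`,
#'   `gap_a_bp`, `gap_b_bp` (negative gap = overlap) and `hazard`. Each
#'   unordered gene pair appears once, the focal gene being the one starting
#'   first in A.
#' @export
detect_overlap_changes <- function(ann_a, ann_b, pairing, window = 1000,
                                   include_size_changes = FALSE) {
  stopifnot(inherits(pairing, "locus_pairing"), window >= 0)
  fa <- ann_a$features
  fb <- ann_b$features
  p <- pairing$pairs
  ia <- match(p$tag_a, fa$locus_tag)
  ib <- match(p$tag_b, fb$locus_tag)
  keep <- !is.na(ia) & !is.na(ib)
  p <- p[keep, ]
  ia <- ia[keep]
  ib <- ib[keep]
  if (nrow(p) < 2L) return(empty_overlap_tbl())

  # candidate neighbor pairs from either annotation's geometry: a pair
  # overlapping only in B may sit outside the window in A, and vice versa
  neighbor_pairs <- function(f, idx) {
    ir <- IRanges::IRanges(start = f$start[idx], end = f$end[idx])
    hits <- IRanges::findOverlaps(ir, maxgap = as.integer(window),
                                  drop.self = TRUE, drop.redundant = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same_seq <- f$sequence_id[idx][qh] == f$sequence_id[idx][sh]
    cbind(pmin(qh, sh), pmax(qh, sh))[same_seq, , drop = FALSE]
  }
  cand <- unique(rbind(neighbor_pairs(fa, ia), neighbor_pairs(fb, ib)))
  if (nrow(cand) == 0L) return(empty_overlap_tbl())
  qh <- cand[, 1L]
  sh <- cand[, 2L]

  # focal = the gene starting first in A (ties by tag)
  first_q <- fa$start[ia][qh] < fa$start[ia][sh] |
    (fa$start[ia][qh] == fa$start[ia][sh] & p$tag_a[qh] <= p$tag_a[sh])
  f <- ifelse(first_q, qh, sh)
  n <- ifelse(first_q, sh, qh)

  same_seq_a <- fa$sequence_id[ia][f] == fa$sequence_id[ia][n]
  gap_a <- ifelse(
    same_seq_a,
    pmax(fa$start[ia][f], fa$start[ia][n]) -
      pmin(fa$end[ia][f], fa$end[ia][n]) - 1L,
    NA_integer_)
  same_seq_b <- fb$sequence_id[ib][f] == fb$sequence_id[ib][n]
  gap_b <- ifelse(
    same_seq_b,
    pmax(fb$start[ib][f], fb$start[ib][n]) -
      pmin(fb$end[ib][f], fb$end[ib][n]) - 1L,
    NA_integer_)
  overlap_a <- pmax(0L, -gap_a)
  overlap_b <- ifelse(is.na(gap_b), 0L, pmax(0L, -gap_b))
  out <- tibble::tibble(
    focal_tag = p$tag_a[f], neighbor_tag = p$tag_a[n],
    focal_tag_b = p$tag_b[f], neighbor_tag_b = p$tag_b[n],
    overlap_a_bp = overlap_a, overlap_b_bp = overlap_b,
    gap_a_bp = gap_a, gap_b_bp = gap_b,
    hazard = xor(overlap_a > 0L, overlap_b > 0L)
  )
  keep_rec <- out$hazard |
    (include_size_changes & out$overlap_a_bp != out$overlap_b_bp)
  out <- out[keep_rec, ]
  out[order(match(out$focal_tag, fa$locus_tag), out$neighbor_tag), ]
}

empty_overlap_tbl <- function() {
  tibble::tibble(
    focal_tag = character(0), neighbor_tag = character(0),
    focal_tag_b = character(0), neighbor_tag_b = character(0),
    overlap_a_bp = integer(0), overlap_b_bp = integer(0),
    gap_a_bp = integer(0), gap_b_bp = integer(0), hazard = logical(0)
  )
}
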