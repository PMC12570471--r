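# Synthetic annotation pairs with a planted ground truth.
#
# The generator emulates a GenBank-style record (annotation A) and its
# re-annotation (annotation B): a shared gene backbone, a configurable
# fraction of strand-aware start/stop shifts with mostly small offsets, a
# handful of source-exclusive genes, rare frame-breaking shifts, planted
# neighbor-overlap flips, a functional-category bias among shifted genes,
# and paired DE tables in which equal-coordinate genes agree closely while
# shifted genes are noisy. Every planted discrepancy is recorded in a truth
# ledger so recovery can be asserted exactly.

#' Configuration for the synthetic annotation-pair generator
#'
#' Defaults mirror the structure of a real GenBank/RefSeq comparison scaled
#' to a small genome: about 15% of paired genes shifted, with half of the
#' offsets at 27 bp or less and a thinning tail out to 300 bp; exclusives
#' and overlap flips at a few percent; frame breaks as the rare exception
#' (about 2 per 900 shifted genes); re-annotated models shrinking more often
#' than growing; and DE noise that is an order of magnitude larger for
#' shifted than for unshifted genes.
#'
#' @param n_genes Number of genes placed on the backbone.
#' @param genome_length Replicon length in bp; generation fails if the genes
#'   cannot be packed with the safety gaps the planted shifts require.
#' @param seed Integer seed; every random draw derives from it.
#' @param frac_shifted Fraction of shared genes given a coordinate shift.
#' @param shift_magnitudes Data frame with `offset_bp` (multiples of 3) and
#'   `prob`, the planted |offset| distribution. Default: mass 0.5 spread
#'   uniformly over 3..27 bp, mass 0.5 decaying geometrically over
#'   30..300 bp.
#' @param frac_frame_breaking Fraction of shifted genes whose offset is
#'   perturbed off the codon grid (breaking the reading frame).
#' @param p_start_shift,p_stop_shift,p_both_shift Class mix among shifted
#'   genes (must sum to 1). Default: starts and stops about equally often,
#'   never both — matching how re-annotation tallies typically partition.
#' @param p_shrink Probability that a shift makes the B gene model smaller.
#' @param n_exclusive_a,n_exclusive_b Genes present only in A / only in B.
#' @param n_overlap_flips Adjacent gene pairs overlapping in exactly one
#'   annotation.
#' @param enriched_category COG supercategory overrepresented among shifted
#'   genes (`NULL` for none).
#' @param enrichment_fold Multiplier on the enriched supercategory's letter
#'   weights when drawing COG letters for shifted genes.
#' @param frac_with_cog Fraction of genes carrying COG letters (the rest are
#'   unassigned, as hypothetical proteins typically are).
#' @param lfc_sd_unshifted,lfc_sd_shifted Per-table log2FC noise sd by class.
#' @param frac_transposase_like Fraction of *shifted* genes treated as
#'   transposase-like repeats, which receive an extra discordance term.
#' @param discordance_lfc Magnitude of that extra term (added to one table).
#' @param lfc_sd_true Spread of the underlying true log2 fold changes.
#' @param padj_noise_sd Noise on the simulated significance transform
#'   (0 makes adjusted p a deterministic function of |log2FC|).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500,
                              genome_length = 1.2e6,
                              seed = 1L,
                              frac_shifted = 0.15,
                              shift_magnitudes = default_shift_magnitudes(),
                              frac_frame_breaking = 2 / 897,
                              p_start_shift = 455 / 897,
                              p_stop_shift = 442 / 897,
                              p_both_shift = 0,
                              p_shrink = 0.7,
                              n_exclusive_a = 14,
                              n_exclusive_b = 7,
                              n_overlap_flips = 10,
                              enriched_category = "cellular_processes_and_signaling",
                              enrichment_fold = 3,
                              frac_with_cog = 0.71,
                              lfc_sd_unshifted = 0.05,
                              lfc_sd_shifted = 1.0,
                              frac_transposase_like = 0.05,
                              discordance_lfc = 3.0,
                              lfc_sd_true = 2.0,
                              padj_noise_sd = 0.2) {
  cfg <- list(
    n_genes = as.integer(n_genes), genome_length = as.integer(genome_length),
    seed = as.integer(seed), frac_shifted = frac_shifted,
    shift_magnitudes = tibble::as_tibble(shift_magnitudes),
    frac_frame_breaking = frac_frame_breaking,
    p_start_shift = p_start_shift, p_stop_shift = p_stop_shift,
    p_both_shift = p_both_shift, p_shrink = p_shrink,
    n_exclusive_a = as.integer(n_exclusive_a),
    n_exclusive_b = as.integer(n_exclusive_b),
    n_overlap_flips = as.integer(n_overlap_flips),
    enriched_category = enriched_category,
    enrichment_fold = enrichment_fold, frac_with_cog = frac_with_cog,
    lfc_sd_unshifted = lfc_sd_unshifted, lfc_sd_shifted = lfc_sd_shifted,
    frac_transposase_like = frac_transposase_like,
    discordance_lfc = discordance_lfc, lfc_sd_true = lfc_sd_true,
    padj_noise_sd = padj_noise_sd
  )
  fracs <- c(cfg$frac_shifted, cfg$frac_frame_breaking, cfg$p_shrink,
             cfg$frac_with_cog, cfg$frac_transposase_like)
  stopifnot(
    is_count(cfg$n_genes), cfg$n_genes >= 2L,
    is_count(cfg$genome_length),
    all(fracs >= 0 & fracs <= 1),
    abs(cfg$p_start_shift + cfg$p_stop_shift + cfg$p_both_shift - 1) < 1e-9,
    cfg$n_exclusive_a + cfg$n_exclusive_b <= cfg$n_genes,
    all(c("offset_bp", "prob") %in% names(cfg$shift_magnitudes)),
    all(cfg$shift_magnitudes$offset_bp > 0),
    all(cfg$shift_magnitudes$offset_bp %% 3 == 0),
    abs(sum(cfg$shift_magnitudes$prob) - 1) < 1e-9,
    cfg$lfc_sd_unshifted >= 0, cfg$lfc_sd_shifted >= 0,
    cfg$discordance_lfc >= 0, cfg$padj_noise_sd >= 0
  )
  structure(cfg, class = "simulation_config")
}

#' Default planted shift-size distribution
#'
#' Half of the mass uniformly on offsets 3..27 bp, half decaying
#' geometrically over 30..300 bp, all on the codon grid.
#'
#' @return Tibble with `offset_bp` and `prob`.
#' @export
default_shift_magnitudes <- function() {
  small <- seq(3L, 27L, by = 3L)
  tail <- seq(30L, 300L, by = 3L)
  w_tail <- 0.9^seq_along(tail)
  tibble::tibble(
    offset_bp = c(small, tail),
    prob = c(rep(0.5 / length(small), length(small)),
             0.5 * w_tail / sum(w_tail))
  )
}

# maximum planted extent change: largest offset plus the frame-break nudge
max_shift_extent <- function(cfg) max(cfg$shift_magnitudes$offset_bp) + 2L

#' Generate a synthetic annotation pair with planted ground truth
#'
#' Places `n_genes` non-overlapping genes on both strands of one replicon
#' (A-namespace tags `PP_0001`-style), then derives annotation B by renaming
#' tags to the `PP_RS00005` style with `old_locus_tag` back-links and
#' applying the planted discrepancies: strand-aware start/stop shifts,
#' frame breaks, source-exclusive genes and overlap flips. Intergenic gaps
#' exceed twice the largest configured shift, so planted shifts never create
#' accidental overlaps — every hazard the diff engine finds is a planted
#' one. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `ann_a`, `ann_b` ([genome_annotation()] objects) and
#'   `truth`, the per-locus ledger: `tag_a`, `tag_b`, `class` (identical /
#'   start_shifted / stop_shifted / both_shifted / exclusive_a /
#'   exclusive_b), signed biological `start_delta_bp` / `stop_delta_bp`,
#'   `frame_preserved`, `overlap_partner` + `hazard`, `cog_letters`,
#'   `transposase_like`.
#' @export
generate_annotation_pair <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_genes
  set.seed(cfg$seed)

  # --- backbone: non-overlapping genes with shift-proof gaps -------------
  lens <- 3L * pmax(50L, as.integer(round(rgamma(n, shape = 4, scale = 75))))
  min_gap <- 2L * max_shift_extent(cfg) + 20L
  gaps <- min_gap + as.integer(floor(runif(n, 0, 400)))
  starts <- cumsum(c(max_shift_extent(cfg) + 1L, head(lens + gaps, -1L)))
  ends <- starts + lens - 1L
  if (ends[n] > cfg$genome_length) {
    stop_annodiff(
      "infeasible packing: %d genes need %d bp but genome_length is %d",
      n, ends[n], cfg$genome_length)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tag_a <- sprintf("PP_%04d", seq_len(n))
  tag_b <- sprintf("PP_RS%05d", 5L * seq_len(n))

  # --- roles -------------------------------------------------------------
  role <- rep("shared", n)
  excl <- sample.int(n, cfg$n_exclusive_a + cfg$n_exclusive_b)
  role[excl[seq_len(cfg$n_exclusive_a)]] <- "exclusive_a"
  role[excl[seq_len(cfg$n_exclusive_b) + cfg$n_exclusive_a]] <- "exclusive_b"

  # overlap flips need two adjacent shared genes; pick disjoint pairs
  flip_focal <- integer(0)
  if (cfg$n_overlap_flips > 0L) {
    cand <- which(seq_len(n) < n & role == "shared" &
                    c(role[-1L], "") == "shared")
    cand <- sample(cand)
    used <- logical(n)
    for (i in cand) {
      if (length(flip_focal) >= cfg$n_overlap_flips) break
      if (!used[i] && !used[i + 1L]) {
        flip_focal <- c(flip_focal, i)
        used[i] <- used[i + 1L] <- TRUE
      }
    }
    if (length(flip_focal) < cfg$n_overlap_flips) {
      stop_annodiff("cannot place %d disjoint overlap flips in %d genes",
                    cfg$n_overlap_flips, n)
    }
    flip_focal <- sort(flip_focal)
  }
  reserved <- c(flip_focal, flip_focal + 1L)

  shared_free <- setdiff(which(role == "shared"), reserved)
  n_shift <- round(cfg$frac_shifted * sum(role == "shared"))
  n_shift <- min(n_shift, length(shared_free))
  shifted_idx <- sort(sample(shared_free, n_shift))

  # --- planted shift deltas (biological orientation, B relative to A) ----
  start_delta <- integer(n)
  stop_delta <- integer(n)
  frame_break <- logical(n)
  if (n_shift > 0L) {
    cls <- sample(c("start_shifted", "stop_shifted", "both_shifted"),
                  n_shift, replace = TRUE,
                  prob = c(cfg$p_start_shift, cfg$p_stop_shift,
                           cfg$p_both_shift))
    frame_break[shifted_idx] <- runif(n_shift) < cfg$frac_frame_breaking
    # cap the shrink so a gene shifted at both ends keeps positive length
    max_mag <- pmax(3L, 3L * ((lens[shifted_idx] - 6L) %/% 6L))
    signed <- function(idx, shrink_sign) {
      k <- length(idx)
      mag <- sample(cfg$shift_magnitudes$offset_bp, k, replace = TRUE,
                    prob = cfg$shift_magnitudes$prob)
      mag <- pmin(mag, max_mag[match(idx, shifted_idx)])
      sgn <- ifelse(runif(k) < cfg$p_shrink, shrink_sign, -shrink_sign)
      as.integer(mag * sgn)
    }
    has_start <- cls %in% c("start_shifted", "both_shifted")
    has_stop <- cls %in% c("stop_shifted", "both_shifted")
    # shrinking means the start moves downstream (+) or the stop upstream (-)
    start_delta[shifted_idx[has_start]] <- signed(shifted_idx[has_start], +1L)
    stop_delta[shifted_idx[has_stop]] <- signed(shifted_idx[has_stop], -1L)
    # frame break: push the (first available) shifted end off the codon grid
    fb <- which(frame_break[shifted_idx])
    for (j in fb) {
      i <- shifted_idx[j]
      nudge <- sample(c(1L, 2L), 1L)
      if (start_delta[i] != 0L) {
        start_delta[i] <- start_delta[i] + sign(start_delta[i]) * nudge
      } else {
        stop_delta[i] <- stop_delta[i] + sign(stop_delta[i]) * nudge
      }
    }
  }

  # --- overlap flips: adjust the focal gene's downstream genomic end -----
  # direction "a": genes overlap in A only; "b": in B only. The focal
  # gene's genomic end is extended toward its right neighbor in exactly one
  # annotation; the extension is kept on the codon grid.
  flip_dir <- sample(c("a", "b"), length(flip_focal), replace = TRUE)
  overlap_partner <- rep(NA_character_, n)
  ext_a <- integer(n)  # extension of the genomic end in annotation A
  ext_b <- integer(n)  # ... in annotation B
  for (j in seq_along(flip_focal)) {
    i <- flip_focal[j]
    gap <- starts[i + 1L] - ends[i] - 1L
    ov <- 6L + (3L - (gap + 6L) %% 3L) %% 3L  # 6..8 bp, extension %% 3 == 0
    if (flip_dir[j] == "a") ext_a[i] <- gap + ov else ext_b[i] <- gap + ov
    overlap_partner[i] <- tag_a[i + 1L]
    # the genomic-end change is a biological stop shift on "+", start on "-"
    delta_bio <- ext_b[i] - ext_a[i]  # end_b - end_a
    if (strand[i] == "+") {
      stop_delta[i] <- delta_bio
    } else {
      start_delta[i] <- -delta_bio
    }
  }

  # --- COG letters (A namespace; enrichment planted among shifted) -------
  is_shifted <- start_delta != 0L | stop_delta != 0L
  cog_letters <- draw_cog_letters(n, is_shifted, cfg)

  # --- materialize features ---------------------------------------------
  product <- ifelse(!is.na(overlap_partner) | seq_len(n) %in% (flip_focal + 1L),
                    "cytochrome c family protein",
                    ifelse(is_shifted & frame_break, "transposase",
                           "hypothetical protein"))
  a_start <- starts
  a_end <- ends + ext_a
  # apply biological deltas to B coordinates (B relative to A)
  plus <- strand == "+"
  b_start <- ifelse(plus, starts + start_delta, starts - stop_delta)
  b_end <- ifelse(plus, ends + stop_delta, ends - start_delta)
  # flip loci: start untouched, genomic end follows its own extension
  sel <- seq_len(n) %in% flip_focal
  b_start[sel] <- starts[sel]
  b_end[sel] <- ends[sel] + ext_b[sel]

  in_a <- role != "exclusive_b"
  in_b <- role != "exclusive_a"

  feats_a <- tibble::tibble(
    locus_tag = tag_a[in_a], old_locus_tags = rep(list(character(0)), sum(in_a)),
    feature_class = "protein_coding",
    start = as.integer(a_start[in_a]), end = as.integer(a_end[in_a]),
    strand = strand[in_a], product_name = product[in_a],
    gene_symbol = NA_character_, sequence_id = "synth_chr1"
  )
  feats_b <- tibble::tibble(
    locus_tag = tag_b[in_b],
    old_locus_tags = purrr::map2(role[in_b], tag_a[in_b], function(r, t) {
      if (r == "exclusive_b") character(0) else t
    }),
    feature_class = "protein_coding",
    start = as.integer(b_start[in_b]), end = as.integer(b_end[in_b]),
    strand = strand[in_b], product_name = product[in_b],
    gene_symbol = NA_character_, sequence_id = "synth_chr1"
  )

  ann_a <- genome_annotation(feats_a, source_label = "synthetic_A",
                             accession = "SYNTH_A.1",
                             retrieval_date = as.character(Sys.Date()))
  ann_b <- genome_annotation(feats_b, source_label = "synthetic_B",
                             accession = "SYNTH_B.1",
                             retrieval_date = as.character(Sys.Date()))

  truth_class <- dplyr::case_when(
    role == "exclusive_a" ~ "exclusive_a",
    role == "exclusive_b" ~ "exclusive_b",
    start_delta != 0L & stop_delta != 0L ~ "both_shifted",
    start_delta != 0L ~ "start_shifted",
    stop_delta != 0L ~ "stop_shifted",
    TRUE ~ "identical"
  )
  truth <- tibble::tibble(
    tag_a = ifelse(role == "exclusive_b", NA_character_, tag_a),
    tag_b = ifelse(role == "exclusive_a", NA_character_, tag_b),
    class = truth_class,
    strand = strand,
    start_delta_bp = as.integer(ifelse(role == "shared", start_delta, NA)),
    stop_delta_bp = as.integer(ifelse(role == "shared", stop_delta, NA)),
    frame_preserved = ifelse(role == "shared",
                             start_delta %% 3L == 0L & stop_delta %% 3L == 0L,
                             NA),
    overlap_partner = overlap_partner,
    hazard = !is.na(overlap_partner),
    cog_letters = cog_letters,
    transposase_like = FALSE
  )
  list(ann_a = ann_a, ann_b = ann_b, truth = truth, config = cfg)
}

# letter weights loosely shaped like a bacterial genome's COG composition
COG_LETTER_WEIGHTS <- c(
  J = 0.045, A = 0.002, K = 0.08, L = 0.04, B = 0.002,
  D = 0.012, Y = 0.001, V = 0.02, T = 0.05, M = 0.06, N = 0.02, Z = 0.004,
  W = 0.005, U = 0.02, O = 0.04, X = 0.012,
  C = 0.06, G = 0.06, E = 0.085, F = 0.025, H = 0.045, I = 0.04, P = 0.055,
  Q = 0.03, R = 0.05, S = 0.15
)

draw_cog_letters <- function(n, is_shifted, cfg) {
  map <- cog_categories()
  w_base <- COG_LETTER_WEIGHTS[map$letter]
  w_enr <- w_base
  if (!is.null(cfg$enriched_category)) {
    boost <- map$supercategory == cfg$enriched_category
    w_enr[boost] <- w_enr[boost] * cfg$enrichment_fold
  }
  has_cog <- runif(n) < cfg$frac_with_cog
  n_letters <- 1L + (runif(n) < 0.15)
  purrr::map(seq_len(n), function(i) {
    if (!has_cog[i]) return(character(0))
    w <- if (is_shifted[i]) w_enr else w_base
    sample(map$letter, n_letters[i], prob = w)
  })
}

#' Simulate paired differential-expression tables from planted truth
#'
#' Each gene's observed log2FC in either table is its true value plus
#' class-dependent noise (`lfc_sd_unshifted` for identical-coordinate
#' genes, `lfc_sd_shifted` for shifted ones, emulating the quantification
#' instability of re-annotated gene models). A fraction of shifted genes is
#' marked transposase-like and receives an extra `discordance_lfc` term in
#' table B only. Adjusted p-values are a monotone transform of |log2FC|
#' with configurable noise, then BH-adjusted — a convenience for
#' significance-flip testing, not a calibrated count model. Deterministic
#' given `cfg$seed`.
#'
#' @param sim A [generate_annotation_pair()] result (uses its `truth` and
#'   `config`).
#' @param cfg Optional [simulation_config()] overriding `sim$config`.
#' @return List with `table_a`, `table_b` (tibbles with `gene_id`,
#'   `log2FoldChange`, `padj`, keyed in the A / B namespace respectively)
#'   and `truth`, the input ledger augmented with `true_lfc` and
#'   `discordant` (planted transposase-like flag).
#' @export
simulate_de_tables <- function(sim, cfg = NULL) {
  cfg <- cfg %||% sim$config
  truth <- sim$truth
  n <- nrow(truth)
  set.seed(cfg$seed + 1000003L)

  true_lfc <- rnorm(n, 0, cfg$lfc_sd_true)
  shifted <- !is.na(truth$class) &
    truth$class %in% c("start_shifted", "stop_shifted", "both_shifted")
  sd_vec <- ifelse(shifted, cfg$lfc_sd_shifted, cfg$lfc_sd_unshifted)

  transposase <- shifted & runif(n) < cfg$frac_transposase_like
  lfc_a <- true_lfc + rnorm(n, 0, sd_vec)
  lfc_b <- true_lfc + rnorm(n, 0, sd_vec) +
    ifelse(transposase, sample(c(-1, 1), n, replace = TRUE) *
             cfg$discordance_lfc, 0)

  padj_from <- function(lfc) {
    z <- abs(lfc) / 0.25 * exp(rnorm(n, 0, cfg$padj_noise_sd))
    p.adjust(2 * pnorm(-z), method = "BH")
  }
  padj_a <- padj_from(lfc_a)
  padj_b <- padj_from(lfc_b)

  in_a <- !is.na(truth$tag_a)
  in_b <- !is.na(truth$tag_b)
  truth$true_lfc <- true_lfc
  truth$transposase_like <- transposase
  truth$discordant <- transposase
  list(
    table_a = tibble::tibble(gene_id = truth$tag_a[in_a],
                             log2FoldChange = lfc_a[in_a],
                             padj = padj_a[in_a]),
    table_b = tibble::tibble(gene_id = truth$tag_b[in_b],
                             log2FoldChange = lfc_b[in_b],
                             padj = padj_b[in_b]),
    truth = truth
  )
}
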