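test_that("pair_loci matches via old_locus_tag and identical tags", {
  a <- toy_annotation(dplyr::bind_rows(feat("PP_0001", 1, 900),
                                       feat("PP_0002", 2000, 2900)))
  b_feats <- dplyr::bind_rows(feat("PP_RS00005", 1, 900),
                              feat("PP_0002", 2000, 2900))
  b_feats$old_locus_tags <- list("PP_0001", character(0))
  b <- toy_annotation(b_feats)

  pairing <- pair_loci(a, b)
  expect_equal(nrow(pairing$pairs), 2L)
  expect_equal(
    pairing$pairs$match_basis[pairing$pairs$tag_a == "PP_0001"],
    "old_locus_tag")
  expect_equal(
    pairing$pairs$tag_b[pairing$pairs$tag_a == "PP_0001"], "PP_RS00005")
  expect_equal(
    pairing$pairs$match_basis[pairing$pairs$tag_a == "PP_0002"],
    "identical_tag")
  expect_equal(nrow(pairing$only_a), 0L)
  expect_equal(nrow(pairing$only_b), 0L)
})

test_that("disjoint tag universes yield no pairs", {
  a <- toy_annotation(feat("A1", 1, 900))
  b <- toy_annotation(feat("B1", 1, 900))
  pairing <- pair_loci(a, b)
  expect_equal(nrow(pairing$pairs), 0L)
  expect_equal(pairing$only_a$locus_tag, "A1")
  expect_equal(pairing$only_b$locus_tag, "B1")
})

test_that("conflicting claims are surfaced, never paired silently", {
  a <- toy_annotation(feat("PP_0001", 1, 900))
  b_feats <- dplyr::bind_rows(feat("X1", 1, 450), feat("X2", 460, 900))
  b_feats$old_locus_tags <- list("PP_0001", "PP_0001")
  b <- toy_annotation(b_feats)
  pairing <- pair_loci(a, b)
  expect_equal(nrow(pairing$pairs), 0L)
  expect_equal(nrow(pairing$conflicts), 2L)
  expect_setequal(pairing$conflicts$tag_b, c("X1", "X2"))
  # conflicted features still covered by the exclusive lists
  expect_equal(pairing$only_a$locus_tag, "PP_0001")
  expect_setequal(pairing$only_b$locus_tag, c("X1", "X2"))
})

test_that("pairing is independent of feature order", {
  sim <- generate_annotation_pair(simulation_config(seed = 3, n_genes = 80,
                                                    n_overlap_flips = 2,
                                                    n_exclusive_a = 4,
                                                    n_exclusive_b = 2))
  shuffled <- sim$ann_b
  set.seed(42)
  shuffled$features <- shuffled$features[sample.int(nrow(shuffled$features)), ]
  p1 <- pair_loci(sim$ann_a, sim$ann_b)
  p2 <- pair_loci(sim$ann_a, shuffled)
  expect_equal(p1$pairs, p2$pairs)
})

test_that("convert_locus_tag maps both directions and round-trips", {
  a <- toy_annotation(feat("PP_0001", 1, 900))
  b_feats <- feat("PP_RS00005", 1, 900)
  b_feats$old_locus_tags <- list("PP_0001")
  pairing <- pair_loci(a, toy_annotation(b_feats))

  expect_equal(convert_locus_tag("PP_0001", pairing, "a_to_b"), "PP_RS00005")
  expect_equal(convert_locus_tag("PP_RS00005", pairing, "b_to_a"), "PP_0001")
  expect_true(is.na(convert_locus_tag("nope", pairing, "a_to_b")))

  sim <- generate_annotation_pair(simulation_config(seed = 5, n_genes = 60))
  pr <- pair_loci(sim$ann_a, sim$ann_b)
  back <- convert_locus_tag(
    convert_locus_tag(pr$pairs$tag_a, pr, "a_to_b"), pr, "b_to_a")
  expect_equal(back, pr$pairs$tag_a)
})

test_that("classify_pair handles the canonical strand conventions", {
  # identical
  r <- classify_pair(feat("a", 100, 400), feat("b", 100, 400))
  expect_equal(r$category, "identical")
  expect_equal(r$start_delta_bp, 0L)
  expect_equal(r$stop_delta_bp, 0L)
  expect_true(r$frame_preserved)

  # plus-strand start shift, in frame
  r <- classify_pair(feat("a", 100, 400), feat("b", 127, 400))
  expect_equal(r$category, "start_shifted")
  expect_equal(r$start_delta_bp, 27L)
  expect_equal(r$stop_delta_bp, 0L)
  expect_true(r$frame_preserved)
  expect_equal(r$length_delta_bp, -27L)

  # minus strand: the biological start is the high coordinate
  r <- classify_pair(feat("a", 100, 400, "-"), feat("b", 100, 370, "-"))
  expect_equal(r$category, "start_shifted")
  expect_equal(r$start_delta_bp, 30L)
  expect_equal(r$stop_delta_bp, 0L)
  expect_true(r$frame_preserved)

  # one-bp shift breaks the frame
  r <- classify_pair(feat("a", 100, 400), feat("b", 101, 400))
  expect_false(r$frame_preserved)
  expect_equal(r$category, "start_shifted")

  # strand mismatch
  r <- classify_pair(feat("a", 100, 400, "+"), feat("b", 100, 400, "-"))
  expect_false(r$strand_consistent)
  expect_false(r$frame_preserved)
  expect_equal(r$category, "both_shifted")
})

test_that("classify_pair agrees with a codon-enumeration oracle", {
  set.seed(99)
  for (i in 1:200) {
    strand_a <- sample(c("+", "-"), 1)
    strand_b <- if (runif(1) < 0.9) strand_a else setdiff(c("+", "-"), strand_a)
    s_a <- sample(200:400, 1)
    e_a <- s_a + 3 * sample(30:80, 1) - 1
    s_b <- s_a + sample(-30:30, 1)
    e_b <- e_a + sample(-30:30, 1)
    a <- feat("a", s_a, e_a, strand_a)
    b <- feat("b", s_b, e_b, strand_b)
    got <- classify_pair(a, b)
    want <- classify_oracle(a, b)
    expect_equal(got$category, want$category)
    if (strand_a == strand_b) {
      expect_equal(got$start_delta_bp, unname(want$start_delta))
      expect_equal(got$stop_delta_bp, unname(want$stop_delta))
    }
    expect_equal(got$frame_preserved, want$frame_preserved)
  }
})

test_that("length delta equals stop minus start delta in biological orientation", {
  set.seed(7)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    a <- feat("a", 500, 500 + 3 * sample(40:60, 1) - 1, strand)
    b <- feat("b", a$start + sample(-12:12, 1), a$end + sample(-12:12, 1),
              strand)
    r <- classify_pair(a, b)
    expect_equal(r$length_delta_bp, r$stop_delta_bp - r$start_delta_bp)
  }
})

test_that("diffing identical annotations reports no differences", {
  sim <- generate_annotation_pair(simulation_config(seed = 2, n_genes = 50,
                                                    frac_shifted = 0,
                                                    n_exclusive_a = 0,
                                                    n_exclusive_b = 0,
                                                    n_overlap_flips = 0))
  d <- diff_annotations(sim$ann_a, sim$ann_a)
  expect_equal(d$summary$n_shifted, 0L)
  expect_equal(d$summary$n_only_a, 0L)
  expect_equal(d$summary$n_only_b, 0L)
  expect_equal(d$summary$n_pairs, d$summary$n_identical)
  expect_equal(d$summary$n_frame_broken, 0L)
})

test_that("summary counts partition the pairs and pool shift magnitudes", {
  sim <- generate_annotation_pair(simulation_config(seed = 13))
  d <- diff_annotations(sim$ann_a, sim$ann_b)
  s <- d$summary
  expect_equal(s$n_pairs, s$n_identical + s$n_shifted)
  expect_equal(s$n_shifted,
               s$n_start_shifted_only + s$n_stop_shifted_only +
                 s$n_both_shifted)
  n_pc_a <- nrow(protein_coding_subset(sim$ann_a)$features)
  n_pc_b <- nrow(protein_coding_subset(sim$ann_b)$features)
  expect_equal(s$n_pairs + s$n_only_a, n_pc_a)
  expect_equal(s$n_pairs + s$n_only_b, n_pc_b)
  expect_equal(length(s$shift_magnitudes),
               sum(d$records$start_delta_bp != 0) +
                 sum(d$records$stop_delta_bp != 0))
  expect_true(all(s$shift_magnitudes > 0))
})

test_that("swapping A and B negates deltas and swaps exclusives", {
  sim <- generate_annotation_pair(simulation_config(seed = 17))
  fwd <- diff_annotations(sim$ann_a, sim$ann_b)
  rev <- diff_annotations(sim$ann_b, sim$ann_a)

  expect_equal(rev$summary$n_pairs, fwd$summary$n_pairs)
  expect_equal(rev$summary$n_shifted, fwd$summary$n_shifted)
  expect_equal(rev$summary$n_only_a, fwd$summary$n_only_b)
  expect_equal(rev$summary$n_only_b, fwd$summary$n_only_a)

  key_fwd <- fwd$records[order(fwd$records$tag_a), ]
  key_rev <- rev$records[order(rev$records$tag_b), ]
  expect_equal(key_rev$tag_b, key_fwd$tag_a)
  expect_equal(key_rev$start_delta_bp, -key_fwd$start_delta_bp)
  expect_equal(key_rev$stop_delta_bp, -key_fwd$stop_delta_bp)
  expect_equal(key_rev$frame_preserved, key_fwd$frame_preserved)
})

test_that("reflecting the genome leaves categories and magnitudes invariant", {
  sim <- generate_annotation_pair(simulation_config(seed = 23))
  L <- simulation_config(seed = 23)$genome_length
  refl_a <- reflect_annotation(sim$ann_a, L)
  refl_b <- reflect_annotation(sim$ann_b, L)

  d0 <- diff_annotations(sim$ann_a, sim$ann_b)
  d1 <- diff_annotations(refl_a, refl_b)

  k0 <- d0$records[order(d0$records$tag_a), ]
  k1 <- d1$records[order(d1$records$tag_a), ]
  expect_equal(k1$category, k0$category)
  expect_equal(abs(k1$start_delta_bp), abs(k0$start_delta_bp))
  expect_equal(abs(k1$stop_delta_bp), abs(k0$stop_delta_bp))
  expect_equal(k1$frame_preserved, k0$frame_preserved)
})

test_that("overlap-change detection mirrors the adjacent-gene hazard case", {
  # A: X and Y overlap by 6 bp; B: Y starts 6 bp downstream of X's end
  a <- toy_annotation(dplyr::bind_rows(feat("X", 1, 300), feat("Y", 295, 600)))
  b_f <- dplyr::bind_rows(feat("X", 1, 300), feat("Y", 307, 600))
  b <- toy_annotation(b_f)
  pairing <- pair_loci(a, b)
  ov <- detect_overlap_changes(a, b, pairing)
  expect_equal(nrow(ov), 1L)
  expect_true(ov$hazard)
  expect_equal(ov$focal_tag, "X")
  expect_equal(ov$neighbor_tag, "Y")
  expect_equal(ov$overlap_a_bp, 6L)
  expect_equal(ov$overlap_b_bp, 0L)
  expect_equal(ov$gap_b_bp, 6L)
})

test_that("well-separated genes yield no overlap-change records", {
  a <- toy_annotation(dplyr::bind_rows(feat("X", 1, 300), feat("Y", 2000, 2300)))
  pairing <- pair_loci(a, a)
  expect_equal(nrow(detect_overlap_changes(a, a, pairing)), 0L)
})

test_that("planted overlap flips are recovered exactly and exclusively", {
  for (s in c(31, 32)) {
    cfg <- simulation_config(seed = s, n_overlap_flips = 8)
    sim <- generate_annotation_pair(cfg)
    d <- diff_annotations(sim$ann_a, sim$ann_b)
    ov <- detect_overlap_changes(sim$ann_a, sim$ann_b, d$pairing)
    expect_equal(sum(ov$hazard), 8L)
    expect_setequal(ov$focal_tag[ov$hazard],
                    sim$truth$tag_a[sim$truth$hazard & !is.na(sim$truth$tag_a)])
  }
})
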