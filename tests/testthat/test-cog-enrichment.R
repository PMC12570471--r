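test_that("COG letters map to the fixed supercategory table", {
  asn <- cog_assignments(c("PP_0001", "PP_0002", "PP_0003"),
                         c("D", "", "KQ"))
  expect_equal(asn$supercategories[[1L]], "cellular_processes_and_signaling")
  expect_true(asn$unassigned[2L])
  expect_equal(length(asn$cog_letters[[2L]]), 0L)
  expect_setequal(asn$supercategories[[3L]],
                  c("information_storage_and_processing", "metabolism"))
})

test_that("unknown COG letters are kept verbatim without a supercategory", {
  expect_warning(asn <- cog_assignments("PP_0001", "D#"), "#")
  expect_setequal(asn$cog_letters[[1L]], c("D", "#"))
  expect_equal(asn$supercategories[[1L]], "cellular_processes_and_signaling")
})

test_that("COG TSV fixtures load losslessly", {
  path <- tempfile(fileext = ".tsv")
  tbl <- tibble::tibble(
    locus_tag = sprintf("PP_%04d", 1:10),
    cog_letters = c("D", "DU", "", "K", "S", "EG", "M", "", "T", "O")
  )
  readr::write_tsv(tbl, path)
  asn <- load_cog_assignments(path)
  expect_equal(asn$locus_tag, tbl$locus_tag)
  expect_equal(
    sort(unlist(asn$cog_letters)),
    sort(unlist(strsplit(tbl$cog_letters, "")))
  )
  # duplicate locus tags are rejected
  readr::write_tsv(tbl[c(1, 1), ], path)
  expect_error(load_cog_assignments(path), "duplicate")
})

test_that("the one-tailed Fisher test matches its closed-form cases", {
  r <- fisher_one_tailed_greater(1, 0, 0, 1)
  expect_equal(r$p, 0.5)
  expect_equal(r$odds_ratio, Inf)

  # a = 0 sits at the bottom of the upper tail: p covers all mass
  r <- fisher_one_tailed_greater(0, 10, 5, 85)
  expect_equal(r$p, 1.0)

  expect_error(fisher_one_tailed_greater(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p matches the enumeration oracle on random tables", {
  set.seed(11)
  for (i in 1:300) {
    t <- as.integer(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    got <- fisher_one_tailed_greater(t[1], t[2], t[3], t[4])$p
    expect_equal(got, fisher_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with fisher.test's one-sided p", {
  set.seed(12)
  for (i in 1:50) {
    t <- as.integer(stats::rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
    got <- fisher_one_tailed_greater(t[1], t[2], t[3], t[4])$p
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("Fisher p is monotone nonincreasing in a at fixed margins", {
  for (m in list(c(10, 20), c(5, 35), c(15, 15))) {
    n1 <- m[1]; n2 <- m[2]; K <- 12
    ks <- max(0, K - n2):min(K, n1)
    ps <- vapply(ks, function(a) {
      fisher_one_tailed_greater(a, n1 - a, K - a, n2 - (K - a))$p
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("an all-in-one-category shifted set attains the minimum p", {
  records <- tibble::tibble(
    tag_a = sprintf("g%02d", 1:40),
    category = rep(c("start_shifted", "identical"), each = 20)
  )
  letters <- c(rep("D", 20),                       # shifted: all cellular
               rep(c("C", "K", "S", "E"), 5))      # background: none in D
  asn <- cog_assignments(records$tag_a, letters)
  enr <- enrich_categories(records, asn)
  expect_equal(enr$category[1L], "cellular_processes_and_signaling")
  expect_true(enr$p[1L] < 1e-6)
  expect_true(all(enr$p[-1L] > enr$p[1L]))
})

test_that("identical composition in both sets gives no enrichment signal", {
  base_letters <- rep(c("D", "K", "C", "S"), 10)
  records <- tibble::tibble(
    tag_a = sprintf("g%02d", 1:80),
    category = rep(c("start_shifted", "identical"), each = 40)
  )
  asn <- cog_assignments(records$tag_a, rep(base_letters, 2))
  enr <- enrich_categories(records, asn)
  expect_true(all(enr$p >= 0.5))
})

test_that("genes partition into shifted, background and no-COG sets", {
  sim <- generate_annotation_pair(simulation_config(seed = 41))
  d <- diff_annotations(sim$ann_a, sim$ann_b)
  asn <- truth_cog_assignments(sim$truth)
  enr <- enrich_categories(d$records, asn)
  a_plus_b <- enr$a[1L] + enr$b[1L]
  c_plus_d <- enr$c[1L] + enr$d[1L]
  expect_equal(a_plus_b + c_plus_d +
                 attr(enr, "n_shifted_no_cog") +
                 attr(enr, "n_unshifted_no_cog"),
               d$summary$n_pairs)
  expect_true(all(enr$a + enr$b == a_plus_b))
  expect_true(all(enr$c + enr$d == c_plus_d))
})

test_that("a planted 3x-enriched category attains the minimum p almost always", {
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 6000 + s, n_genes = 600,
                             genome_length = 2e6)
    sim <- generate_annotation_pair(cfg)
    shifted <- sim$truth$class %in%
      c("start_shifted", "stop_shifted", "both_shifted")
    records <- tibble::tibble(
      tag_a = sim$truth$tag_a,
      category = ifelse(shifted, "start_shifted", "identical")
    )
    records <- records[!is.na(records$tag_a) & !is.na(sim$truth$tag_b), ]
    enr <- enrich_categories(records, truth_cog_assignments(sim$truth))
    hits <- hits + (enr$category[1L] == "cellular_processes_and_signaling")
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("permuting the shifted labels destroys the planted enrichment", {
  cfg <- simulation_config(seed = 77, n_genes = 600, genome_length = 2e6)
  sim <- generate_annotation_pair(cfg)
  d <- diff_annotations(sim$ann_a, sim$ann_b)
  asn <- truth_cog_assignments(sim$truth)
  set.seed(78)
  calm <- 0L
  n_perm <- 100L
  for (i in seq_len(n_perm)) {
    perm <- d$records
    perm$category <- sample(perm$category)
    enr <- enrich_categories(perm, asn)
    calm <- calm + (min(enr$p) >= 0.01)
  }
  expect_gte(calm / n_perm, 0.90)
})

test_that("treemap aggregation counts gene-letter incidences", {
  records <- tibble::tibble(
    tag_a = c("g1", "g2", "g3", "g4"),
    category = c("start_shifted", "stop_shifted", "both_shifted", "identical")
  )
  asn <- cog_assignments(records$tag_a, c("D", "K", "DU", "C"))
  tre <- treemap_table(records, asn)
  # g4 is unshifted and excluded; g3 contributes to two rows
  expect_equal(sum(tre$n_genes), 4L)
  expect_equal(tre$n_genes[tre$letter == "D"], 2L)
  expect_equal(tre$n_genes[tre$letter == "U"], 1L)
  expect_false("C" %in% tre$letter)
  expect_equal(
    tre$supercategory[tre$letter == "K"], "information_storage_and_processing")
})

test_that("enrichment requires both shifted and background COG-annotated loci", {
  records <- tibble::tibble(tag_a = c("g1", "g2"),
                            category = c("start_shifted", "start_shifted"))
  asn <- cog_assignments(c("g1", "g2"), c("D", "K"))
  expect_error(enrich_categories(records, asn), "undefined")
})
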