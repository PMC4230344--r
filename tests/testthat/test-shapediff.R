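test_that("spline smoothing reproduces constants, lines and knot values", {
  s <- smooth_profile(rep(3.5, 8))
  expect_equal(s$values, rep(3.5, 24))

  ramp <- smooth_profile(0:9)
  expect_equal(ramp$values, ramp$eval_points, tolerance = 1e-9)

  # interpolating property: re-evaluating at the knots returns the bins
  bins <- c(0, 5, 1, 8, 2, 9)
  for (ends in c("fmm", "natural")) {
    at_knots <- stats::spline(0:5, bins, xout = 0:5, method = ends)$y
    expect_equal(at_knots, bins, tolerance = 1e-9)
  }
  expect_error(smooth_profile(c(1, 2, 3)), "at least 4 bins")
})

test_that("natural-end smoothing matches the independent spline oracle", {
  bins <- c(0, 5, 1, 8, 2, 9)
  got <- smooth_profile(bins, ends = "natural")
  expect_length(got$values, 18)
  want <- oracle_natural_spline(0:5, bins, got$eval_points)
  expect_equal(got$values, want, tolerance = 1e-6)

  set.seed(19)
  for (i in 1:10) {
    nb <- sample(4:40, 1)
    b <- rpois(nb, 6)
    if (var(b) == 0) next
    g <- smooth_profile(b, ends = "natural")
    expect_equal(g$values,
                 oracle_natural_spline(0:(nb - 1), b, g$eval_points),
                 tolerance = 1e-6)
  }
})

test_that("penalized smoothing spline tracks the signal's scale", {
  set.seed(2)
  b <- sin(seq(0, 4 * pi, length.out = 40)) * 10 + rnorm(40, sd = 0.5)
  s <- smooth_profile(b, method = "smoothing")
  expect_length(s$values, 120)
  expect_lt(max(abs(range(s$values) - range(b))), 5)
})

test_that("profile correlation handles identity, inversion and scaling", {
  a <- c(1, 4, 2, 8, 3, 7)
  expect_equal(profile_correlation(a, a)$r, 1)
  expect_equal(profile_correlation(a, -a)$r, -1)
  expect_equal(profile_correlation(a, 2 * a + 5)$r, 1)
  expect_equal(profile_correlation(a, rev(a))$r,
               oracle_pearson(a, rev(a)))
})

test_that("degenerate and short inputs yield statuses, never silent numbers", {
  a <- c(1, 4, 2, 8, 3, 7)
  flat <- rep(2, 6)
  expect_identical(profile_correlation(flat, a)$status, "degenerate_a")
  expect_true(is.na(profile_correlation(flat, a)$r))
  expect_identical(profile_correlation(a, flat)$status, "degenerate_b")
  expect_identical(profile_correlation(a[1:3], a[1:3])$status,
                   "too_short")
  expect_error(profile_correlation(a, a[1:4]), "different lengths")
})

test_that("the per-gene statistic is invariant to depth scaling", {
  set.seed(23)
  cs <- toy_chrom_sizes(600)
  tr_a <- toy_track(rpois(600, 5), total_reads = 3000)
  tr_b <- toy_track(rpois(600, 5), total_reads = 3000)
  g <- gene_model("g", "chrI", 50, 550, "+")
  r0 <- shape_diff_gene(tr_a, tr_b, g)$r
  expect_equal(shape_diff_gene(tr_a, tr_a, g)$r, 1)
  expect_equal(shape_diff_gene(tr_a, normalize_rpm(tr_a), g)$r, 1,
               tolerance = 1e-12)
  for (k in c(0.001, 0.37, 42, 1e6)) {
    r <- shape_diff_gene(scale_track(tr_a, k),
                         scale_track(tr_b, 1 / k), g)$r
    expect_equal(r, r0, tolerance = 1e-9)
  }
  # symmetry
  expect_equal(shape_diff_gene(tr_b, tr_a, g)$r, r0, tolerance = 1e-12)
})

test_that("a severely disrupted gene body drops the correlation", {
  cfg <- sim_config(seed = 7, n_genes = 1,
                    gene_length_range = c(1500, 1500),
                    intron_fraction = 0)
  sim <- simulate_annotation(cfg)
  g <- sim$annotation$genes[[1]]
  cl <- sim$annotation$chrom_sizes[[1]]
  d_wt <- nucleosome_density(g, cfg, chrom_len = cl)
  d_mut <- nucleosome_density(
    g, cfg, perturbation_spec("chd1_body_disruption", 1), chrom_len = cl)
  rd_wt <- sample_reads(d_wt, 5000, cfg, seed = 7, chrom_len = cl)
  rd_mut <- sample_reads(d_mut, 5000, cfg, seed = 8, chrom_len = cl)
  # dyad-centred coverage, the convention for nucleosome positioning
  tr_wt <- coverage_from_alignments(rd_wt, sim$annotation$chrom_sizes,
                                    mode = "midpoint")
  tr_mut <- coverage_from_alignments(rd_mut, sim$annotation$chrom_sizes,
                                     mode = "midpoint")
  r <- shape_diff_gene(tr_wt, tr_mut, g)$r
  expect_lt(r, 0.5)
  # while two samplings of the same intact density stay similar
  rd_wt2 <- sample_reads(d_wt, 5000, cfg, seed = 9, chrom_len = cl)
  tr_wt2 <- coverage_from_alignments(rd_wt2, sim$annotation$chrom_sizes,
                                     mode = "midpoint")
  expect_gt(shape_diff_gene(tr_wt, tr_wt2, g)$r, r)
})

test_that("genome-wide iteration yields one row per gene, order-stable", {
  sim <- build_scenario("null", sim_config(seed = 3, n_genes = 25,
                                           depth = 3e4))
  fit <- shape_diff(sim$tracks$a, sim$tracks$a, sim$annotation)
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 25)
  ok <- tab$status == "ok"
  expect_true(all(abs(tab$r[ok] - 1) < 1e-12))
  expect_true(all(is.na(tab$r[!ok])))

  # permuting the gene order permutes rows, values unchanged
  perm <- sample(names(sim$annotation$genes))
  ann2 <- genome_annotation(sim$annotation$genes[perm],
                            sim$annotation$chrom_sizes)
  fit2 <- shape_diff(sim$tracks$a, sim$tracks$b, sim$annotation)
  fit3 <- shape_diff(sim$tracks$a, sim$tracks$b, ann2)
  t2 <- as.data.frame(fit2); t3 <- as.data.frame(fit3)
  expect_identical(t3$gene_id, perm)
  expect_equal(t3[order(t3$gene_id), ], t2[order(t2$gene_id), ],
               ignore_attr = TRUE)

  expect_error(shape_diff(sim$tracks$a, sim$tracks$b,
                          genome_annotation(list(),
                                            c(chrSim = 100))),
               "empty")
})

test_that("short genes are skipped with an explanatory status", {
  tr <- toy_track(rpois(200, 5))
  short <- gene_model("s", "chrI", 10, 40, "+")  # 3 bins < min_bins
  res <- shape_diff_gene(tr, tr, short)
  expect_identical(res$status, "too_short")
  expect_true(is.na(res$r))
})

test_that("gene-set summaries report n, medians and threshold counts", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    r = c(0.2, 0.4, 0.9, NA),
                    status = c("ok", "ok", "ok", "degenerate_a"))
  s <- summarize_gene_sets(tab, list(s1 = c("a", "b", "c")),
                           threshold = 0.6)
  expect_equal(s$median_r, 0.4, tolerance = 1e-12)
  expect_equal(s$n, 3)

  tab2 <- data.frame(gene_id = c("a", "b", "c", "d"),
                     r = c(0.2, 0.61, 0.9, NA),
                     status = c("ok", "ok", "ok", "degenerate_a"))
  s2 <- summarize_gene_sets(tab2, list(all = tab2$gene_id),
                            threshold = 0.6)
  expect_equal(s2$n_above_threshold, 2)  # the NA gene never counts
  expect_equal(s2$n, 3)

  # disjoint sets partition the ok rows
  s3 <- summarize_gene_sets(tab, list(x = c("a", "d"), y = c("b", "c")))
  expect_equal(sum(s3$n), 3)
  expect_warning(summarize_gene_sets(tab, list(z = c("a", "nope"))),
                 "unknown gene id")
  s4 <- suppressWarnings(summarize_gene_sets(tab, list(z = "nope")))
  expect_equal(s4$n, 0)
  expect_true(is.na(s4$median_r))
})

test_that("correlation tables round-trip through the TSV writer", {
  sim <- build_scenario("null", sim_config(seed = 5, n_genes = 10,
                                           depth = 2e4))
  fit <- shape_diff(sim$tracks$a, sim$tracks$b, sim$annotation)
  f <- tempfile(fileext = ".tsv")
  write_correlation_table(fit, f)
  expect_match(readLines(f, n = 1), "^#gene_id\t")
  back <- read_correlation_table(f)
  expect_equal(back$r, fit$table$r, tolerance = 1e-12)
  expect_identical(back$gene_id, fit$table$gene_id)
})
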