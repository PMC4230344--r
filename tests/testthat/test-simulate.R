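test_that("annotation simulation is deterministic and respects geometry", {
  cfg <- sim_config(seed = 4, n_genes = 50, intron_fraction = 0.5)
  a <- simulate_annotation(cfg)
  b <- simulate_annotation(cfg)
  expect_identical(a, b)

  genes <- a$annotation$genes
  expect_length(genes, 50)
  # non-overlapping with >= 500 bp gaps, alternating strands
  starts <- vapply(genes, `[[`, numeric(1), "start")
  ends <- vapply(genes, `[[`, numeric(1), "end")
  expect_true(all(starts[-1] - ends[-50] >= 500))
  expect_identical(unique(vapply(genes, `[[`, character(1), "strand")),
                   c("+", "-"))
  # introns single, in the 5' half
  for (g in genes) {
    if (!has_intron(g)) next
    expect_equal(nrow(g$introns), 1)
    mid <- (g$start + g$end) / 2
    if (g$strand == "+") expect_lt(g$introns[1, 2], mid)
    else expect_gt(g$introns[1, 1], mid)
  }
})

test_that("intron fraction 0 and 1 are honoured exactly", {
  none <- simulate_annotation(sim_config(seed = 1, n_genes = 10,
                                         intron_fraction = 0))
  expect_false(any(vapply(none$annotation$genes, has_intron,
                          logical(1))))
  all_in <- simulate_annotation(sim_config(seed = 1, n_genes = 10,
                                           intron_fraction = 1))
  expect_true(all(vapply(all_in$annotation$genes, has_intron,
                         logical(1))))
})

test_that("a too-small chromosome is rejected with the required minimum", {
  expect_error(simulate_annotation(sim_config(seed = 1, n_genes = 100,
                                              chrom_length = 1000)),
               "need at least")
})

test_that("densities are normalized and perturbation endpoints behave", {
  cfg <- sim_config(seed = 2, n_genes = 6, intron_fraction = 1)
  sim <- simulate_annotation(cfg)
  cl <- sim$annotation$chrom_sizes[[1]]
  for (g in sim$annotation$genes) {
    for (d in list(nucleosome_density(g, cfg, chrom_len = cl),
                   polymerase_density(g, "ser5_like", cfg,
                                      chrom_len = cl),
                   polymerase_density(g, "ser2_like", cfg,
                                      chrom_len = cl))) {
      expect_equal(sum(d$values), 1, tolerance = 1e-9)
      expect_true(all(d$values >= 0))
    }
  }
  g <- sim$annotation$genes[[1]]
  base <- nucleosome_density(g, cfg, chrom_len = cl)
  s0 <- nucleosome_density(g, cfg, perturbation_spec("none"),
                           chrom_len = cl)
  expect_equal(s0$values, base$values)
  z <- nucleosome_density(g, cfg,
                          perturbation_spec("chd1_body_disruption", 0),
                          chrom_len = cl)
  expect_equal(z$values, base$values)

  # severity 1: flat from midway between +1 and +2 to the PAS
  s1 <- nucleosome_density(g, cfg,
                           perturbation_spec("chd1_body_disruption", 1),
                           chrom_len = cl)
  region_lo <- 75 + cfg$nucleosome_spacing / 2
  gpos <- s1$start:(s1$end - 1)
  t <- if (g$strand == "+") gpos - g$start else (g$end - 1) - gpos
  inreg <- t >= region_lo & t < (g$end - g$start)
  expect_lt(diff(range(s1$values[inreg])), 1e-6 * mean(s1$values[inreg]))
  # -1/+1 region untouched
  expect_equal(s1$values[t < region_lo & t > -300][1:50],
               base$values[t < region_lo & t > -300][1:50],
               tolerance = 1e-6)
})

test_that("unperturbed array autocorrelation peaks at the spacing", {
  cfg <- sim_config(seed = 2, n_genes = 2, intron_fraction = 0,
                    gene_length_range = c(2000, 2400))
  sim <- simulate_annotation(cfg)
  g <- sim$annotation$genes[[1]]
  d <- nucleosome_density(g, cfg,
                          chrom_len = sim$annotation$chrom_sizes[[1]])
  gpos <- d$start:(d$end - 1)
  t <- if (g$strand == "+") gpos - g$start else (g$end - 1) - gpos
  body <- d$values[order(t)][sort(t) >= 75 & sort(t) < (g$end - g$start)]
  ac <- acf(body, lag.max = 250, plot = FALSE)$acf[-1]
  # first local maximum of the non-zero-lag autocorrelation
  peaks <- which(diff(sign(diff(ac))) == -2) + 1
  expect_lt(abs(peaks[1] - cfg$nucleosome_spacing), 3)
})

test_that("polymerase modes are 5'- vs 3'-biased and stall adds density", {
  cfg <- sim_config(seed = 6, n_genes = 8, intron_fraction = 1)
  sim <- simulate_annotation(cfg)
  cl <- sim$annotation$chrom_sizes[[1]]
  for (g in sim$annotation$genes) {
    tmean <- function(d) {
      gpos <- d$start:(d$end - 1)
      t <- if (g$strand == "+") gpos - g$start else (g$end - 1) - gpos
      sum(t * d$values)
    }
    m5 <- tmean(polymerase_density(g, "ser5_like", cfg, chrom_len = cl))
    m2 <- tmean(polymerase_density(g, "ser2_like", cfg, chrom_len = cl))
    expect_lt(m5, m2)
  }
  g <- sim$annotation$genes[[1]]
  base <- polymerase_density(g, "ser5_like", cfg, chrom_len = cl)
  stalled <- polymerase_density(
    g, "ser5_like", cfg,
    perturbation_spec("intron3_stall_release", 1), chrom_len = cl)
  anchor <- intron_anchor_points(g, "three_prime_end")$position[1]
  i <- anchor - base$start + 1
  expect_gt(stalled$values[i], base$values[i])

  # stall on an intron-less gene is a documented no-op
  g0 <- gene_model("g0", g$chrom, g$start, g$end, g$strand)
  d0 <- polymerase_density(g0, "ser5_like", cfg, chrom_len = cl)
  d0s <- polymerase_density(
    g0, "ser5_like", cfg,
    perturbation_spec("intron3_stall_release", 1), chrom_len = cl)
  expect_equal(d0s$values, d0$values)
})

test_that("the upstream shift translates the density 5'-ward on both strands", {
  cfg <- sim_config(seed = 6, n_genes = 4, intron_fraction = 1)
  sim <- simulate_annotation(cfg)
  cl <- sim$annotation$chrom_sizes[[1]]
  for (g in sim$annotation$genes[1:2]) {
    base <- polymerase_density(g, "ser5_like", cfg, chrom_len = cl)
    sh <- polymerase_density(
      g, "ser5_like", cfg,
      perturbation_spec("ser5p_upstream_shift", shift_bp = 80),
      chrom_len = cl)
    gpos <- base$start:(base$end - 1)
    t <- if (g$strand == "+") gpos - g$start else (g$end - 1) - gpos
    tmean <- function(d) sum(t * d$values)
    expect_lt(tmean(sh), tmean(base))
    expect_equal(abs(tmean(sh) - tmean(base)), 80, tolerance = 5)
  }
})

test_that("read sampling is seeded, truncated, and converges to the density", {
  cfg <- sim_config(seed = 1, n_genes = 1)
  d <- structure(list(chrom = "chrI", start = 1000, end = 3000,
                      values = dnorm(1:2000, 1000, 120) /
                        sum(dnorm(1:2000, 1000, 120))),
                 class = "occupancy_density")
  expect_equal(nrow(sample_reads(d, 0, cfg, seed = 1)), 0)
  r1 <- sample_reads(d, 2000, cfg, seed = 5, chrom_len = 5000)
  r2 <- sample_reads(d, 2000, cfg, seed = 5, chrom_len = 5000)
  expect_identical(r1, r2)
  len <- r1$end - r1$start
  expect_true(all(len >= 100 & len <= 250))

  big <- sample_reads(d, 1e5, cfg, seed = 6, chrom_len = 5000)
  mids <- floor((big$start + big$end) / 2)
  true_mean <- sum((d$start:(d$end - 1)) * d$values)
  expect_lt(abs(mean(mids) - true_mean), 3 * 120 / sqrt(1e5) + 1)

  # empirical midpoint distribution close to the density (KS distance)
  emp <- ecdf(mids)(d$start:(d$end - 1))
  expect_lt(max(abs(emp - cumsum(d$values))), 0.01)
})

test_that("scenario construction is deterministic with labelled truth", {
  cfg <- sim_config(seed = 13, n_genes = 20, depth = 2e4)
  a <- build_scenario("chd1_like", cfg)
  b <- build_scenario("chd1_like", cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 20)
  expect_equal(sum(a$truth$disrupted), 10)
  expect_true(all(a$truth$severity[a$truth$disrupted] >= 0.6))
  expect_true(all(c("wt", "mut") %in% names(a$tracks)))
  expect_identical(a$tracks$wt$normalized, "rpm")

  ex <- build_scenario("exchange", cfg)
  expect_setequal(names(ex$tracks),
                  c("flag_wt", "myc_wt", "flag_mut", "myc_mut"))
  expect_error(build_scenario("bogus", cfg), "valid")
})

test_that("SAM and BED serializations of reads round-trip", {
  cfg <- sim_config(seed = 3, n_genes = 5, depth = 2000)
  sc <- build_scenario("null", cfg)
  rd <- sc$reads$a[1:200, ]
  cs <- sc$annotation$chrom_sizes

  fs <- tempfile(fileext = ".sam")
  write_sam(rd, cs, fs)
  back_sam <- read_alignments(fs)
  expect_equal(back_sam$start, rd$start)
  expect_equal(back_sam$end, rd$end)
  expect_equal(back_sam$strand, rd$strand)
  expect_equal(back_sam$mapq, rd$mapq)

  fb <- tempfile(fileext = ".bed")
  write_bed6(rd, fb)
  back_bed <- read_alignments(fb)
  expect_equal(back_bed$start, rd$start)
  expect_equal(back_bed$end, rd$end)
  expect_equal(back_bed$mapq, rd$mapq)
})
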