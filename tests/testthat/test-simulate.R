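test_that("all generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 9)
  expect_identical(gen_reference_population(cfg),
                   gen_reference_population(cfg))
  truth <- gen_individual_truth(cfg, 1)
  expect_identical(truth, gen_individual_truth(cfg, 1))
  expect_identical(gen_technical_replicates(truth, 4, cfg),
                   gen_technical_replicates(truth, 4, cfg))
  expect_identical(gen_paired_wgbs_array(truth, cfg),
                   gen_paired_wgbs_array(truth, cfg))
  expect_identical(gen_intensities(truth, 1, 0.2, cfg),
                   gen_intensities(truth, 1, 0.2, cfg))
})

test_that("reference population collapses to locus means in the zero-noise limit", {
  cfg <- sim_config(n_loci = 200, n_reference_samples = 5,
                    population_sd = 1e-12, wide_population_sd = 1e-12,
                    seed = 3)
  pop <- gen_reference_population(cfg)
  expect_lt(max(apply(pop, 1, function(x) diff(range(x)))), 1e-9)
})

test_that("reference population has unimodal per-locus distributions", {
  # modes placed away from [0, 1] so the boundary truncation atoms do not
  # register as extra density peaks
  cfg <- sim_config(n_loci = 5, n_reference_samples = 2000,
                    hypo_mode = 0.2, hyper_mode = 0.8,
                    wide_fraction = 0, seed = 5)
  pop <- gen_reference_population(cfg)
  n_modes <- function(x) {
    # oversmoothed kernel density: sampling wiggle must not count as a mode
    d <- stats::density(x, adjust = 3)
    peaks <- which(diff(sign(diff(d$y))) == -2) + 1
    sum(d$y[peaks] > 0.1 * max(d$y))
  }
  expect_true(all(apply(pop, 1, n_modes) == 1))
})

test_that("default population IQR distribution peaks near 0.03", {
  cfg <- sim_config(n_loci = 10000, seed = 7)
  ref <- build_reference(gen_reference_population(cfg))
  s <- summarize_iqr(ref)
  expect_gte(s$mode, 0.02)
  expect_lte(s$mode, 0.04)
})

test_that("technical replicates reproduce the truth exactly without noise", {
  cfg <- sim_config(n_loci = 100, replicate_noise_sd = 0,
                    outlier_rate = 0, seed = 2)
  truth <- runif(100)
  names(truth) <- sprintf("cg%03d", 1:100)
  reps <- gen_technical_replicates(truth, 3, cfg)
  for (j in 1:3) expect_equal(unname(reps[, j]), unname(truth))
})

test_that("replicate noise magnitude matches the half-normal closed form", {
  # mean |replicate - truth| for additive N(0, sd) noise is sd * sqrt(2/pi)
  cfg <- sim_config(n_loci = 10000, replicate_noise_sd = 0.01,
                    outlier_rate = 0, seed = 8)
  truth <- rep(0.5, 10000)  # far from [0,1] so truncation never bites
  names(truth) <- sprintf("cg%05d", 1:10000)
  reps <- gen_technical_replicates(truth, 2, cfg)
  observed <- mean(abs(reps - truth))
  expected <- 0.01 * sqrt(2 / pi)
  expect_lt(abs(observed - expected) / expected, 0.05)
})

test_that("six technical replicates mirror the precision study design", {
  cfg <- small_config()
  truth <- gen_individual_truth(cfg, 1)
  reps <- gen_technical_replicates(truth, 6, cfg)
  expect_equal(ncol(reps), 6L)
})

test_that("paired WGBS/array reduces to the identity in the noiseless limit", {
  cfg <- sim_config(n_loci = 50, array_intercept = 0, array_slope = 1,
                    array_noise_sd = 0, coverage_mean = 1e6,
                    coverage_sd = 1, seed = 4)
  truth <- seq(0.05, 0.95, length.out = 50)
  names(truth) <- sprintf("cg%03d", 1:50)
  paired <- gen_paired_wgbs_array(truth, cfg)
  expect_equal(unname(paired$array), unname(truth))
  expect_lt(max(abs(paired$wgbs$level - truth)), 5e-3)
})

test_that("WGBS coverage distribution matches the configured parameters", {
  cfg <- sim_config(n_loci = 5000, seed = 6)
  truth <- rep(0.5, 5000)
  names(truth) <- sprintf("cg%05d", 1:5000)
  paired <- gen_paired_wgbs_array(truth, cfg)
  se <- cfg$coverage_sd / sqrt(5000)
  expect_lt(abs(mean(paired$wgbs$coverage) - cfg$coverage_mean),
            2 * cfg$coverage_sd)
  expect_lt(abs(mean(paired$wgbs$coverage) - cfg$coverage_mean), 10 * se)
  expect_true(all(paired$wgbs$coverage >= 1))
})

test_that("contamination depresses total probe intensity monotonically", {
  cfg <- small_config()
  truth <- gen_individual_truth(cfg, 1)
  medians <- vapply(c(0, 0.1, 0.3, 0.5), function(ct) {
    tab <- gen_intensities(truth, 1, ct, cfg)
    probes <- tab[!tab$is_background_control, ]
    stats::median(probes$M + probes$U)
  }, numeric(1))
  expect_true(all(diff(medians) < 0))
})

test_that("fully methylated loci carry only background in the U channel", {
  cfg <- sim_config(n_loci = 2000, seed = 12)
  truth <- rep(1, 2000)
  names(truth) <- sprintf("cg%05d", 1:2000)
  tab <- gen_intensities(truth, 1, 0, cfg)
  probes <- tab[!tab$is_background_control, ]
  expect_lt(abs(mean(probes$U) - cfg$background_mean),
            3 * cfg$background_sd / sqrt(2000))
})

test_that("degenerate contamination decay is rejected", {
  cfg <- small_config()
  truth <- gen_individual_truth(cfg, 1)
  expect_error(gen_intensities(truth, 1, 0.6, cfg), "degenerate")
})

test_that("beta values are recoverable from strong intensities", {
  cfg <- sim_config(n_loci = 3000, seed = 13)
  truth <- gen_individual_truth(cfg, 2)
  tab <- gen_intensities(truth, 1, 0, cfg)
  beta <- betas_from_intensities(tab, cfg$beta_offset)
  expect_equal(names(beta), names(truth))
  expect_lt(mean(abs(beta - truth)), 0.05)
})
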