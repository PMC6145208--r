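test_that("coverage filtering keeps the inclusive [30, 100] window", {
  wgbs <- data.frame(chrom = "chr1", pos = seq(0, 400, by = 100),
                     strand = "+", context = "CpG",
                     level = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     coverage = c(10L, 30L, 50L, 100L, 150L))
  array <- stats::setNames(c(0.15, 0.25, 0.35, 0.45, 0.55),
                           paste("chr1", seq(0, 400, by = 100), "+",
                                 sep = ":"))
  pairs <- filter_comparable_loci(wgbs, array)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$coverage, c(30L, 50L, 100L))
  expect_equal(pairs$y, c(0.2, 0.3, 0.4))

  wgbs0 <- wgbs
  wgbs0$coverage <- 0L
  expect_error(filter_comparable_loci(wgbs0, array), "survive")
})

test_that("coverage filtering matches a brute-force count on synthetic data", {
  cfg <- sim_config(n_loci = 3000, seed = 91)
  truth <- gen_individual_truth(cfg, 1)
  paired <- gen_paired_wgbs_array(truth, cfg)
  pairs <- filter_comparable_loci(paired$wgbs, paired$array, paired$map)
  brute_keep <- paired$wgbs$coverage >= 30 & paired$wgbs$coverage <= 100
  expect_equal(nrow(pairs), sum(brute_keep))
  expect_equal(pairs$probe_id, paired$map$probe_id[brute_keep])
  # realistic coverage spreads drop a substantial share of loci
  expect_lt(nrow(pairs) / nrow(paired$wgbs), 0.9)
})

test_that("accuracy correlation behaves as Pearson r", {
  x <- seq(0.1, 0.9, by = 0.1)
  expect_equal(accuracy_correlation(data.frame(x = x, y = x)), 1)
  expect_equal(accuracy_correlation(data.frame(x = x, y = -x)), -1)
  expect_error(accuracy_correlation(data.frame(x = x[1:2], y = x[1:2])),
               "at least 3")
  expect_error(accuracy_correlation(data.frame(x = x, y = rep(0.5, 9))),
               "variance")
})

test_that("correlation with the gold standard improves with WGBS coverage", {
  truth <- runif(4000)
  names(truth) <- sprintf("cg%04d", seq_along(truth))
  r_at <- vapply(c(5, 80), function(cov_mean) {
    cfg <- sim_config(n_loci = 4000, coverage_mean = cov_mean,
                      coverage_sd = 1, array_intercept = 0,
                      array_slope = 1, array_noise_sd = 0, seed = 92)
    paired <- gen_paired_wgbs_array(truth, cfg)
    stats::cor(paired$array, paired$wgbs$level)
  }, numeric(1))
  expect_gt(r_at[2], r_at[1])
})

test_that("OLS fit and reportable-range cut-offs match closed forms", {
  x <- seq(0.05, 0.95, by = 0.05)
  exact <- data.frame(x = x, y = x)
  fit <- suppressWarnings(fit_reportable_range(exact))
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$R_low, 0)
  expect_equal(fit$R_high, 1)
  expect_equal(fit$adj_r2, 1)

  shifted <- data.frame(x = x, y = -0.0494 + 0.95 * x)
  fit2 <- suppressWarnings(fit_reportable_range(shifted))
  expect_equal(fit2$R_low, 0.0494 / 0.95, tolerance = 1e-10)
  expect_equal(fit2$R_high, 1)  # (1 + 0.0494)/0.95 > 1, clipped

  expect_error(fit_reportable_range(data.frame(x = x, y = -x)),
               "not positive")
  expect_error(fit_reportable_range(exact[1:2, ]), "at least 3")
})

test_that("OLS coefficients agree with the normal-equation oracle", {
  set.seed(93)
  for (rep in 1:10) {
    d <- data.frame(x = runif(50), y = runif(50, 0.2, 0.8))
    d$y <- d$y + 0.5 * d$x  # ensure a positive slope
    fit <- fit_reportable_range(d)
    o <- oracle_ols(d$x, d$y)
    expect_equal(fit$a, unname(o["a"]), tolerance = 1e-10)
    expect_equal(fit$b, unname(o["b"]), tolerance = 1e-10)
    r <- stats::cor(d$x, d$y)
    expect_equal(fit$adj_r2,
                 1 - (1 - r^2) * (nrow(d) - 1) / (nrow(d) - 2),
                 tolerance = 1e-10)
  }
})

test_that("cut-offs are invariant to duplicating every pair", {
  x <- seq(0.1, 0.9, by = 0.1)
  d <- data.frame(x = x, y = -0.03 + 0.9 * x)
  f1 <- suppressWarnings(fit_reportable_range(d))
  f2 <- suppressWarnings(fit_reportable_range(rbind(d, d)))
  expect_equal(f1$R_low, f2$R_low, tolerance = 1e-12)
  expect_equal(f1$R_high, f2$R_high, tolerance = 1e-12)
})

test_that("the iterative trimming mode converges on exact data", {
  x <- seq(0.05, 0.95, by = 0.01)
  d <- data.frame(x = x, y = -0.0494 + 0.95 * x)
  fit <- suppressWarnings(fit_reportable_range(d, iterate = TRUE))
  expect_equal(fit$R_low, 0.0494 / 0.95, tolerance = 1e-3)
  expect_lte(fit$iterations, 20)
})

test_that("per-sample ranges aggregate to the largest overlapping interval", {
  lows <- c(0.051, 0.034, 0.043, 0.038, 0.052, 0.044, 0.035, 0.028)
  fits <- lapply(lows, function(lo)
    structure(list(R_low = lo, R_high = 1), class = "reportable_fit"))
  expect_equal(aggregate_reportable_range(fits), c(0.052, 1))

  single <- fits[1]
  expect_equal(aggregate_reportable_range(single), c(0.051, 1))

  disjoint <- list(structure(list(R_low = 0.0, R_high = 0.3),
                             class = "reportable_fit"),
                   structure(list(R_low = 0.5, R_high = 1),
                             class = "reportable_fit"))
  expect_error(aggregate_reportable_range(disjoint), "overlap")
})
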