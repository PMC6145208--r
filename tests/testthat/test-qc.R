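test_that("detection p-values match the normal-background closed form", {
  # controls constructed with pooled mean exactly 200 and sd exactly 20
  tab <- manual_intensity_table(c(400, 400 + 3 * 20 * sqrt(2), 440))
  p <- detection_pvalues(tab)
  expect_equal(unname(p[1]), 0.5)
  expect_equal(unname(p[2]), stats::pnorm(3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(p[2]), 0.00135, tolerance = 2e-3)
  expect_equal(unname(p[3]), stats::pnorm(sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(p[3]), 0.0786, tolerance = 1e-3)
  # the z = sqrt(2) probe fails at the 0.01 cutoff
  expect_true(failed_probe_mask(p)$failed[3])

  expect_error(detection_pvalues(manual_intensity_table(400, n_controls = 4)),
               "background-control")
  degen <- manual_intensity_table(400)
  degen$M[degen$is_background_control] <- 200
  degen$U[degen$is_background_control] <- 200
  expect_error(detection_pvalues(degen), "degenerate")
})

test_that("detection p-values on pure background are approximately uniform", {
  cfg <- sim_config(n_loci = 10000, n_background = 2000, seed = 81)
  truth <- rep(0.5, 10000)
  names(truth) <- sprintf("cg%05d", 1:10000)
  tab <- gen_intensities(truth, concentration_fraction = 0,
                         contamination_fraction = 0, cfg)
  p <- detection_pvalues(tab)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("failed-probe and failed-sample rules use strict inequalities", {
  m <- failed_probe_mask(rep(0.005, 10))
  expect_equal(m$fraction, 0)
  expect_false(any(failed_probe_mask(c(0.01, 0.0099))$failed))
  expect_equal(failed_probe_mask(c(rep(0.001, 57), rep(0.5, 3)))$fraction,
               0.05)
  expect_error(failed_probe_mask(numeric(0)), "empty")

  expect_true(sample_sensitivity_pass(0.05))   # boundary passes
  expect_false(sample_sensitivity_pass(0.051))
  expect_true(sample_sensitivity_pass(0))
})

test_that("MU is the log2 geometric mean of median channel intensities", {
  tab <- data.frame(probe_id = c("a", "b", "c", "n1"),
                    M = c(1024, 1024, 1024, 200),
                    U = c(1024, 1024, 1024, 200),
                    is_background_control = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(mu_statistic(tab), 10)
  tab$M[1:3] <- 512
  tab$U[1:3] <- 2048
  expect_equal(mu_statistic(tab), 10)  # geometric-mean symmetry
  # control rows are excluded from the medians
  tab$M[4] <- 1e6
  expect_equal(mu_statistic(tab), 10)
  tab$M[1:3] <- 0
  expect_error(mu_statistic(tab), "positive")
})

test_that("MU is monotone in both channel medians", {
  base <- data.frame(probe_id = sprintf("p%d", 1:9),
                     M = seq(100, 900, by = 100),
                     U = seq(100, 900, by = 100),
                     is_background_control = FALSE)
  up <- base
  up$M <- up$M * 2
  expect_gt(mu_statistic(up), mu_statistic(base))
  up2 <- base
  up2$U <- up2$U + 500
  expect_gt(mu_statistic(up2), mu_statistic(base))
})

test_that("normal aberrant-count range matches the normal approximation", {
  counts <- c(10, 12, 14, 9, 11, 13, 10, 12)
  r <- normal_aberrant_range(counts)
  expect_equal(r[1], mean(counts) - stats::qnorm(0.995) * stats::sd(counts))
  expect_equal(r, c(7.03, 15.72), tolerance = 1e-2)
  expect_true(40 < r[1] || 40 > r[2])  # a count of 40 falls outside

  expect_equal(normal_aberrant_range(rep(7, 5)), c(7, 7))
  expect_error(normal_aberrant_range(c(1, 2)), "at least 3")
})

test_that("the learned MU threshold is the midpoint max-margin separator", {
  expect_equal(learn_mu_threshold(c(9.0, 9.5), c(10.4, 11.0)), 9.95)
  eps <- 1e-6
  expect_equal(learn_mu_threshold(9.96 - eps, 9.96 + eps), 9.96)
  expect_error(learn_mu_threshold(c(9, 10.5), c(10.4, 11)),
               "not separable")

  set.seed(82)
  for (rep in 1:20) {
    cut <- runif(1, 8, 12)
    failed <- cut - runif(sample(1:6, 1), 0.05, 2)
    passed <- cut + runif(sample(1:6, 1), 0.05, 2)
    expect_equal(learn_mu_threshold(failed, passed),
                 oracle_margin_threshold(failed, passed))
  }
})

test_that("contamination inflates aberrant counts until MU filtering removes them", {
  cfg <- small_config(seed = 83)
  ref <- build_reference(gen_reference_population(cfg))
  grid <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  res <- do.call(rbind, lapply(1:4, function(s) {
    truth <- gen_individual_truth(cfg, 300 + s)
    do.call(rbind, lapply(seq_along(grid), function(k) {
      tab <- gen_intensities(truth, 1, grid[k], cfg, 300 + 10 * s + k)
      beta <- betas_from_intensities(tab, cfg$beta_offset)
      data.frame(level = grid[k],
                 count = aberrant_count(
                   call_sample(beta, ref, 0.2, 0.052, "x")),
                 mu = mu_statistic(tab))
    }))
  }))
  # MU decreases monotonically along each sample's contamination series
  for (s in 0:3) {
    mus <- res$mu[(s * 6 + 1):(s * 6 + 6)]
    expect_true(all(diff(mus) < 0))
  }
  # counts correlate positively with contamination before MU filtering
  expect_gt(stats::cor(res$count, res$level, method = "spearman"), 0.3)
  expect_gt(mean(res$count[res$level == 0.5]), 10)
  # among high-MU (passing) replicates the association is gone
  nr <- normal_aberrant_range(res$count[res$level == 0])
  failed <- res$count < nr[1] | res$count > nr[2]
  thr <- learn_mu_threshold(res$mu[failed], res$mu[!failed])
  keep <- res$mu >= thr
  if (stats::sd(res$count[keep]) > 0 && stats::sd(res$level[keep]) > 0) {
    ct <- suppressWarnings(stats::cor.test(res$count[keep],
                                           res$level[keep]))
    expect_true(is.na(ct$p.value) || ct$p.value > 0.05)
  } else {
    # counts among passing replicates are flat: trivially uncorrelated
    expect_true(TRUE)
  }
})
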