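test_that("off-curve scaling maps T0 to 1 and vehicle level to 0", {
  expect_equal(scale_profile(1.5, 1.5), 1)     # no recovery
  expect_equal(scale_profile(1.0, 1.5), 0)     # full recovery
  expect_equal(scale_profile(1.25, 1.5), 0.5)  # hand arithmetic
  # mirrored destabilized protein behaves identically
  expect_equal(scale_profile(0.833333333333333, 2 / 3), 0.5)
  expect_error(scale_profile(1.2, 1 + 1e-9), "no measurable shift")
})

test_that("model routing follows the last-time-point mean with exclusive boundary", {
  prof <- function(last) scaled_profile(
    "P", default_grid, matrix(c(1, 0.9, 0.8, 0.7, last), 5, 3))
  expect_equal(select_model(prof(0.55)), "exponential")
  expect_equal(select_model(prof(0.60)), "linear")
  expect_equal(select_model(prof(0.95)), "linear")
  short <- scaled_profile("P", c(0, 1), matrix(1, 2, 3))
  expect_error(select_model(short), "at least 3")
})

test_that("exponential fits recover noiseless parameters", {
  S <- (1 - 0.2) * exp(-0.5 * default_grid) + 0.2
  prof <- scaled_profile("P", default_grid, matrix(rep(S, 3), ncol = 3))
  fit <- fit_offcurve(prof)
  expect_equal(fit$model, "exponential")
  expect_equal(fit$k_d, 0.5, tolerance = 1e-6)
  expect_equal(fit$b, 0.2, tolerance = 1e-6)
  expect_equal(fit$residence_time_h, 2, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat profiles route linear with zero slope and no residence time", {
  prof <- scaled_profile("P", default_grid, matrix(1, 5, 3))
  fit <- fit_offcurve(prof)
  expect_equal(fit$model, "linear")
  expect_equal(fit$k_d, 0)
  expect_true(is.na(fit$residence_time_h))
})

test_that("noisy fits recover the decay rate within 20 percent", {
  set.seed(77)
  S <- (1 - 0.1) * exp(-0.5 * default_grid) + 0.1
  noisy <- matrix(rep(S, 3), ncol = 3) * matrix(rnorm(15, 1, 0.05), ncol = 3)
  fit <- fit_offcurve(scaled_profile("P", default_grid, noisy),
                      model = "exponential")
  expect_lt(abs(fit$k_d - 0.5) / 0.5, 0.2)
})

test_that("AUC is the per-replicate sum over the time course", {
  prof1 <- scaled_profile("P", default_grid, matrix(1, 5, 3))
  expect_equal(compute_auc(prof1)$auc, rep(5, 3))
  prof0 <- scaled_profile("P", default_grid, matrix(0, 5, 3))
  expect_equal(compute_auc(prof0)$mean, 0)

  # term-by-term evaluation of exp(-0.5 t) over the default grid
  terms <- c(1, 0.47237, 0.22313, 0.03020, 0.0000061)
  S <- exp(-0.5 * default_grid)
  prof <- scaled_profile("P", default_grid, matrix(rep(S, 3), ncol = 3))
  a <- compute_auc(prof)
  expect_equal(a$mean, sum(terms), tolerance = 1e-4)
  expect_equal(a$mean, 1.72570, tolerance = 1e-4)
  expect_equal(a$sd, 0)

  # trapezoid option weights by actual spacings
  tz <- compute_auc(prof, method = "trapezoid")
  expect_equal(tz$mean,
               sum(diff(default_grid) * (head(S, -1) + tail(S, -1)) / 2))

  bad <- scaled_profile("P", default_grid,
                        matrix(c(1, NA, rep(0.5, 13)), 5, 3))
  expect_error(compute_auc(bad), "missing")
})

test_that("AUC normalization divides by the maximum", {
  expect_equal(normalize_auc(c(5, 2.5, 1)), c(1, 0.5, 0.2))
  expect_equal(normalize_auc(3), 1)
  expect_equal(normalize_auc(c(4, 4, 2)), c(1, 1, 0.5))
  expect_error(normalize_auc(c(0, 0)), "zero")
})

test_that("correlations are Pearson with degenerate flagging", {
  x <- c(1, 2, 3)
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  # hand computation: cov(x, y)/ (sd sd) for y = {1, 3, 2}
  expect_equal(correlate(x, c(1, 3, 2)), 0.5)
  expect_warning(r <- correlate(x, c(1, 1, 1)), "zero variance")
  expect_true(is.na(r))
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
})

test_that("AUC decreases strictly with the decay rate at fixed asymptote", {
  kds <- seq(0.05, 2, length.out = 12)
  aucs <- sapply(kds, function(k) {
    S <- (1 - 0.2) * exp(-k * default_grid) + 0.2
    compute_auc(scaled_profile("P", default_grid, matrix(S, ncol = 1)))$mean
  })
  expect_true(all(diff(aucs) < 0))
})

test_that("stabilized and destabilized twins give identical kinetics", {
  d <- experiment_design(noise_cv = 0, seed = 17)
  pars <- list(up = binding_params(log2(1.5), k_d = 0.4, b = 0.1),
               down = binding_params(log2(2 / 3), k_d = 0.4, b = 0.1))
  qm <- simulate_offcurve_experiment(pars, d)
  kin <- fit_kinetics(normalize_to_vehicle(qm))
  expect_equal(kin$k_d[1], kin$k_d[2], tolerance = 1e-8)
  expect_equal(kin$b[1], kin$b[2], tolerance = 1e-8)
  expect_equal(kin$auc_mean[1], kin$auc_mean[2], tolerance = 1e-10)
})

test_that("proteins without a T0 shift are excluded from kinetics", {
  d <- experiment_design(noise_cv = 0, seed = 19)
  pars <- list(null = binding_params(0, k_d = 1),
               tgt = binding_params(0.8, k_d = 0.5))
  kin <- fit_kinetics(normalize_to_vehicle(
    simulate_offcurve_experiment(pars, d)))
  expect_equal(kin$flag[kin$protein == "null"], "no_t0_shift")
  expect_equal(kin$k_d[kin$protein == "tgt"], 0.5, tolerance = 1e-6)
})
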