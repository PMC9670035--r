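test_that("off-curve simulation honors the engagement model", {
  d <- experiment_design(noise_cv = 0, seed = 5)

  # no effect: treated equals vehicle everywhere
  qm <- simulate_offcurve_experiment(list(binding_params(0, k_d = 1)), d)
  drug <- qm$values[, qm$meta$condition == "drug"]
  veh <- qm$values[, qm$meta$condition == "vehicle"]
  expect_equal(unname(drug), unname(veh))

  # no dissociation: constant treated/vehicle ratio of 2^delta_sm
  qm <- simulate_offcurve_experiment(list(binding_params(0.7, k_d = 0)), d)
  fc <- normalize_to_vehicle(qm)
  expect_equal(fc$fc, rep(2^0.7, nrow(fc)))

  # half-life construction: k_d = ln(2)/1.5 gives E(1.5) = 0.5 exactly
  p <- binding_params(1, k_d = log(2) / 1.5, b = 0)
  expect_equal(engagement(p, 1.5), 0.5)
  qm <- simulate_offcurve_experiment(list(p), d)
  expect_equal(unname(qm$truth$engagement[1L, "t1.5"]), 0.5)
})

test_that("off-curve simulation validates its inputs", {
  d <- experiment_design()
  expect_error(simulate_offcurve_experiment(list(), d), "at least one")
  expect_error(experiment_design(noise_cv = -0.1), "non-negative")
  expect_error(experiment_design(time_points = c(1, 3)), "start at 0")
  expect_error(experiment_design(time_points = c(0, 3, 3)), "increasing")
  expect_error(experiment_design(n_replicates = 1), "at least 2")
  expect_error(binding_params(1, k_d = -1), "k_d")
  expect_error(binding_params(1, k_d = 1, b = 1.2), "b")
  expect_error(binding_params(1, k_d = 1, ec50 = 0), "ec50")
})

test_that("conc-PISA pooling matches the Hill occupancy mean", {
  pars <- function(ec50) list(binding_params(0.8, k_d = 1, ec50 = ec50))
  d <- experiment_design(noise_cv = 0, seed = 2)

  # saturating and vanishing limits of the 7-point series
  qm <- simulate_concpisa(pars(1e-15), d)
  expect_lt(abs(qm$truth$pooled_engagement - 1), 1e-3)
  qm <- simulate_concpisa(pars(1), d)
  expect_lt(abs(qm$truth$pooled_engagement - 0), 2e-3)

  # term-by-term oracle at ec50 = 20 nM, hill = 1
  conc <- c(2e-6, 2e-7, 2e-8, 2e-9, 2e-10, 2e-11, 2e-12)
  theta_oracle <- conc / (conc + 20e-9)
  expect_equal(mean(theta_oracle), 0.3573, tolerance = 1e-4)
  qm <- simulate_concpisa(pars(20e-9), d)
  expect_equal(unname(qm$truth$pooled_engagement), mean(theta_oracle))
  # the pooled column is the mean of the per-concentration abundances
  m <- qm$meta
  per_conc <- qm$values[1L, m$condition == "drug" & !m$pooled & m$replicate == 1]
  pooled <- qm$values[1L, m$pooled & m$replicate == 1]
  expect_equal(unname(pooled), mean(per_conc))
  # and downstream scaling recovers the mean occupancy exactly
  fc <- normalize_to_vehicle(qm)
  pooled_fc <- mean(fc$fc[fc$pooled])
  ref_fc <- mean(fc$fc[!fc$pooled & fc$conc_M == max(conc, na.rm = TRUE)],
                 na.rm = TRUE)
  # reference is the top concentration, itself at occupancy theta(2 uM)
  recovered <- scale_compressed(pooled_fc, ref_fc) * theta_oracle[1L]
  expect_equal(recovered, mean(theta_oracle), tolerance = 1e-10)

  expect_error(experiment_design(concentrations = c(2e-6, -1)), "positive")
  d1 <- experiment_design(concentrations = 2e-6)
  expect_error(simulate_concpisa(pars(1e-9), d1), "at least 2")
})

test_that("cResT pooling equals the time average of the off-curve", {
  d <- experiment_design(noise_cv = 0, seed = 9)

  # constant engagement: pooled column equals the T0 column
  qm <- simulate_compressed_rest(list(binding_params(0.9, k_d = 0)), d)
  m <- qm$meta
  expect_equal(unname(qm$values[1L, m$pooled]),
               unname(qm$values[1L, m$condition == "drug" & !m$pooled]))

  # independent sum of the exponential terms at k_d = 0.5, b = 0
  Es <- exp(-0.5 * default_grid)
  expect_equal(sum(Es), 1.72570, tolerance = 1e-5)
  qm <- simulate_compressed_rest(list(binding_params(0.6, k_d = 0.5)), d)
  expect_equal(unname(qm$truth$pooled_engagement), sum(Es) / 5)

  # single-time-point design pools to that point itself
  d1 <- experiment_design(time_points = 0, noise_cv = 0, seed = 9)
  qm <- simulate_compressed_rest(list(binding_params(0.6, k_d = 0.5)), d1)
  m <- qm$meta
  expect_equal(unname(qm$values[1L, m$pooled]),
               unname(qm$values[1L, m$condition == "drug" & !m$pooled]))
})

test_that("simulation is deterministic under a fixed seed", {
  pars <- simulate_target_panel(20, seed = 11)
  d <- experiment_design(noise_cv = 0.1, seed = 42)
  a <- simulate_offcurve_experiment(pars, d)
  b <- simulate_offcurve_experiment(pars, d)
  expect_identical(a$values, b$values)
  expect_identical(simulate_concpisa(pars, d)$values,
                   simulate_concpisa(pars, d)$values)
})

test_that("lognormal noise has the requested CV and unit mean", {
  d <- experiment_design(noise_cv = 0.2, seed = 13)
  qm <- simulate_offcurve_experiment(
    replicate(2000, binding_params(0, k_d = 1), simplify = FALSE), d)
  fc <- normalize_to_vehicle(qm)
  # the ratio of two independent mean-one lognormals at CV c is lognormal
  # with meanlog 0 and sdlog sqrt(2) * sigma, sigma^2 = log(1 + c^2):
  # mean (1 + c^2), sd (1 + c^2) * sqrt((1 + c^2)^2 - 1)
  cc <- 1 + 0.2^2
  expect_equal(mean(fc$fc), cc, tolerance = 0.02)
  expect_equal(stats::sd(fc$fc), cc * sqrt(cc^2 - 1), tolerance = 0.05)
  # per-measurement noise itself is mean-one at the requested CV
  veh <- qm$values[, qm$meta$condition == "vehicle"] / qm$truth$baseline
  expect_equal(mean(veh), 1, tolerance = 0.01)
  expect_equal(stats::sd(veh), 0.2, tolerance = 0.05)
})

test_that("reporter spectrum simulation plants recoverable peaks", {
  mzs <- tmt_channels("tmt10")$mz
  expect_error(simulate_reporter_spectra(rep(1, 10), mzs, ppm_jitter = 20),
               "below 20")
  sim <- simulate_reporter_spectra(matrix(c(100, 0, 50, 200, 10, 30, 40, 60,
                                            70, 80), 1), mzs,
                                   ppm_jitter = 0, n_decoy_peaks = 0, seed = 3)
  rec <- extract_reporters(sim$spectra[[1L]], tmt_channels("tmt10"))
  expect_true(is.na(rec$intensity[2L]))   # zero-intensity channel missing
  expect_equal(rec$intensity[-2L], sim$truth[1, -2])
  # decoys land at least 50 ppm away from every channel
  sim <- simulate_reporter_spectra(matrix(runif(10, 10, 100), 1), mzs,
                                   ppm_jitter = 5, n_decoy_peaks = 200,
                                   seed = 4)
  sp <- sim$spectra[[1L]]
  dist_ppm <- sapply(sp$mz, function(m) min(abs(m - mzs) / mzs) * 1e6)
  expect_true(all(dist_ppm <= 5 | dist_ppm > 50))
})
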