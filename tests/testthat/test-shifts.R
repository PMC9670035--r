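test_that("vehicle normalization pairs by replicate within time point", {
  # identity: treated equals vehicle
  qm <- toy_quant(c(`0` = 1, `3` = 1))
  fc <- normalize_to_vehicle(qm)
  expect_equal(fc$fc, rep(1, nrow(fc)))
  expect_equal(fc$log2fc, rep(0, nrow(fc)))

  # doubling at one time point
  qm <- toy_quant(c(`0` = 1, `3` = 2))
  fc <- normalize_to_vehicle(qm)
  expect_equal(unique(fc$log2fc[fc$time_h == 3]), 1)
  expect_equal(unique(fc$log2fc[fc$time_h == 0]), 0)

  # a shared degradation multiplier cancels
  qm2 <- toy_quant(c(`0` = 1, `3` = 2))
  at24 <- qm2$meta$time_h == 3
  qm2$values[, at24] <- qm2$values[, at24] * 0.5
  expect_equal(normalize_to_vehicle(qm2)$fc, fc$fc)

  # missing partner is rejected with the offending coordinates
  qm3 <- toy_quant(c(`0` = 1, `3` = 2))
  drop <- qm3$meta$sample_id != "vehicle_t3_r2"
  qm4 <- quant_matrix(qm3$values[, drop, drop = FALSE],
                      qm3$meta[drop, ], truth = NULL)
  expect_error(normalize_to_vehicle(qm4), "time 3, replicate 2")
})

test_that("the shift test is a pooled-variance two-sample t-test", {
  # closed-form oracle: pooled t for {1.0,1.1,0.9} vs {0.0,0.1,-0.1}
  g1 <- c(1.0, 1.1, 0.9); g2 <- c(0.0, 0.1, -0.1)
  sp2 <- (2 * var(g1) + 2 * var(g2)) / 4
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (2 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), 4)
  expect_equal(t_oracle, 12.247, tolerance = 1e-4)
  expect_equal(p_oracle, 2.6e-4, tolerance = 0.02)

  res <- test_shift(g1, g2)
  expect_equal(res$t_statistic, t_oracle)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, p_oracle)

  # identical groups: no difference
  res <- test_shift(g1, g1)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  # degenerate: zero pooled variance
  expect_equal(test_shift(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(test_shift(c(2, 2), c(1, 1))$p_value, 0)
  expect_error(test_shift(1, c(1, 2)), "at least 2")
})

test_that("vectorized row t-tests agree with t.test per protein", {
  set.seed(31)
  qm <- simulate_offcurve_experiment(
    simulate_target_panel(25, seed = 31),
    experiment_design(time_points = c(0, 3), noise_cv = 0.1, seed = 31))
  sh <- compute_shifts(qm)
  l2 <- log2(qm$values)
  m <- qm$meta
  for (p in sample(rownames(qm$values), 8)) {
    for (t in c(0, 3)) {
      dcols <- m$sample_id[m$condition == "drug" & m$time_h == t]
      vcols <- m$sample_id[m$condition == "vehicle" & m$time_h == t]
      tt <- t.test(l2[p, dcols], l2[p, vcols], var.equal = TRUE)
      row <- sh[sh$protein == p & sh$time_h == t, ]
      expect_equal(row$p_value, tt$p.value)
      expect_equal(row$t_statistic, unname(tt$statistic))
    }
  }
})

test_that("hit calling applies inclusive lfc and exclusive p thresholds", {
  tab <- data.frame(log2fc = c(0.30, -0.5, 0.6, 0.29, 0.4),
                    p_value = c(0.049, 0.01, 0.05, 0.01, 0.2))
  out <- call_hits(tab)
  expect_equal(out$hit, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$direction[1:2], c(1, -1))
})

test_that("shifts are invariant to global intensity scaling", {
  qm <- simulate_offcurve_experiment(
    simulate_target_panel(15, seed = 5),
    experiment_design(noise_cv = 0.08, seed = 5))
  sh1 <- compute_shifts(qm)
  qm2 <- quant_matrix(qm$values * 37.5, qm$meta)
  sh2 <- compute_shifts(qm2)
  expect_equal(sh1$log2fc, sh2$log2fc)
  expect_equal(sh1$p_value, sh2$p_value)
})

test_that("the t-test is unaffected by permuting replicate labels", {
  qm <- simulate_offcurve_experiment(
    simulate_target_panel(10, seed = 6),
    experiment_design(noise_cv = 0.1, seed = 6))
  sh1 <- compute_shifts(qm)
  m2 <- qm$meta
  # swap replicates 1 and 3 in both conditions at every time point
  m2$replicate <- c(`1` = 3L, `2` = 2L, `3` = 1L)[as.character(m2$replicate)]
  qm2 <- quant_matrix(qm$values, m2)
  sh2 <- compute_shifts(qm2)
  expect_equal(sh1$t_statistic, sh2$t_statistic)
  expect_equal(sh1$p_value, sh2$p_value)
})

test_that("expression normalization corrects for abundance drift", {
  # one protein, expression doubled in the treated cells at t = 3 while
  # solubility is unchanged: corrected fold change halves
  qm <- toy_quant(c(`0` = 1.5, `3` = 1.5))
  expr <- toy_quant(c(`0` = 1, `3` = 2))   # drift in treated cells only
  corrected <- normalize_expression(qm, expr)
  fc_raw <- normalize_to_vehicle(qm)
  fc_cor <- normalize_to_vehicle(corrected)
  expect_equal(unique(fc_cor$fc[fc_cor$time_h == 3]),
               unique(fc_raw$fc[fc_raw$time_h == 3]) / 2)
  expect_equal(unique(fc_cor$fc[fc_cor$time_h == 0]),
               unique(fc_raw$fc[fc_raw$time_h == 0]))

  # identical expression across conditions: output is input up to a
  # per-protein constant
  expr2 <- toy_quant(c(`0` = 1, `3` = 1))
  same <- normalize_expression(qm, expr2)
  expect_equal(same$values / same$values[1, 1],
               qm$values / qm$values[1, 1])

  # zero expression flags and excludes that (protein, sample)
  expr3 <- toy_quant(c(`0` = 1, `3` = 1))
  expr3$values[1, "drug_t3_r1"] <- NA
  expr3 <- quant_matrix(ifelse(is.na(expr3$values), NA, expr3$values),
                        expr3$meta)
  out <- normalize_expression(qm, expr3)
  expect_true(is.na(out$values[1, "drug_t3_r1"]))
  expect_equal(attr(out, "excluded")$sample_id, "drug_t3_r1")

  # complete-case filtering then removes the protein
  expect_equal(nrow(complete_cases(out)$values), 0L)
})
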