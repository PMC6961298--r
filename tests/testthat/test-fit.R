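sch <- default_bvalue_scheme()
b <- sch$b_values

test_that("log-linear mono fit recovers the ADC of noiseless decays", {
  # two points determine the line exactly
  two <- bvalue_scheme(c(0, 1000), c(1L, 1L))
  ft <- fit_mono(signal_mono(two$b_values, 3, 1.2e-3), two)
  expect_equal(ft$params$adc, 1.2e-3)
  expect_equal(ft$params$s0, 3)
  # worked-example ADCs over the full 12-b scheme
  for (adc in c(0.619e-3, 0.993e-3)) {
    ft <- fit_mono(signal_mono(b, 1, adc), sch)
    expect_true(ft$converged)
    expect_lt(abs(ft$params$adc - adc) / adc, 1e-9)
    expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("degenerate signals are flagged instead of fitted", {
  # constant signal: zero slope violates adc > 0
  ft <- fit_mono(rep(5, 12), sch)
  expect_false(ft$converged)
  expect_equal(ft$params$adc, 0, tolerance = 1e-12)
  # any non-positive value makes the log undefined: unfittable
  vals <- signal_mono(b, 1, 1e-3); vals[5] <- 0
  expect_equal(fit_mono(vals, sch)$status, "unfittable")
  expect_false(fit_mono(vals, sch)$converged)
  # increasing signal gives a negative adc estimate, reported unconverged
  expect_false(fit_mono(exp(b * 1e-3), sch)$converged)
})

test_that("mono fit agrees with a brute-force log-scale SSE grid search", {
  set.seed(11)
  for (i in 1:5) {
    adc <- runif(1, 3e-4, 2e-3)
    vals <- signal_mono(b, 1, adc) * exp(rnorm(12, 0, 0.03))
    ft <- fit_mono(vals, sch)
    adc_grid <- seq(ft$params$adc * 0.9, ft$params$adc * 1.1, length.out = 41)
    lns0_grid <- seq(log(ft$params$s0) - 0.05, log(ft$params$s0) + 0.05,
                     length.out = 41)
    gr <- mono_grid_oracle(vals, b, adc_grid, lns0_grid)
    sse_lm <- sum((log(vals) - (log(ft$params$s0) - b * ft$params$adc))^2)
    expect_lte(sse_lm, gr$sse + 1e-12)
    expect_lt(abs(gr$adc - ft$params$adc), diff(adc_grid[1:2]) + 1e-12)
  }
})

test_that("IVIM full fit recovers noiseless parameters", {
  cases <- list(c(d = 0.443e-3, d_star = 6.891e-3, f = 0.25318),
                c(d = 0.608e-3, d_star = 6.891e-3, f = 0.25318),
                c(d = 0.876e-3, d_star = 8.820e-3, f = 0.32356))
  for (cs in cases) {
    vals <- signal_ivim(b, 1, cs[["d"]], cs[["d_star"]], cs[["f"]])
    ft <- fit_ivim(vals, sch, strategy = "full")
    expect_true(ft$converged)
    for (p in names(cs))
      expect_lt(abs(ft$params[[p]] - cs[[p]]) / cs[[p]], 1e-4)
    expect_equal(ft$params$s0, 1, tolerance = 1e-6)
  }
})

test_that("IVIM collapses gracefully when there is no perfusion", {
  vals <- signal_ivim(b, 1, 0.7e-3, 8e-3, 0)
  ft <- fit_ivim(vals, sch)
  expect_lt(ft$params$f, 1e-5)
  mono <- fit_mono(vals, sch)
  expect_equal(ft$params$d, mono$params$adc, tolerance = 1e-6)
})

test_that("segmented IVIM takes D from the perfusion-free segment", {
  vals <- signal_ivim(b, 1, 0.6e-3, 7e-3, 0.2)
  seg <- fit_ivim(vals, sch, strategy = "segmented")
  hi <- b >= 200
  d_hi <- -stats::coef(stats::lm(log(vals[hi]) ~ b[hi]))[[2]]
  expect_equal(seg$params$d, d_hi, tolerance = 1e-10)
  # preconditions: enough b-values on both sides of the threshold
  small <- bvalue_scheme(c(0, 50, 100), c(1L, 1L, 1L))
  expect_error(fit_ivim(signal_mono(c(0, 50, 100), 1, 1e-3), small),
               "spanning")
})

test_that("SEM fit recovers noiseless worked-example parameters", {
  cases <- list(c(ddc = 0.972e-3, alpha = 0.910),
                c(ddc = 1.237e-3, alpha = 0.621))
  for (cs in cases) {
    vals <- signal_sem(b, 1, cs[["ddc"]], cs[["alpha"]])
    ft <- fit_sem(vals, sch)
    expect_true(ft$converged)
    expect_lt(abs(ft$params$ddc - cs[["ddc"]]) / cs[["ddc"]], 1e-4)
    expect_lt(abs(ft$params$alpha - cs[["alpha"]]) / cs[["alpha"]], 1e-4)
  }
  # a Gaussian decay drives alpha to its upper bound with ddc = adc
  ft <- fit_sem(signal_mono(b, 1, 0.8e-3), sch)
  expect_equal(ft$params$alpha, 1, tolerance = 1e-6)
  expect_equal(ft$params$ddc, 0.8e-3, tolerance = 1e-7)
})

test_that("noiseless round-trips hold across the plausible parameter space", {
  # grids spanning the reference group means +/- 2 SD (clipped to valid)
  for (adc in c(0.466, 0.610, 0.980, 1.158) * 1e-3) {
    ft <- fit_mono(signal_mono(b, 1, adc), sch)
    expect_lt(abs(ft$params$adc - adc) / adc, 1e-4)
  }
  for (ddc in c(0.549, 0.831, 1.257, 1.591) * 1e-3)
    for (alpha in c(0.6, 0.826, 0.912, 0.998)) {
      ft <- fit_sem(signal_sem(b, 1, ddc, alpha), sch)
      expect_lt(abs(ft$params$ddc - ddc) / ddc, 1e-4)
      expect_lt(abs(ft$params$alpha - alpha) / alpha, 1e-4)
    }
  for (d in c(0.443, 0.843, 1.313) * 1e-3)
    for (f in c(0.07, 0.25, 0.54)) {
      ft <- fit_ivim(signal_ivim(b, 1, d, 8e-3, f), sch)
      expect_lt(abs(ft$params$d - d) / d, 1e-4)
      expect_lt(abs(ft$params$f - f) / f, 1e-4)
      expect_lt(abs(ft$params$d_star - 8e-3) / 8e-3, 1e-4)
    }
})

test_that("goodness of fit matches hand arithmetic and edge cases", {
  vals <- signal_sem(b, 1, 1e-3, 0.8)
  expect_equal(goodness_of_fit(vals, fit_sem(vals, sch)), 1,
               tolerance = 1e-10)
  # mono fit of a strongly bi-exponential curve leaves residual
  biexp <- signal_ivim(b, 1, 0.4e-3, 20e-3, 0.4)
  expect_lt(fit_mono(biexp, sch)$r_squared, 1)
  # 3-point hand computation: SS_res = 2, SS_tot = 294/9
  expect_equal(goodness_of_fit(c(10, 5, 2), c(9, 6, 2)), 1 - 2 / (294 / 9))
  expect_true(is.na(goodness_of_fit(rep(3, 4), rep(3, 4))))
})

test_that("the SEM fit never undercuts the mono fit (model nesting)", {
  set.seed(21)
  for (i in 1:10) {
    vals <- signal_mono(b, 1, runif(1, 3e-4, 2e-3)) * exp(rnorm(12, 0, 0.02))
    r2_mono <- fit_mono(vals, sch)$r_squared
    r2_sem <- fit_sem(vals, sch)$r_squared
    expect_gte(r2_sem, r2_mono - 1e-8)
  }
})

test_that("estimation error shrinks monotonically with SNR under Rician noise", {
  snrs <- c(20, 50, 200)
  n_rep <- 200
  stats_at <- function(snr) {
    set.seed(33)
    est <- replicate(n_rep, {
      g <- generate_voxel_signals(
        data.frame(adc = 0.8, d = 0.6, d_star = 8, f = 28, ddc = 1.0,
                   alpha = 0.8),
        sch, snr, "sem", voxel_cv = 0)
      sem <- fit_sem(g$signals[1, ], sch)
      mono <- fit_mono(g$signals[1, ], sch)
      c(ddc = sem$params$ddc, alpha = sem$params$alpha,
        adc = mono$params$adc)
    })
    list(bias = abs(rowMeans(est) - c(1.0e-3, 0.8, NA)),
         disp = apply(est, 1, sd))
  }
  res <- lapply(snrs, stats_at)
  for (p in c("ddc", "alpha")) {
    biases <- vapply(res, function(r) r$bias[[p]], numeric(1))
    disps <- vapply(res, function(r) r$disp[[p]], numeric(1))
    expect_true(all(diff(biases) < 0))
    expect_true(all(diff(disps) < 0))
  }
  # dispersion of the mono ADC estimate also shrinks
  disps <- vapply(res, function(r) r$disp[["adc"]], numeric(1))
  expect_true(all(diff(disps) < 0))
})

test_that("fit_volume reduces to the direct fitters and handles edge cases", {
  vol <- array(0, c(2, 2, 1, 12))
  mask <- array(0L, c(2, 2, 1))
  mask[1, 1, 1] <- 1L
  vals <- signal_sem(b, 50, 1.1e-3, 0.75)
  vol[1, 1, 1, ] <- vals
  res <- fit_volume(vol, mask, sch)
  expect_equal(res$n_voxels, 1L)
  expect_equal(res$maps$ddc[1, 1, 1], fit_sem(vals, sch)$params$ddc)
  expect_equal(res$maps$adc[1, 1, 1], fit_mono(vals, sch)$params$adc)
  expect_equal(res$maps$d[1, 1, 1], fit_ivim(vals, sch)$params$d)
  expect_equal(res$maps$status[1, 1, 1], 0L)
  expect_true(is.na(res$maps$ddc[2, 2, 1]))
  # empty mask: warning and empty maps
  expect_warning(empty <- fit_volume(vol, array(0L, c(2, 2, 1)), sch),
                 "empty")
  expect_equal(empty$n_voxels, 0L)
  # grid mismatch
  expect_error(fit_volume(vol, array(0L, c(3, 2, 1)), sch), "grids differ")
})

test_that("fit_volume recovers a two-region noiseless phantom", {
  pars <- list(a = c(ddc = 0.8e-3, alpha = 0.9),
               b = c(ddc = 1.3e-3, alpha = 0.6))
  vol <- array(0, c(2, 2, 2, 12))
  mask <- array(0L, c(2, 2, 2))
  mask[, , 1] <- 1L; mask[, , 2] <- 2L
  for (i in 1:2) for (j in 1:2) {
    vol[i, j, 1, ] <- signal_sem(b, 10, pars$a[["ddc"]], pars$a[["alpha"]])
    vol[i, j, 2, ] <- signal_sem(b, 10, pars$b[["ddc"]], pars$b[["alpha"]])
  }
  res <- fit_volume(vol, mask, sch, models = "sem")
  expect_equal(mean(res$maps$ddc[, , 1]), pars$a[["ddc"]], tolerance = 1e-4)
  expect_equal(mean(res$maps$ddc[, , 2]), pars$b[["ddc"]], tolerance = 1e-4)
  expect_equal(mean(res$maps$alpha[, , 1]), pars$a[["alpha"]],
               tolerance = 1e-4)
  expect_equal(mean(res$maps$alpha[, , 2]), pars$b[["alpha"]],
               tolerance = 1e-4)
})
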