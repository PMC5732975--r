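cosine_record <- function(amp, harmonic, n_cycles = 4, period = 64,
                          phase = 0, fs = FS_TEST) {
  L <- n_cycles * period
  w <- amp * cos(2 * pi * harmonic * n_cycles * (0:(L - 1)) / L + phase)
  steady_state_record(w, fs, segments = rep(period, n_cycles),
                      n_cycles = n_cycles, f0 = fs / period)
}

test_that("harmonic extraction follows the RMS amplitude convention", {
  r <- cosine_record(amp = 2, harmonic = 1)
  h <- harmonic_set(r)
  expect_length(h$coef, 3)
  expect_equal(Mod(h$coef[1]), 2 / sqrt(2), tolerance = 1e-12)
  expect_lt(max(Mod(h$coef[2:3])), 1e-12)

  # phase is carried in the complex coefficient
  hp <- harmonic_set(cosine_record(1, 1, phase = pi / 3))
  expect_equal(Arg(hp$coef[1]), pi / 3, tolerance = 1e-10)

  # zero record -> zero coefficients
  z <- harmonic_set(numeric(256), n_cycles = 4)
  expect_true(all(Mod(z$coef) == 0))

  expect_error(harmonic_set(numeric(255), n_cycles = 4), "integer")
  expect_error(harmonic_set(numeric(16), n_cycles = 4, n_harmonics = 3),
               "Nyquist")
})

test_that("harmonic energy obeys Parseval and reconstruction is exact in-band", {
  # a record containing only bins C, 2C, 3C reconstructs exactly
  r3 <- cosine_record(1.2, 1)$waveform + cosine_record(0.5, 2)$waveform +
    cosine_record(0.2, 3, phase = 1)$waveform
  h <- harmonic_set(r3, n_cycles = 4)
  expect_equal(reconstruct_harmonics(h), r3, tolerance = 1e-10)
  # harmonic energy equals the record's mean square exactly here
  expect_equal(sum(Mod(h$coef)^2), mean(r3^2), tolerance = 1e-12)

  # for a general synthetic steady-state record the three harmonics hold
  # at most the total energy; residual energy is the exact difference
  assr <- synthesize_assr(default_template(), 25.6, 4)
  ha <- harmonic_set(assr)
  expect_lte(sum(Mod(ha$coef)^2), mean(assr$waveform^2) + 1e-12)
  resid <- assr$waveform - reconstruct_harmonics(ha)
  expect_equal(mean(resid^2), mean(assr$waveform^2) - sum(Mod(ha$coef)^2),
               tolerance = 1e-10)

  # declining harmonic amplitudes on the default template's response
  expect_gt(Mod(ha$coef[1]), Mod(ha$coef[2]))
  expect_gt(Mod(ha$coef[2]), Mod(ha$coef[3]))

  # full-spectrum Parseval for the DFT as used (sanity of conventions)
  y <- rnorm(128)
  expect_equal(sum(Mod(stats::fft(y))^2) / 128, sum(y^2), tolerance = 1e-9)
})

test_that("pointwise t-tests: trivial masks and zero-variance convention", {
  z <- pointwise_ttest(matrix(0, 5, 20))
  expect_equal(z$fraction_pct, 0)
  expect_true(all(z$p == 1))

  big <- pointwise_ttest(matrix(10, 6, 15) + rnorm(90, sd = 1e-3))
  expect_equal(big$fraction_pct, 100)

  # zero variance, nonzero mean -> p = 0 by convention
  const <- pointwise_ttest(matrix(rep(c(0, 2), each = 4), nrow = 4))
  expect_equal(const$p, c(1, 0))

  expect_error(pointwise_ttest(matrix(0, 2, 4)), "3 subjects")

  # agrees with t.test where defined
  set.seed(12)
  m <- matrix(rnorm(9 * 6, mean = 0.4), 9, 6)
  res <- pointwise_ttest(m)
  ref <- apply(m, 2, function(col) stats::t.test(col)$p.value)
  expect_equal(res$p, ref, tolerance = 1e-12)
})

test_that("pointwise null calibration: significant fraction near alpha", {
  set.seed(200)
  fracs <- replicate(200, {
    pointwise_ttest(matrix(rnorm(19 * 256), 19, 256))$fraction_pct
  })
  expect_equal(mean(fracs), 5, tolerance = 0.2)  # 5% +- 1 percentage point
})

test_that("Hotelling T2: identities, errors and ellipse geometry", {
  set.seed(33)
  # p = 1 reduces to the squared t statistic
  x <- matrix(rnorm(12, mean = 0.8), ncol = 1)
  h1 <- hotelling_one_sample(x)
  tt <- stats::t.test(x[, 1])
  expect_equal(h1$t2, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(h1$p_value, tt$p.value, tolerance = 1e-10)

  # exactly centred data -> T2 = 0, p = 1
  y <- matrix(rnorm(20), 10, 2)
  y <- sweep(y, 2, colMeans(y))
  h0 <- hotelling_one_sample(y)
  expect_equal(h0$t2, 0, tolerance = 1e-12)
  expect_equal(h0$p_value, 1)

  # invariance under invertible linear maps
  z <- matrix(rnorm(17 * 6, mean = 0.2), 17, 6)
  M <- matrix(rnorm(36), 6, 6) + 6 * diag(6)
  expect_equal(hotelling_one_sample(z %*% M)$t2, hotelling_one_sample(z)$t2,
               tolerance = 1e-8)

  expect_error(hotelling_one_sample(matrix(rnorm(12), 2, 6)), "n > p")

  # ellipse: mean on the boundary has squared Mahalanobis radius equal to
  # the F-quantile scale
  h2 <- hotelling_one_sample(y + 1)  # shift mean to 1
  e <- h2$ellipse
  v <- e$axes[, 1] * e$radii[1]
  q <- drop(t(v) %*% solve(h2$cov / h2$n) %*% v)
  expect_equal(q, h2$p * (h2$n - 1) / (h2$n - h2$p) *
                 stats::qf(0.95, h2$p, h2$n - h2$p), tolerance = 1e-8)
})

test_that("printed T2-to-F conversions and the F identity", {
  expect_equal(round(t2_to_f(32.33, 17, 6), 2), 3.70)
  expect_equal(round(t2_to_f(92.04, 17, 6), 2), 10.55)
  expect_equal(round(t2_to_f(6.96, 17, 6), 2), 0.80)
  expect_equal(t2_to_f(0, 17, 6), 0)
  expect_error(t2_to_f(5, 6, 6), "n > p")

  # internal consistency on random data: F = T2 (n-p) / (p (n-1))
  set.seed(44)
  x <- matrix(rnorm(17 * 6), 17, 6)
  h <- hotelling_one_sample(x)
  expect_equal(h$f, h$t2 * 11 / (6 * 16), tolerance = 1e-12)
})

test_that("Hotelling null calibration at study dimensions", {
  set.seed(77)
  rej <- replicate(2000, {
    hotelling_one_sample(matrix(rnorm(17 * 6), 17, 6))$p_value < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.2)  # 5% +- 1 point
})

test_that("outlier screening: clean rates, planted outlier, degenerate input", {
  set.seed(50)
  # clean multivariate normal: low average removal rate
  rates <- replicate(100, {
    x <- matrix(rnorm(100 * 3), 100, 3)
    length(outlier_policy(x)$removed) / 100
  })
  expect_lte(mean(rates), 0.05)

  # one planted 10-sigma outlier is caught
  x <- matrix(rnorm(20 * 4), 20, 4)
  x[7, ] <- x[7, ] + 10
  out <- outlier_policy(x)
  expect_true(7 %in% out$removed)

  # identical vectors: nothing removed
  same <- matrix(1, 5, 3)
  expect_equal(outlier_policy(same)$removed, integer(0))

  expect_error(outlier_policy(matrix(rnorm(8), 4, 2)), "5 subjects")
})
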