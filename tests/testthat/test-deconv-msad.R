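test_that("fold matrix structure on hand-checkable systems", {
  # single period P = N: identity operator
  id <- build_fold_system(4, 4)
  expect_equal(id$A, diag(4))

  # P = 2, N = 4: two wrapped copies per phase
  s24 <- build_fold_system(2, 4)
  expect_equal(s24$A, rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))

  # stacked system rows and dims
  sys <- build_fold_system(c(2, 3), 6)
  expect_equal(dim(sys$A), c(5L, 6L))
  expect_true(all(sys$A %in% c(0, 1)))

  expect_error(build_fold_system(c(4, 8), 6), ">=")
})

test_that("fold products match brute-force time-domain overlap", {
  # paper-size system plus an odd-shaped one, random templates
  systems <- list(list(periods = PAPER_PERIODS, n = 512),
                  list(periods = c(5, 7, 9), n = 20))
  set.seed(55)
  for (ss in systems) {
    sys <- build_fold_system(ss$periods, ss$n)
    for (rep_i in 1:50) {
      x <- rnorm(ss$n)
      b <- drop(sys$A %*% x)
      oracle <- unlist(lapply(ss$periods, function(p) oracle_fold(x, p)))
      expect_equal(b, oracle, tolerance = 1e-12)
    }
  }
})

test_that("noiseless solves recover the truth at machine precision", {
  sys <- with_svd(build_fold_system(PAPER_PERIODS, 256))
  tmpl <- default_template()
  x_true <- tmpl$waveform[1:256]
  b <- drop(sys$A %*% x_true)

  tik0 <- msad_deconvolve(b, sys, "tikhonov", parameter = 0, fs = FS_TEST)
  expect_equal(tik0$estimate$waveform, x_true, tolerance = 1e-9)

  d <- tik0$singular_values
  rank <- sum(d > max(dim(sys$A)) * .Machine$double.eps * d[1])
  tsvd_full <- msad_deconvolve(b, sys, "tsvd", parameter = rank, fs = FS_TEST)
  expect_equal(tsvd_full$estimate$waveform, x_true, tolerance = 1e-9)

  # zero record -> zero estimate
  z <- msad_deconvolve(numeric(nrow(sys$A)), sys, "tikhonov", 0)
  expect_equal(z$estimate$waveform, numeric(256))

  # norms in the solution object are recomputable
  expect_equal(tik0$solution_norm, sqrt(sum(tik0$estimate$waveform^2)))
  expect_equal(tik0$residual_norm,
               sqrt(sum((sys$A %*% tik0$estimate$waveform - b)^2)),
               tolerance = 1e-8)

  expect_error(msad_deconvolve(numeric(10), sys), "length")
  expect_error(msad_deconvolve(b, sys, "tsvd", parameter = 1e6), "rank")
  expect_error(msad_deconvolve(b, sys, "tikhonov", parameter = -1), ">= 0")
})

test_that("Tikhonov norms are monotone along the lambda grid (L-curve)", {
  sys <- with_svd(build_fold_system(PAPER_PERIODS, 256))
  set.seed(60)
  b <- drop(sys$A %*% default_template()$waveform[1:256]) + rnorm(512, sd = 0.1)
  lams <- 10^seq(-3, 1, length.out = 9)
  sols <- lapply(lams, function(l)
    msad_deconvolve(b, sys, "tikhonov", parameter = l))
  sol_norm <- vapply(sols, function(s) s$solution_norm, 0)
  res_norm <- vapply(sols, function(s) s$residual_norm, 0)
  expect_true(all(diff(sol_norm) <= 1e-10))
  expect_true(all(diff(res_norm) >= -1e-10))
})

test_that("auto regularization beats the unregularized solve under noise", {
  sys <- with_svd(build_fold_system(PAPER_PERIODS, 256))
  x_true <- default_template()$waveform[1:256]
  b_clean <- drop(sys$A %*% x_true)
  set.seed(70)
  wins <- 0L
  for (i in 1:20) {
    b <- b_clean + rnorm(512, sd = 1)  # 1 uV noise on the observation
    rmse <- function(sol) sqrt(mean((sol$estimate$waveform - x_true)^2))
    reg <- rmse(msad_deconvolve(b, sys, "tikhonov", "auto"))
    raw <- rmse(msad_deconvolve(b, sys, "tikhonov", 0))
    if (reg < raw) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("isochronic single-rate system agrees with the inverse filter", {
  # one rate with P = N is the degenerate case both methods share
  one <- to_impulse_train(stim_sequence(25.6), FS_TEST)
  sys <- build_fold_system(64, 64)
  set.seed(81)
  y <- rnorm(64)
  expect_equal(msad_deconvolve(y, sys, "tikhonov", 0, fs = FS_TEST)$estimate$waveform,
               clad_deconvolve(y, one)$waveform, tolerance = 1e-10)
})

test_that("parameter recovery: estimate converges to truth as noise vanishes", {
  sys <- with_svd(build_fold_system(PAPER_PERIODS, 256))
  x_true <- default_template()$waveform[1:256]
  b_clean <- drop(sys$A %*% x_true)
  set.seed(90)
  noise <- rnorm(512)
  errs <- vapply(c(1e-2, 1e-4, 0), function(sd) {
    sol <- msad_deconvolve(b_clean + sd * noise, sys, "tikhonov", 0)
    sqrt(mean((sol$estimate$waveform - x_true)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("recovery report: exact case, identity conditioning, paper-size SVD", {
  sys <- build_fold_system(PAPER_PERIODS, 512)
  tmpl <- default_template()
  b <- drop(sys$A %*% tmpl$waveform)
  sol <- msad_deconvolve(b, sys, "tsvd", parameter = 392, fs = FS_TEST)
  rep <- recovery_report(sol, truth = tmpl, windows = component_windows())
  expect_gt(rep$condition_number, 1)
  expect_true(is.finite(rep$condition_number))
  expect_length(rep$singular_values, 512)
  expect_equal(nrow(rep$components), 5)

  # estimate == truth -> all errors zero
  id <- build_fold_system(8, 8)
  w <- rnorm(8)
  sid <- msad_deconvolve(w, id, "tikhonov", 0, fs = FS_TEST)
  r0 <- recovery_report(sid, truth = transient_aep(w, FS_TEST))
  expect_equal(r0$rmse_uv, 0, tolerance = 1e-12)
  expect_equal(r0$condition_number, 1)
})
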