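test_that("template construction honours anchors, ordering and degeneracies", {
  fs <- 20000  # 7.05 ms is exactly on this grid
  tmpl <- make_template(template_spec(aep_components(), fs = fs))
  t_ms <- (seq_along(tmpl$waveform) - 1) / fs * 1000
  win <- t_ms >= 5 & t_ms <= 10
  peak_i <- which(win)[which.max(tmpl$waveform[win])]
  expect_equal(t_ms[peak_i], 7.05)
  expect_equal(tmpl$waveform[peak_i], 0.44, tolerance = 0.01)

  # empty component list -> all-zero waveform
  empty <- make_template(template_spec(aep_components()[0, ], fs = FS_TEST))
  expect_true(all(empty$waveform == 0))

  # invariant violations are rejected
  bad_order <- aep_components()
  bad_order$latency_ms[3] <- 10  # Pa before Na
  expect_error(template_spec(bad_order), "order")
  bad_sign <- aep_components()
  bad_sign$amplitude_uv[2] <- 0.5  # Na positive
  expect_error(template_spec(bad_sign), "negative")
  expect_error(template_spec(aep_components(), duration_ms = 300), "204.8")
  late <- aep_components()
  late$latency_ms[5] <- 250
  expect_error(template_spec(late, duration_ms = 204.8), "latency")
})

test_that("single-lobe template RMS matches the closed-form Gaussian RMS", {
  # RMS of a * exp(-(t-mu)^2/(2 s^2)) over [0, T): a * sqrt(s * sqrt(pi) / T)
  comp <- data.frame(name = "Pa", latency_ms = 25, amplitude_uv = 0.8,
                     width_ms = 3.5)
  fs <- 20000
  tmpl <- make_template(template_spec(comp, 204.8, fs))
  closed <- 0.8 * sqrt(3.5 * sqrt(pi) / 204.8)
  expect_equal(sqrt(mean(tmpl$waveform^2)), closed, tolerance = 1e-4)
  expect_true(all(tmpl$waveform > 0 | abs(tmpl$waveform) < 1e-12))
})

test_that("band-limited noise has the requested rms, zero mean, in-band spectrum", {
  set.seed(7)
  n <- 4096
  x <- band_noise(n, FS_TEST, rms = 1.5)
  expect_equal(sqrt(mean(x^2)), 1.5, tolerance = 1e-12)
  expect_lt(abs(mean(x)), 1e-10)

  # averaged periodogram over draws: flat in band (+-3 dB), suppressed outside
  p <- rowMeans(replicate(40, Mod(stats::fft(band_noise(n, FS_TEST, 1)))^2))
  f <- (0:(n - 1)) * FS_TEST / n
  inb <- f >= 30 & f <= 800          # interior of the 10-1000 band
  out <- f >= 1200 & f <= 1250
  ref <- mean(p[inb])
  expect_lt(max(p[inb]) / ref, 2)    # +3 dB
  expect_gt(min(p[inb]) / ref, 0.5)  # -3 dB
  expect_lt(mean(p[out]) / ref, 0.2)
  expect_equal(band_noise(100, FS_TEST, 0), numeric(100))
})

test_that("sweep simulation: noiseless exactness, convergence, determinism", {
  tmpl <- default_template()
  tr <- paper_train()

  # zero noise: every sweep equals the circular convolution exactly
  clean <- simulate_sweeps(tmpl, tr, n_sweeps = 3, noise_rms = 0)
  conv <- oracle_circ_conv(tr$samples,
                           c(tmpl$waveform,
                             numeric(512 - length(tmpl$waveform))))
  for (i in 1:3) expect_equal(clean$data[i, ], conv, tolerance = 1e-10)

  # unit-impulse template on a single-click train: sweep = impulse + noise
  imp <- transient_aep(c(1, numeric(63)), FS_TEST)
  one <- to_impulse_train(stim_sequence(25.6), FS_TEST)
  s <- simulate_sweeps(imp, one, 1, noise_rms = 0)
  expect_equal(s$data[1, ], c(1, numeric(63)))

  # averaging error scales as 1/sqrt(n): rms(avg - clean) ~ 1/sqrt(400)
  noisy <- simulate_sweeps(tmpl, tr, n_sweeps = 400, noise_rms = 1, seed = 11)
  err <- sqrt(mean((colMeans(noisy$data) - noisy$noiseless)^2))
  expect_equal(err, 1 / sqrt(400), tolerance = 0.2)

  # seeded reproducibility without disturbing the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  a <- simulate_sweeps(tmpl, tr, 5, noise_rms = 1, seed = 42)
  set.seed(99)
  b <- simulate_sweeps(tmpl, tr, 5, noise_rms = 1, seed = 42)
  expect_identical(a$data, b$data)
  set.seed(99); expect_identical(rnorm(1), before)

  # fs mismatch rejected
  expect_error(simulate_sweeps(default_template(fs = 5000), tr, 1), "fs")
})

test_that("artifact injection produces >40 uV excursions at the stated rate", {
  tmpl <- default_template()
  tr <- paper_train()
  s <- simulate_sweeps(tmpl, tr, 200, noise_rms = 1, artifact_rate = 0.5,
                       seed = 5)
  peaks <- apply(abs(s$data), 1, max)
  frac <- mean(peaks > 40)
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.65)
  clean <- simulate_sweeps(tmpl, tr, 50, noise_rms = 1, artifact_rate = 0,
                           seed = 5)
  expect_true(all(apply(abs(clean$data), 1, max) <= 40))
})

test_that("simulate_study writes a reproducible on-disk bundle", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  subs <- list(subject_spec(n_sweeps = 3, noise_rms = 0.5),
               subject_spec(n_sweeps = 3, noise_rms = 0.5))
  m1 <- simulate_study(subs, d1, fs = FS_TEST, seed = 123)
  m2 <- simulate_study(subs, d2, fs = FS_TEST, seed = 123)

  expect_length(m1$subjects, 2)
  # per subject: traditional + clad + control + 8 msad rate files
  files1 <- sort(list.files(d1, pattern = "\\.tsv$"))
  expect_length(files1, 2 * (3 + 8))
  # same seed twice -> byte-identical sweep files
  for (f in files1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # round trip through the TSV reader
  ss <- read_sweep_set(file.path(d1, files1[1]))
  expect_equal(ss$fs, FS_TEST)
  expect_equal(nrow(ss$data), 3)
})
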