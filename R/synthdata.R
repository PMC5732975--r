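#' Default transient AEP component table
#'
#' The transient auditory evoked potential (AEP) to a click is modeled as a
#' sum of Gaussian lobes, one per canonical component: wave V of the
#' auditory brainstem response (ABR) followed by the middle latency response
#' (MLR) components Na, Pa, Nb and Pb. Wave V is anchored at 7.05 ms /
#' 0.44 µV and Pa near 25 ms; the remaining latencies, amplitudes and widths
#' are free parameters chosen to give a plausible click MLR morphology and
#' are NOT literature values.
#'
#' @param latency_shift_ms additive shift applied to all latencies (ms).
#'   Components recovered at 40 Hz stimulation show slightly prolonged
#'   latencies relative to low-rate stimulation; a shift of about +0.5 ms
#'   emulates that.
#' @param amplitude_scale multiplicative scaling, either a single number or
#'   a named vector keyed by component name (e.g. `c(Na = 1.3)`).
#' @return data.frame with columns `name`, `latency_ms`, `amplitude_uv`,
#'   `width_ms` (Gaussian sigma).
#' @export
aep_components <- function(latency_shift_ms = 0, amplitude_scale = 1) {
  comp <- data.frame(
    name = c("V", "Na", "Pa", "Nb", "Pb"),
    latency_ms = c(7.05, 18, 25, 38, 52),
    amplitude_uv = c(0.44, -0.50, 0.80, -0.45, 0.55),
    width_ms = c(0.8, 3, 3.5, 4, 5),
    stringsAsFactors = FALSE
  )
  comp$latency_ms <- comp$latency_ms + latency_shift_ms
  if (length(amplitude_scale) == 1L && is.null(names(amplitude_scale))) {
    comp$amplitude_uv <- comp$amplitude_uv * amplitude_scale
  } else {
    idx <- match(names(amplitude_scale), comp$name)
    if (anyNA(idx)) stop("unknown component in `amplitude_scale`: ",
                         paste(names(amplitude_scale)[is.na(idx)], collapse = ", "))
    comp$amplitude_uv[idx] <- comp$amplitude_uv[idx] * amplitude_scale
  }
  comp
}

#' Specification of a ground-truth transient AEP template
#'
#' @param components data.frame as returned by [aep_components()]; may be
#'   empty (zero-row) for an all-zero template.
#' @param duration_ms support of the transient response; must not exceed
#'   204.8 ms, the sweep length of the jittered paradigm (both deconvolution
#'   models assume the transient dies out within one sweep).
#' @param fs sampling rate in Hz.
#' @return object of class `template_spec`.
#' @export
template_spec <- function(components = aep_components(), duration_ms = 204.8,
                          fs = 20000) {
  stopifnot(is.data.frame(components), duration_ms > 0, fs > 0)
  if (duration_ms > 204.8 + 1e-9) {
    stop("duration_ms must be <= 204.8 ms (transient support assumption)")
  }
  if (nrow(components) > 0) {
    need <- c("name", "latency_ms", "amplitude_uv", "width_ms")
    if (!all(need %in% names(components))) {
      stop("components must have columns ", paste(need, collapse = ", "))
    }
    if (any(components$latency_ms <= 0 | components$latency_ms >= duration_ms)) {
      stop("component latency outside (0, duration_ms)")
    }
    known <- components$name %in% c("V", "Na", "Pa", "Nb", "Pb")
    if (all(known) && nrow(components) > 1) {
      ord <- match(components$name, c("V", "Na", "Pa", "Nb", "Pb"))
      if (is.unsorted(ord) ||
          is.unsorted(components$latency_ms[order(ord)], strictly = TRUE)) {
        stop("component latencies must increase in the order V < Na < Pa < Nb < Pb")
      }
      pos <- components$name %in% c("V", "Pa", "Pb")
      if (any(sign(components$amplitude_uv) != ifelse(pos, 1, -1))) {
        stop("V, Pa, Pb must have positive amplitude; Na, Nb negative")
      }
    }
  }
  structure(list(components = components, duration_ms = duration_ms, fs = fs),
            class = "template_spec")
}

#' Build a transient AEP waveform from its specification
#'
#' Each component contributes a Gaussian lobe
#' `a * exp(-(t - latency)^2 / (2 width^2))`; the waveform is the sum of the
#' lobes, sampled on `[0, duration)` at `fs`.
#'
#' @param spec a `template_spec`.
#' @return object of class `transient_aep`: fields `waveform` (µV, length
#'   `duration_ms * fs / 1000`), `fs`.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  n <- round(spec$duration_ms * spec$fs / 1000)
  t_ms <- (seq_len(n) - 1) / spec$fs * 1000
  w <- numeric(n)
  if (nrow(spec$components) > 0) {
    for (i in seq_len(nrow(spec$components))) {
      c_i <- spec$components[i, ]
      w <- w + c_i$amplitude_uv *
        exp(-(t_ms - c_i$latency_ms)^2 / (2 * c_i$width_ms^2))
    }
  }
  transient_aep(w, spec$fs)
}

#' @rdname make_template
#' @param waveform numeric vector, µV, time origin at stimulus onset.
#' @param fs sampling rate, Hz.
#' @export
transient_aep <- function(waveform, fs) {
  stopifnot(is.numeric(waveform), is.na(fs) || fs > 0)
  structure(list(waveform = as.numeric(waveform), fs = fs),
            class = "transient_aep")
}

#' @export
print.transient_aep <- function(x, ...) {
  cat(sprintf("<transient_aep> %d samples @ %g Hz (%.1f ms), rms %.3g uV\n",
              length(x$waveform), x$fs, length(x$waveform) / x$fs * 1000,
              sqrt(mean(x$waveform^2))))
  invisible(x)
}

## circular convolution of equal-length real vectors via the DFT
circ_convolve <- function(a, b) {
  stopifnot(length(a) == length(b))
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / length(a)
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise shaped in the frequency domain by the squared-
#' magnitude response of a 4th-order Butterworth band-pass (applied with
#' zero phase), then rescaled to the requested RMS. The DC bin is zeroed, so
#' the noise has (numerically) zero mean. Draws from the current R RNG
#' stream.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param rms target root-mean-square amplitude (µV); 0 gives silence.
#' @param band length-2 passband edges in Hz, within `(0, fs/2)`.
#' @param order Butterworth order of each edge (default 4).
#' @return numeric vector of length `n`.
#' @export
band_noise <- function(n, fs, rms, band = c(10, 1000), order = 4) {
  if (rms == 0) return(numeric(n))
  stopifnot(rms > 0, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  x <- stats::rnorm(n)
  f <- bin_freqs(n, fs)
  h <- 1 / sqrt(1 + (band[1] / pmax(f, 1e-12))^(2 * order)) /
    sqrt(1 + (f / band[2])^(2 * order))
  h[1] <- 0  # kill DC
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

## matrix version: one band-limited noise trace per column, each scaled to
## the target rms; one pair of mvfft calls instead of a per-sweep loop
band_noise_mat <- function(n, n_traces, fs, rms, band = c(10, 1000),
                           order = 4) {
  if (rms == 0) return(matrix(0, n, n_traces))
  stopifnot(rms > 0, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  x <- matrix(stats::rnorm(n * n_traces), n, n_traces)
  f <- bin_freqs(n, fs)
  h <- 1 / sqrt(1 + (band[1] / pmax(f, 1e-12))^(2 * order)) /
    sqrt(1 + (f / band[2])^(2 * order))
  h[1] <- 0
  y <- Re(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE)) / n
  sc <- rms / sqrt(colMeans(y^2))
  y * rep(sc, each = n)
}

#' Simulate sweep-level EEG for one paradigm
#'
#' Each sweep is the circular convolution of the stimulus impulse train with
#' the (zero-padded) transient template, plus independent band-limited
#' noise. The circular model makes every simulated sweep a steady-state
#' sweep: there is no onset transient, matching the looped-stimulation
#' assumption of the deconvolution models. With probability
#' `artifact_rate`, a sweep additionally receives a single-sample 50 µV
#' excursion at a random position — the simplest event a 40 µV rejection
#' rule must catch.
#'
#' @param template a `transient_aep`; must not be longer than the train.
#' @param train an `impulse_train` at the same sampling rate.
#' @param n_sweeps number of sweeps to simulate.
#' @param noise_rms per-sweep noise RMS in µV (0 for noiseless).
#' @param noise_band passband of the noise, Hz.
#' @param artifact_rate per-sweep probability of an injected 50 µV spike.
#' @param paradigm free-text tag stored with the sweep set.
#' @param seed optional integer; when given, the RNG is seeded locally so
#'   the sweep set is reproducible without disturbing the caller's stream.
#' @return object of class `sweep_set`: `data` (n_sweeps x N matrix, µV),
#'   `fs`, `paradigm` (free-text tag), `noiseless` (the pure convolution).
#' @export
simulate_sweeps <- function(template, train, n_sweeps, noise_rms = 1,
                            noise_band = c(10, 1000), artifact_rate = 0,
                            paradigm = "sim", seed = NULL) {
  stopifnot(inherits(template, "transient_aep"), inherits(train, "impulse_train"))
  if (abs(template$fs - train$fs) > 1e-9) {
    stop("template fs (", template$fs, ") and train fs (", train$fs,
         ") must match")
  }
  n <- length(train$samples)
  if (length(template$waveform) > n) {
    stop("template longer than the sweep: ", length(template$waveform),
         " > ", n, " samples")
  }
  x <- c(template$waveform, numeric(n - length(template$waveform)))
  clean <- circ_convolve(train$samples, x)
  gen <- function() {
    noise <- band_noise_mat(n, n_sweeps, train$fs, noise_rms, noise_band)
    data <- t(noise + clean)
    if (artifact_rate > 0) {
      hit <- which(stats::runif(n_sweeps) < artifact_rate)
      for (i in hit) {
        pos <- sample.int(n, 1)
        data[i, pos] <- data[i, pos] + 50
      }
    }
    data
  }
  data <- if (is.null(seed)) gen() else withr_seed(seed, gen)
  structure(list(data = data, fs = train$fs, paradigm = paradigm,
                 noiseless = clean),
            class = "sweep_set")
}

## evaluate fn under a local RNG seed, restoring the caller's stream
withr_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s: %d sweeps x %d samples @ %g Hz\n",
              x$paradigm, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Per-subject simulation settings
#'
#' @param latency_shift_ms,amplitude_scale passed to [aep_components()] to
#'   derive this subject's template; either a single value (shared template
#'   across paradigms — the perfect-superposition world) or a named list
#'   keyed by paradigm (`traditional`, `clad`, `msad`, `control`) to emulate
#'   rate- and sequencing-dependent templates.
#' @param n_sweeps sweeps per paradigm (single number or named list).
#' @param noise_rms per-sweep noise RMS, µV.
#' @param artifact_rate per-sweep artifact probability.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(latency_shift_ms = 0, amplitude_scale = 1,
                         n_sweeps = 200, noise_rms = 1, artifact_rate = 0) {
  stopifnot(all(unlist(n_sweeps) >= 1))
  structure(list(latency_shift_ms = latency_shift_ms,
                 amplitude_scale = amplitude_scale,
                 n_sweeps = n_sweeps, noise_rms = noise_rms,
                 artifact_rate = artifact_rate),
            class = "subject_spec")
}

per_paradigm <- function(x, paradigm) {
  if (is.list(x) && !is.null(names(x))) {
    if (!is.null(x[[paradigm]])) x[[paradigm]] else x[["default"]]
  } else x
}

#' Write a full synthetic study to disk
#'
#' For each subject and paradigm, simulates a sweep set and writes it as a
#' TSV matrix (sweeps x samples) with a JSON sidecar; a `manifest.json`
#' records templates, seeds and file names. Output is byte-identical for a
#' fixed seed.
#'
#' @param subjects list of [subject_spec()] objects.
#' @param dir output directory (created if missing).
#' @param fs sampling rate, Hz.
#' @param isis jittered-sequence ISIs (ms); also the multi-rate set.
#' @param control_isi_ms isochronic control ISI (ms); the classical
#'   steady-state sweep covers `control_cycles` cycles.
#' @param trad_isi_ms traditional (low-rate) epoch length in ms.
#' @param control_cycles cycles per classical steady-state sweep.
#' @param msad_cycles cycles per multi-rate sweep at each rate; `"auto"`
#'   uses enough cycles to cover the template support.
#' @param seed integer master seed; per-subject/paradigm seeds derive from it.
#' @param template_duration_ms support of the ground-truth template.
#' @return (invisibly) the manifest as a list.
#' @export
simulate_study <- function(subjects, dir, fs = 20000, isis = clad_isis(),
                           control_isi_ms = 25.6, trad_isi_ms = 204.8,
                           control_cycles = 4, msad_cycles = "auto",
                           seed = 1, template_duration_ms = 204.8) {
  stopifnot(length(subjects) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paradigms <- c("traditional", "clad", "msad", "control")
  manifest <- list(fs_hz = fs, seed = seed, isis_ms = isis,
                   control_isi_ms = control_isi_ms,
                   trad_isi_ms = trad_isi_ms, subjects = list())
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    stopifnot(inherits(sub, "subject_spec"))
    entry <- list(id = si, files = list(), templates = list())
    for (pi in seq_along(paradigms)) {
      p <- paradigms[pi]
      comp <- aep_components(
        latency_shift_ms = per_paradigm(sub$latency_shift_ms, p),
        amplitude_scale = per_paradigm(sub$amplitude_scale, p))
      tmpl <- make_template(template_spec(comp, template_duration_ms, fs))
      train <- paradigm_train(p, fs, isis, control_isi_ms, trad_isi_ms,
                              control_cycles, msad_cycles,
                              template_samples = length(tmpl$waveform))
      sseed <- (seed * 1009L + si * 101L + pi) %% 2147483647L
      nsw <- per_paradigm(sub$n_sweeps, p)
      if (p == "msad") {
        sets <- lapply(seq_along(train), function(ri) {
          simulate_sweeps(tmpl, train[[ri]], nsw, sub$noise_rms,
                          artifact_rate = sub$artifact_rate,
                          paradigm = sprintf("msad_rate%02d", ri),
                          seed = (sseed + ri) %% 2147483647L)
        })
        files <- vapply(seq_along(sets), function(ri) {
          f <- file.path(dir, sprintf("s%02d_msad_r%02d.tsv", si, ri))
          write_sweep_set(sets[[ri]], f)
          basename(f)
        }, character(1))
        entry$files[[p]] <- files
      } else {
        set <- simulate_sweeps(tmpl, train, nsw, sub$noise_rms,
                               artifact_rate = sub$artifact_rate,
                               paradigm = p, seed = sseed)
        f <- file.path(dir, sprintf("s%02d_%s.tsv", si, p))
        write_sweep_set(set, f)
        entry$files[[p]] <- basename(f)
      }
      entry$templates[[p]] <- comp
      entry$seeds[[p]] <- sseed
    }
    manifest$subjects[[si]] <- entry
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## impulse train(s) for one named paradigm
paradigm_train <- function(paradigm, fs, isis, control_isi_ms, trad_isi_ms,
                           control_cycles, msad_cycles, template_samples) {
  switch(paradigm,
    traditional = to_impulse_train(stim_sequence(trad_isi_ms,
                                                 kind = "traditional"), fs),
    clad = to_impulse_train(make_clad_sequence(isis), fs),
    control = {
      p <- isi_to_samples(control_isi_ms, fs)
      k <- max(control_cycles, ceiling(template_samples / p))
      to_impulse_train(stim_sequence(rep(control_isi_ms, k)), fs)
    },
    msad = lapply(isis, function(isi) {
      p <- isi_to_samples(isi, fs)
      k <- if (identical(msad_cycles, "auto")) {
        max(1L, as.integer(ceiling(template_samples / p)))
      } else as.integer(msad_cycles)
      to_impulse_train(stim_sequence(rep(isi, k)), fs)
    }),
    stop("unknown paradigm: ", paradigm))
}
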