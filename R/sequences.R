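#' Stimulus sequences for steady-state and deconvolution paradigms
#'
#' A stimulus sequence is an ordered list of inter-stimulus intervals (ISIs,
#' in ms). One sweep of stimulation presents one click at the start of each
#' interval; the last interval closes the loop back to the first click, so a
#' sweep of total duration `sum(isis)` can be repeated seamlessly
#' ("continuous loop" convention).
#'
#' @param isis numeric vector of inter-stimulus intervals in ms, all > 0.
#' @param kind one of `"clad"`, `"isochronic"`, `"traditional"`. If `NULL`
#'   (default) the kind is inferred: `"isochronic"` when all ISIs are equal,
#'   `"clad"` otherwise.
#' @return An object of class `stim_sequence` with fields `isis` (ms),
#'   `sweep_ms` (total sweep duration, ms) and `kind`.
#' @examples
#' s <- stim_sequence(clad_isis())
#' s$sweep_ms   # 204.8
#' @export
stim_sequence <- function(isis, kind = NULL) {
  if (!is.numeric(isis) || length(isis) == 0L) {
    stop("`isis` must be a non-empty numeric vector of intervals in ms")
  }
  if (any(!is.finite(isis)) || any(isis <= 0)) {
    stop("all inter-stimulus intervals must be finite and strictly positive")
  }
  iso <- isTRUE(diff(range(isis)) < 1e-12)
  if (is.null(kind)) {
    kind <- if (iso) "isochronic" else "clad"
  }
  kind <- match.arg(kind, c("clad", "isochronic", "traditional"))
  if (kind == "isochronic" && !iso) {
    stop("kind = \"isochronic\" requires all ISIs equal")
  }
  structure(
    list(isis = as.numeric(isis), sweep_ms = sum(isis), kind = kind),
    class = "stim_sequence"
  )
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence> kind=%s, %d stimuli, sweep %.2f ms\n",
              x$kind, length(x$isis), x$sweep_ms))
  cat("  ISIs (ms):", paste(format(x$isis), collapse = ", "), "\n")
  invisible(x)
}

#' The 8-click jittered ISI list used throughout the package
#'
#' The canonical low-noise-gain jittered sequence: eight clicks, sweep
#' 204.8 ms, nominal rate 39.0625 Hz (reported as 39.1 Hz).
#'
#' @return numeric vector of 8 ISIs in ms.
#' @export
clad_isis <- function() {
  c(16.00, 28.80, 19.20, 27.20, 24.00, 32.00, 36.80, 20.80)
}

#' Construct a jittered (CLAD) stimulus sequence
#'
#' @param isis numeric vector of ISIs in ms.
#' @return A `stim_sequence`; `kind` is `"clad"` when the ISIs vary and
#'   `"isochronic"` when they are all equal (a single interval degenerates to
#'   the classical isochronic paradigm).
#' @export
make_clad_sequence <- function(isis = clad_isis()) {
  stim_sequence(isis)
}

#' Construct the multi-rate (MSAD) family of isochronic sequences
#'
#' One isochronic sequence per distinct ISI, in the order given. The ISIs are
#' conventionally the same as those of the companion jittered sequence, so
#' that the two paradigms share a nominal rate.
#'
#' @param isis numeric vector of ISIs in ms; duplicates are collapsed with a
#'   warning.
#' @return An object of class `msad_set`: a list of isochronic
#'   `stim_sequence` objects.
#' @export
make_msad_set <- function(isis = clad_isis()) {
  if (length(isis) == 0L) stop("`isis` must be non-empty")
  if (anyDuplicated(isis)) {
    warning("duplicate ISIs collapsed: ",
            paste(format(isis[duplicated(isis)]), collapse = ", "))
    isis <- isis[!duplicated(isis)]
  }
  out <- lapply(isis, function(i) stim_sequence(i, kind = "isochronic"))
  structure(out, class = "msad_set", isis = as.numeric(isis))
}

#' Summary metrics of a stimulus sequence or multi-rate set
#'
#' For a single sequence: `nominal_rate_hz = 1000 / mean(isis)` and
#' `max_isi_jitter_ms = max(isis) - min(isis)` (0 iff isochronic). For a
#' multi-rate set, additionally `max_rate_jitter_hz`, the spread between the
#' fastest (`1000/min ISI`) and slowest (`1000/max ISI`) member rates.
#'
#' @param x a `stim_sequence` or `msad_set`.
#' @return A list with `nominal_rate_hz`, `max_isi_jitter_ms`,
#'   `max_rate_jitter_hz` (NA for a single sequence), `sweep_ms`, and for a
#'   set also `rates_hz` (per-member rates) and `rate_range_hz`.
#' @export
seq_metrics <- function(x) {
  if (inherits(x, "msad_set")) {
    isis <- attr(x, "isis")
    rates <- 1000 / isis
    return(list(
      nominal_rate_hz   = 1000 / mean(isis),
      max_isi_jitter_ms = max(isis) - min(isis),
      max_rate_jitter_hz = max(rates) - min(rates),
      rates_hz          = rates,
      rate_range_hz     = range(rates),
      sweep_ms          = sum(isis)
    ))
  }
  stopifnot(inherits(x, "stim_sequence"))
  list(
    nominal_rate_hz   = 1000 / mean(x$isis),
    max_isi_jitter_ms = max(x$isis) - min(x$isis),
    max_rate_jitter_hz = NA_real_,
    sweep_ms          = x$sweep_ms
  )
}

isi_to_samples <- function(isi_ms, fs, tol = 1e-6) {
  k <- isi_ms * fs / 1000
  bad <- abs(k - round(k)) > tol
  if (any(bad)) {
    stop(sprintf(
      "ISI %s ms is not an integer number of samples at fs = %g Hz (%s samples)",
      paste(format(isi_ms[bad]), collapse = ", "), fs,
      paste(format(k[bad]), collapse = ", ")))
  }
  as.integer(round(k))
}

#' Realize a stimulus sequence as an impulse train on a sample grid
#'
#' The train is a binary vector of length `sweep_ms * fs / 1000` with a 1 at
#' each stimulus onset. The first onset is at index 0 (0-based), and the last
#' ISI wraps the loop back to index 0.
#'
#' @param seq a `stim_sequence`.
#' @param fs sampling rate in Hz. Every ISI must be an integer number of
#'   samples at `fs`; the canonical ISIs are multiples of 0.4 ms, so any
#'   multiple of 2.5 kHz works.
#' @return An object of class `impulse_train` with fields `samples` (0/1
#'   vector of length N), `fs`, and `onsets` (0-based onset indices).
#' @export
to_impulse_train <- function(seq, fs) {
  stopifnot(inherits(seq, "stim_sequence"), is.numeric(fs), fs > 0)
  gaps <- isi_to_samples(seq$isis, fs)
  n <- sum(gaps)
  onsets <- cumsum(c(0L, gaps[-length(gaps)]))
  samples <- numeric(n)
  samples[onsets + 1L] <- 1
  structure(list(samples = samples, fs = fs, onsets = onsets),
            class = "impulse_train")
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("<impulse_train> %d clicks in %d samples @ %g Hz\n",
              length(x$onsets), length(x$samples), x$fs))
  invisible(x)
}

## DFT bin frequencies folded onto [0, fs/2] (two-sided bins share a
## physical frequency with their mirror).
bin_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

in_band_bins <- function(n, fs, band) {
  f <- bin_freqs(n, fs)
  which(f >= band[1] & f <= band[2])
}

#' Noise gain factor of a deconvolution sequence
#'
#' The inverse filter `1/S(k)` that recovers the transient response from a
#' looped sweep rescales stationary noise at each DFT bin by `1/|S(k)|`,
#' where `S` is the DFT of the sweep's impulse train. The noise gain factor
#' summarizes this over the recording band as the root-mean-square of
#' `1/|S(k)|` across in-band bins:
#' \deqn{C_{dec} = \sqrt{ \mathrm{mean}_{k \in band} \; 1/|S(k)|^2 }}
#' A value below 1 means the deconvolution attenuates stationary noise
#' relative to plain averaging of an equal number of sweeps.
#'
#' The band convention (default 10–1000 Hz, the usual recording passband,
#' DC excluded) is configurable: published values for specific sequences
#' depend on the band used, which is not always restated.
#'
#' @param train an `impulse_train`.
#' @param band numeric length-2, band edges in Hz.
#' @param floor smallest `|S(k)|` tolerated in-band; any smaller magnitude
#'   makes the sequence unusable and raises an error listing the bins.
#' @return The dimensionless noise gain (a single number).
#' @export
noise_gain_cdec <- function(train, band = c(10, 1000), floor = 1e-8) {
  stopifnot(inherits(train, "impulse_train"))
  predicted_noise_gain(train, ridge = 0, band = band, floor = floor)
}

#' Predicted noise gain of the (possibly ridged) inverse filter
#'
#' Closed-form root-mean-square gain of the filter
#' `conj(S)/(|S|^2 + lambda)` over the in-band bins. With `ridge = 0` this
#' is exactly [noise_gain_cdec()]; as `ridge` grows the filter, and hence
#' the gain, shrinks toward zero.
#'
#' @inheritParams noise_gain_cdec
#' @param ridge non-negative Tikhonov-style ridge added to `|S|^2`.
#' @return The dimensionless predicted noise gain.
#' @export
predicted_noise_gain <- function(train, ridge = 0, band = c(10, 1000),
                                 floor = 1e-8) {
  stopifnot(inherits(train, "impulse_train"), ridge >= 0)
  n <- length(train$samples)
  S <- stats::fft(train$samples)
  bins <- in_band_bins(n, train$fs, band)
  if (length(bins) == 0L) stop("no DFT bins inside the requested band")
  mag <- Mod(S[bins])
  if (ridge == 0 && any(mag < floor)) {
    stop("sequence spectrum vanishes in-band at bins (0-based): ",
         paste(bins[mag < floor] - 1L, collapse = ", "),
         "; the sequence is unusable without regularization")
  }
  gain2 <- (mag / (mag^2 + ridge))^2
  sqrt(mean(gain2))
}
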