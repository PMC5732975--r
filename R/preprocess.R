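#' Reject artifact-contaminated sweeps
#'
#' A sweep is rejected when the absolute amplitude of *any* data point
#' exceeds the threshold; a point exactly at the threshold is kept (the
#' rule is "more than" the threshold, read strictly).
#'
#' @param sweeps a `sweep_set`.
#' @param threshold_uv rejection threshold in µV (default 40).
#' @return list with `sweeps` (the surviving `sweep_set`) and `report`
#'   (list: `rejected` — row indices removed, `n_rejected`, `n_kept`,
#'   `threshold_uv`).
#' @export
reject_artifacts <- function(sweeps, threshold_uv = 40) {
  stopifnot(inherits(sweeps, "sweep_set"), threshold_uv > 0)
  peak <- apply(abs(sweeps$data), 1, max)
  bad <- which(peak > threshold_uv)
  if (length(bad) == nrow(sweeps$data)) {
    stop("all ", length(bad), " sweeps exceed ", threshold_uv,
         " uV; review the threshold or the noise level")
  }
  kept <- sweeps
  if (length(bad) > 0) kept$data <- sweeps$data[-bad, , drop = FALSE]
  list(sweeps = kept,
       report = list(rejected = bad, n_rejected = length(bad),
                     n_kept = nrow(kept$data), threshold_uv = threshold_uv))
}

#' Ensemble-average sweeps with an odd/even consistency score
#'
#' Plain arithmetic mean across sweeps. As a data-quality check, the
#' Pearson correlation between the average of odd-indexed and the average
#' of even-indexed sweeps is reported; a low score (e.g. r < 0.5) flags an
#' inconsistent recording.
#'
#' @param sweeps a `sweep_set` (or plain matrix, sweeps x samples).
#' @param discard_first number of leading sweeps dropped before averaging
#'   (onset-effect guard); default 0.
#' @return list with `average` (numeric waveform, µV), `consistency`
#'   (Pearson r, `NA` with a warning when fewer than 2 sweeps), `n_used`.
#' @export
average_sweeps <- function(sweeps, discard_first = 0) {
  data <- if (inherits(sweeps, "sweep_set")) sweeps$data else as.matrix(sweeps)
  if (discard_first > 0) {
    if (discard_first >= nrow(data)) stop("discard_first leaves no sweeps")
    data <- data[-seq_len(discard_first), , drop = FALSE]
  }
  avg <- colMeans(data)
  n <- nrow(data)
  if (n < 2) {
    warning("single sweep: consistency score undefined")
    return(list(average = avg, consistency = NA_real_, n_used = n))
  }
  odd <- colMeans(data[seq(1, n, by = 2), , drop = FALSE])
  even <- colMeans(data[seq(2, n, by = 2), , drop = FALSE])
  r <- if (stats::sd(odd) == 0 || stats::sd(even) == 0) NA_real_
       else stats::cor(odd, even)
  list(average = avg, consistency = r, n_used = n)
}

#' Fold a periodic record into a one-cycle average
#'
#' @param waveform numeric vector whose length is an integer multiple of
#'   `period_samples`.
#' @param period_samples stimulation period in samples.
#' @param discard_cycles leading cycles dropped before averaging (onset
#'   guard; irrelevant for circularly simulated data).
#' @return numeric vector of length `period_samples`.
#' @export
fold_cycles <- function(waveform, period_samples, discard_cycles = 0) {
  n <- length(waveform)
  if (n %% period_samples != 0) {
    stop("record length ", n, " is not an integer multiple of the period ",
         period_samples)
  }
  k <- n %/% period_samples
  if (discard_cycles >= k) stop("discard_cycles leaves no cycles")
  m <- matrix(waveform, nrow = period_samples)[, (discard_cycles + 1):k,
                                               drop = FALSE]
  rowMeans(m)
}

#' A steady-state (periodic or quasi-periodic) averaged record
#'
#' @param waveform numeric, µV.
#' @param fs sampling rate, Hz.
#' @param segments integer vector of segment lengths in samples; their sum
#'   must equal the waveform length. A purely periodic record has equal
#'   segments.
#' @param isis_ms per-segment ISI in ms (optional bookkeeping).
#' @param n_cycles for a periodic record, the number of cycles.
#' @param f0 fundamental (stimulation) frequency in Hz, when defined.
#' @return object of class `steady_state_record`.
#' @export
steady_state_record <- function(waveform, fs, segments, isis_ms = NULL,
                                n_cycles = NULL, f0 = NULL) {
  stopifnot(sum(segments) == length(waveform))
  structure(list(waveform = as.numeric(waveform), fs = fs,
                 segments = as.integer(segments), isis_ms = isis_ms,
                 n_cycles = n_cycles, f0 = f0),
            class = "steady_state_record")
}

#' @export
print.steady_state_record <- function(x, ...) {
  cat(sprintf("<steady_state_record> %d samples @ %g Hz, %d segment(s)%s\n",
              length(x$waveform), x$fs, length(x$segments),
              if (!is.null(x$n_cycles)) sprintf(", %d cycles", x$n_cycles) else ""))
  invisible(x)
}

#' Splice per-rate one-cycle averages into the multi-rate record
#'
#' The eight (in general, `length(isis)`) one-cycle steady-state averages,
#' one per isochronic rate, are concatenated in the order of the jittered
#' sequence's ISI list. The result is the multi-rate observation vector of
#' the fold-matrix inverse problem; its total length equals one jittered
#' sweep.
#'
#' @param cycles list of numeric one-cycle waveforms, one per ISI, each of
#'   length `isi * fs / 1000`.
#' @param isis ISI list in ms fixing the splice order.
#' @param fs sampling rate, Hz.
#' @return a `steady_state_record` with one segment per rate.
#' @export
build_multi_rate_assr <- function(cycles, isis, fs) {
  if (length(cycles) != length(isis)) {
    stop("need one cycle average per ISI; missing: ",
         paste(format(isis[seq_along(isis) > length(cycles)]), collapse = ", "))
  }
  periods <- isi_to_samples(isis, fs)
  for (i in seq_along(isis)) {
    if (length(cycles[[i]]) != periods[i]) {
      stop(sprintf("cycle %d has %d samples but ISI %.2f ms needs %d",
                   i, length(cycles[[i]]), isis[i], periods[i]))
    }
  }
  steady_state_record(unlist(cycles), fs, segments = periods, isis_ms = isis)
}

#' Assemble the classical recorded steady-state response
#'
#' Folds an averaged isochronic record to one cycle, then tiles it to
#' `n_cycles` cycles (default four, i.e. a 102.4 ms window at a 25.6 ms
#' ISI).
#'
#' @param average numeric averaged waveform whose length is an integer
#'   multiple of the period.
#' @param isi_ms isochronic ISI in ms.
#' @param fs sampling rate, Hz.
#' @param n_cycles cycles in the output record.
#' @param discard_cycles leading cycles dropped before folding.
#' @return a `steady_state_record` with `n_cycles` set and `f0 = 1000/isi`.
#' @export
build_rassr <- function(average, isi_ms, fs, n_cycles = 4,
                        discard_cycles = 0) {
  p <- isi_to_samples(isi_ms, fs)
  one <- fold_cycles(average, p, discard_cycles)
  steady_state_record(rep(one, n_cycles), fs,
                      segments = rep(p, n_cycles),
                      isis_ms = rep(isi_ms, n_cycles),
                      n_cycles = n_cycles, f0 = 1000 / isi_ms)
}
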