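#' Default component isolation windows
#'
#' Time intervals (ms from stimulus onset) used to isolate the canonical
#' transient components. Only the wave-V and wave-Pa anchors are
#' constrained by the template defaults; the remaining boundaries are
#' conventional choices and fully configurable.
#'
#' @return named list of `c(start_ms, end_ms)` windows, ordered
#'   V < Na < Pa < Nb < Pb.
#' @export
component_windows <- function() {
  list(V = c(5, 12), Na = c(12, 22), Pa = c(22, 35),
       Nb = c(35, 48), Pb = c(48, 70))
}

#' Synthesize a steady-state response from a transient template
#'
#' Implements the superposition construction: the template is folded at
#' the isochronic stimulation period (equivalently, circularly convolved
#' with the isochronic impulse train) and the resulting one-cycle
#' steady-state response is tiled over `n_cycles`.
#'
#' @param template a `transient_aep`.
#' @param isi_ms isochronic ISI in ms; must be an integer number of samples.
#' @param n_cycles number of cycles in the output (default 4, i.e. a
#'   102.4 ms window at the 25.6 ms ISI).
#' @return a `steady_state_record` with `f0 = 1000 / isi_ms`.
#' @export
synthesize_assr <- function(template, isi_ms, n_cycles = 4) {
  stopifnot(inherits(template, "transient_aep"), n_cycles >= 1)
  p <- isi_to_samples(isi_ms, template$fs)
  x <- template$waveform
  pad <- ceiling(length(x) / p) * p - length(x)
  cycle <- fold_cycles(c(x, numeric(pad)), p) * (length(x) + pad) / p
  # fold_cycles averages; the steady-state cycle is the *sum* of wrapped
  # copies, hence the rescale by the number of wraps
  steady_state_record(rep(cycle, n_cycles), template$fs,
                      segments = rep(p, n_cycles),
                      isis_ms = rep(isi_ms, n_cycles),
                      n_cycles = n_cycles, f0 = 1000 / isi_ms)
}

#' Isolate one transient component by zeroing the others
#'
#' Returns a copy of the template that equals the (baseline-referenced)
#' template inside the component's window and zero elsewhere. The baseline
#' is the mean over a pre-stimulus reference segment. Optionally the window
#' edges are smoothed with a cosine taper to suppress edge spectra.
#'
#' @param template a `transient_aep`.
#' @param windows named list of windows in ms (see [component_windows()]).
#' @param name component to keep; must name an entry of `windows`.
#' @param baseline_ms length-2 segment (ms) whose mean defines the
#'   baseline; default `c(0, 1)`.
#' @param taper_ms half-cosine taper length at each edge, ms; 0 (default)
#'   gives hard zeroing.
#' @return a `transient_aep`.
#' @export
isolate_component <- function(template, windows = component_windows(), name,
                              baseline_ms = c(0, 1), taper_ms = 0) {
  stopifnot(inherits(template, "transient_aep"))
  if (!name %in% names(windows)) {
    stop("unknown component \"", name, "\"; windows define: ",
         paste(names(windows), collapse = ", "))
  }
  w <- template$waveform
  t_ms <- (seq_along(w) - 1) / template$fs * 1000
  base_idx <- t_ms >= baseline_ms[1] & t_ms <= baseline_ms[2]
  base <- if (any(base_idx)) mean(w[base_idx]) else 0
  win <- windows[[name]]
  mask <- as.numeric(t_ms >= win[1] & t_ms < win[2])
  if (taper_ms > 0) {
    for (edge in win) {
      ramp <- abs(t_ms - edge) < taper_ms
      up <- 0.5 * (1 - cos(pi * (t_ms[ramp] - (edge - taper_ms)) / taper_ms))
      if (edge == win[1]) mask[ramp] <- pmin(mask[ramp] + up, up)
      else mask[ramp] <- pmin(mask[ramp], 1 - up)
    }
  }
  transient_aep((w - base) * mask, template$fs)
}

#' Component contributions to the synthetic steady-state response
#'
#' For each component `c`, the raw contribution is the RMS ratio
#' `100 * RMS(ASSR from isolated c) / RMS(ASSR from full template)`.
#' Because the components partially cancel when superimposed, the raw
#' ratios typically sum to well over 100%; the normalized column rescales
#' them to a total of 100% for cross-paradigm comparison.
#'
#' @inheritParams synthesize_assr
#' @param windows named list of component windows in ms.
#' @param taper_ms passed to [isolate_component()].
#' @return data.frame with columns `component`, `raw_pct`,
#'   `normalized_pct`; the normalized column sums to 100.
#' @export
contribution_table <- function(template, windows = component_windows(),
                               isi_ms = 25.6, n_cycles = 4, taper_ms = 0) {
  stopifnot(inherits(template, "transient_aep"))
  full <- synthesize_assr(template, isi_ms, n_cycles)
  rms_full <- sqrt(mean(full$waveform^2))
  if (rms_full == 0) stop("all-zero template: contributions undefined")
  raw <- vapply(names(windows), function(nm) {
    comp <- isolate_component(template, windows, nm, taper_ms = taper_ms)
    100 * sqrt(mean(synthesize_assr(comp, isi_ms, n_cycles)$waveform^2)) /
      rms_full
  }, numeric(1))
  data.frame(component = names(windows), raw_pct = unname(raw),
             normalized_pct = unname(100 * raw / sum(raw)),
             row.names = NULL)
}
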