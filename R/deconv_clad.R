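#' Recover the transient AEP by frequency-domain inverse filtering
#'
#' Under the linear-superposition model the averaged jittered-sweep
#' response `y` is the circular convolution of the implicit transient
#' response `x` with the sweep's impulse train `s`. In the frequency
#' domain `Y(k) = X(k) S(k)`, so the transient is recovered by the inverse
#' filter
#' \deqn{X(k) = Y(k)\,\overline{S(k)} / (|S(k)|^2 + \lambda)}
#' and an inverse DFT. With `ridge = 0` this is exact division — valid only
#' when the sequence spectrum has no (near-)zeros, which is what jittered
#' sequences are designed for. A small ridge trades bias for noise
#' suppression on poorly conditioned sequences.
#'
#' @param record a `steady_state_record` (or plain numeric vector) of the
#'   same length as the train.
#' @param train the sweep's `impulse_train`.
#' @param ridge non-negative regularization constant added to `|S|^2`.
#' @param floor smallest `|S(k)|` tolerated when `ridge = 0`.
#' @return a `transient_aep` of the same length as the record.
#' @export
clad_deconvolve <- function(record, train, ridge = 0, floor = 1e-8) {
  stopifnot(inherits(train, "impulse_train"), ridge >= 0)
  y <- if (inherits(record, "steady_state_record")) record$waveform else record
  n <- length(train$samples)
  if (length(y) != n) {
    stop("record length (", length(y), ") must equal train length (", n, ")")
  }
  S <- stats::fft(train$samples)
  if (ridge == 0) {
    small <- which(Mod(S) < floor)
    if (length(small) > 0) {
      stop("sequence spectrum below floor at bins (0-based): ",
           paste(small - 1L, collapse = ", "),
           "; use a ridge or a better sequence")
    }
  }
  X <- stats::fft(y) * Conj(S) / (Mod(S)^2 + ridge)
  x <- stats::fft(X, inverse = TRUE) / n
  resid <- sqrt(mean(Im(x)^2))
  scale <- max(sqrt(mean(Re(x)^2)), .Machine$double.eps)
  if (resid > 1e-9 * scale && resid > 1e-12) {
    stop("non-negligible imaginary residue after inverse transform (",
         format(resid), "); circular-convolution model violated")
  }
  transient_aep(Re(x), train$fs)
}
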