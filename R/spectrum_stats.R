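#' Complex Fourier coefficients at the stimulus-rate harmonics
#'
#' A steady-state record of `C` whole cycles concentrates its energy at
#' DFT bins `C, 2C, 3C, ...` — the stimulus-rate harmonics (40, 80,
#' 120 Hz for a 40 Hz response). The first `n_harmonics` complex
#' coefficients are extracted and scaled to the RMS-amplitude convention:
#' a pure cosine of peak amplitude `A` at harmonic `h` yields
#' `|coef[h]| = A / sqrt(2)`.
#'
#' @param record a `steady_state_record` with `n_cycles` set, or a plain
#'   numeric vector with `n_cycles` supplied.
#' @param n_harmonics number of harmonics to keep (default 3).
#' @param n_cycles override/fallback for the number of cycles.
#' @return object of class `harmonic_set`: `f0` (Hz, may be NA), `coef`
#'   (complex vector, RMS µV), `n_cycles`, `length`, `convention = "rms"`.
#' @export
harmonic_set <- function(record, n_harmonics = 3, n_cycles = NULL) {
  if (inherits(record, "steady_state_record")) {
    if (is.null(n_cycles)) n_cycles <- record$n_cycles
    y <- record$waveform
    f0 <- record$f0
  } else {
    y <- as.numeric(record)
    f0 <- NA_real_
  }
  if (is.null(n_cycles)) stop("n_cycles must be known for harmonic analysis")
  L <- length(y)
  if (L %% n_cycles != 0) {
    stop("record length ", L, " is not an integer number of cycles (",
         n_cycles, ")")
  }
  if (n_harmonics * n_cycles >= L / 2 + 1) {
    stop("requested harmonics exceed the Nyquist bin")
  }
  Y <- stats::fft(y)
  bins <- (1:n_harmonics) * n_cycles + 1L       # 1-based DFT indices
  coef <- sqrt(2) * Y[bins] / L                 # peak = 2|Y|/L; rms = peak/sqrt(2)
  structure(list(f0 = if (is.null(f0)) NA_real_ else f0, coef = coef,
                 n_cycles = n_cycles, length = L, convention = "rms"),
            class = "harmonic_set")
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("<harmonic_set> f0 = %s Hz, %d harmonics (RMS uV): %s\n",
              format(x$f0), length(x$coef),
              paste(sprintf("%.3g", Mod(x$coef)), collapse = ", ")))
  invisible(x)
}

#' Flatten a harmonic set to the paired real/imaginary vector
#'
#' The frequency-domain representation used for multivariate comparison:
#' `(Re h1, Im h1, Re h2, Im h2, ...)`, six elements for three harmonics.
#'
#' @param hset a `harmonic_set`.
#' @return numeric vector of length `2 * n_harmonics`.
#' @export
harmonic_vector <- function(hset) {
  stopifnot(inherits(hset, "harmonic_set"))
  as.numeric(rbind(Re(hset$coef), Im(hset$coef)))
}

#' Time-domain reconstruction from the retained harmonics
#'
#' Inverse synthesis of the harmonic set: the sum of the retained
#' harmonic cosines. The residual `record - reconstruction` holds the
#' energy outside the retained bins (non-negative by Parseval).
#'
#' @param hset a `harmonic_set`.
#' @param length output length in samples; defaults to the analyzed
#'   record's length.
#' @return numeric waveform.
#' @export
reconstruct_harmonics <- function(hset, length = hset$length) {
  stopifnot(inherits(hset, "harmonic_set"))
  tt <- 0:(length - 1)
  out <- numeric(length)
  for (h in seq_along(hset$coef)) {
    a_peak <- hset$coef[h] * sqrt(2)   # back to peak convention
    out <- out + Re(a_peak * exp(2i * pi * h * hset$n_cycles * tt / hset$length))
  }
  out
}

#' Pointwise one-sample t-tests along a difference waveform
#'
#' At each sample, a two-sided one-sample t-test of the across-subject
#' differences against zero. No multiple-comparison correction is applied
#' (by design — the significant-fraction metric summarizes the raw mask;
#' interpret accordingly). Samples with zero variance get `p = 1` when the
#' mean is also zero and `p = 0` otherwise.
#'
#' @param diff_matrix numeric matrix, subjects x samples, of difference
#'   waveforms (µV).
#' @param alpha significance level for the mask (default 0.05).
#' @return object of class `diff_trace`: `mean` (µV), `p` (per sample),
#'   `mask` (logical, `p < alpha`), `fraction_pct` (100 x mean(mask)),
#'   `alpha`, `n`.
#' @export
pointwise_ttest <- function(diff_matrix, alpha = 0.05) {
  x <- as.matrix(diff_matrix)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects for pointwise t-tests")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  p <- numeric(ncol(x))
  zero_var <- s == 0
  p[zero_var] <- ifelse(m[zero_var] == 0, 1, 0)
  if (any(!zero_var)) {
    tstat <- m[!zero_var] / (s[!zero_var] / sqrt(n))
    p[!zero_var] <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  }
  mask <- p < alpha
  structure(list(mean = m, p = p, mask = mask,
                 fraction_pct = 100 * mean(mask), alpha = alpha, n = n),
            class = "diff_trace")
}

#' @export
print.diff_trace <- function(x, ...) {
  cat(sprintf("<diff_trace> n = %d, %d samples, %.2f%% significant at alpha = %g\n",
              x$n, length(x$p), x$fraction_pct, x$alpha))
  invisible(x)
}

#' One-sample Hotelling's T-squared test
#'
#' Tests whether the population mean of p-variate observations is zero:
#' `T2 = n * m' S^-1 m` with sample mean `m` and sample covariance `S`,
#' converted to `F = T2 (n - p) / (p (n - 1))` on `(p, n - p)` degrees of
#' freedom. Also returns the `(1 - alpha)` confidence ellipsoid of the
#' mean (for `p = 2`, the familiar confidence ellipse in the complex
#' plane: the null is rejected iff the ellipse excludes the origin).
#'
#' @param x numeric matrix, subjects x p.
#' @param alpha level for the confidence ellipsoid.
#' @return object of class `hotelling_result`: `n`, `p`, `mean`, `cov`,
#'   `t2`, `f`, `df = c(p, n - p)`, `p_value`, `ellipse` (list: `center`,
#'   `radii`, `axes` — unit eigenvectors as columns).
#' @export
hotelling_one_sample <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("Hotelling's T2 needs n > p (n = ", n, ", p = ", p, ")")
  m <- colMeans(x)
  S <- stats::cov(x)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular covariance; T2 undefined"))
  t2 <- drop(n * t(m) %*% Sinv %*% m)
  f <- t2_to_f(t2, n, p)
  pval <- stats::pf(f, p, n - p, lower.tail = FALSE)
  eg <- eigen(S / n, symmetric = TRUE)
  scale <- p * (n - 1) / (n - p) * stats::qf(1 - alpha, p, n - p)
  structure(list(n = n, p = p, mean = m, cov = S, t2 = t2, f = f,
                 df = c(p, n - p), p_value = pval,
                 ellipse = list(center = m,
                                radii = sqrt(pmax(eg$values, 0) * scale),
                                axes = eg$vectors)),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("<hotelling> n = %d, p = %d: T2 = %.2f, F(%d, %d) = %.2f, p = %.3g\n",
              x$n, x$p, x$t2, x$df[1], x$df[2], x$f, x$p_value))
  invisible(x)
}

#' Convert Hotelling's T-squared to its F statistic
#'
#' `F = T2 (n - p) / (p (n - 1))`, distributed as `F(p, n - p)` under the
#' null of zero mean.
#'
#' @param t2 the T-squared statistic (>= 0).
#' @param n number of subjects.
#' @param p dimension of the vectors.
#' @return the F statistic.
#' @export
t2_to_f <- function(t2, n, p) {
  stopifnot(t2 >= 0, p >= 1)
  if (n <= p) stop("conversion requires n > p")
  t2 * (n - p) / (p * (n - 1))
}

#' Robust-distance outlier screen for multivariate samples
#'
#' Flags subjects whose robust (minimum covariance determinant) Mahalanobis
#' distance exceeds the chi-squared quantile at `1 - alpha` with `p`
#' degrees of freedom — a documented, reproducible stand-in for
#' normality-macro-driven outlier removal. Degenerate samples (singular
#' robust covariance, e.g. identical rows) are passed through untouched.
#'
#' @param x numeric matrix, subjects x p.
#' @param alpha tail probability of the distance cutoff (default 0.025,
#'   i.e. the 97.5% quantile).
#' @return list with `kept` (row indices retained), `removed`,
#'   `distances` (squared robust distances), `cutoff`.
#' @export
outlier_policy <- function(x, alpha = 0.025) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 5) stop("outlier screening needs at least 5 subjects")
  cutoff <- stats::qchisq(1 - alpha, df = p)
  rob <- tryCatch(
    suppressWarnings(MASS::cov.rob(x, method = "mcd")),
    error = function(e) NULL)
  if (is.null(rob) || any(!is.finite(rob$cov)) ||
      abs(det(rob$cov)) < .Machine$double.eps) {
    return(list(kept = seq_len(n), removed = integer(0),
                distances = rep(0, n), cutoff = cutoff))
  }
  d2 <- stats::mahalanobis(x, rob$center, rob$cov)
  # reweighting (standard for MCD, iterated to a fixed point): re-estimate
  # the moments from the points the current distances accept, recompute the
  # distances. On clean data this converges to near-classical moments and
  # removes the raw estimator's small-sample distance inflation.
  # consistency factor: covariance of a chi-square-truncated Gaussian
  # underestimates the true scatter by this amount
  cons <- stats::pchisq(cutoff, p + 2) / stats::pchisq(cutoff, p)
  for (it in 1:5) {
    w <- d2 <= cutoff
    if (sum(w) <= p + 1) break
    xs <- x[w, , drop = FALSE]
    Sw <- stats::cov(xs) / cons
    if (abs(det(Sw)) < .Machine$double.eps) break
    d2_new <- stats::mahalanobis(x, colMeans(xs), Sw)
    if (identical(d2_new > cutoff, d2 > cutoff)) { d2 <- d2_new; break }
    d2 <- d2_new
  }
  removed <- which(d2 > cutoff)
  list(kept = setdiff(seq_len(n), removed), removed = removed,
       distances = d2, cutoff = cutoff)
}
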