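#' Build the fold matrix linking a transient response to multi-rate records
#'
#' At an isochronic stimulation period of `P` samples, the steady-state
#' one-cycle response is the transient response "folded" at `P`:
#' `cycle[n] = sum over m = n, n+P, n+2P, ... of x[m]`. Stacking the fold
#' operators of several periods gives a binary matrix `A`
#' (`sum(periods)` rows by `N` columns) with
#' `A[(r, n), m] = 1` iff `m = n (mod P_r)`, mapping the common transient
#' `x` to the concatenated multi-rate observation `b = A x`.
#'
#' @param periods integer vector of stimulation periods in samples.
#' @param n_transient transient support `N` in samples; must be at least
#'   the largest period (otherwise some rows would be empty).
#' @return object of class `fold_system`: fields `A`, `periods`,
#'   `n_transient`.
#' @export
build_fold_system <- function(periods, n_transient) {
  periods <- as.integer(periods)
  stopifnot(all(periods >= 1))
  if (n_transient < max(periods)) {
    stop("n_transient (", n_transient, ") must be >= the largest period (",
         max(periods), ")")
  }
  m <- sum(periods)
  A <- matrix(0, nrow = m, ncol = n_transient)
  row0 <- 0L
  cols <- 0:(n_transient - 1L)
  for (p in periods) {
    phase <- cols %% p                      # 0-based phase of each column
    A[cbind(row0 + phase + 1L, cols + 1L)] <- 1
    row0 <- row0 + p
  }
  structure(list(A = A, periods = periods, n_transient = as.integer(n_transient)),
            class = "fold_system")
}

#' @export
print.fold_system <- function(x, ...) {
  cat(sprintf("<fold_system> %d x %d, %d rates (periods %s)\n",
              nrow(x$A), ncol(x$A), length(x$periods),
              paste(x$periods, collapse = ", ")))
  invisible(x)
}

## SVD cached on the fold_system so repeated solves are cheap
fold_svd <- function(system) {
  if (is.null(attr(system, "svd"))) svd(system$A) else attr(system, "svd")
}

#' Attach a precomputed SVD to a fold system
#'
#' Solving for many records with the same system (e.g. Monte-Carlo
#' replicates) repeats an identical SVD; this computes it once.
#' @param system a `fold_system`.
#' @return the system with the SVD attached.
#' @export
with_svd <- function(system) {
  attr(system, "svd") <- svd(system$A)
  system
}

#' Solve the multi-rate fold system with SVD-based regularization
#'
#' The fold system is an ill-conditioned linear inverse problem: the
#' transient estimate is obtained either by truncated SVD (minimum-norm
#' least squares restricted to the top `k` singular triplets) or Tikhonov
#' regularization (minimize `||Ax - b||^2 + lambda^2 ||x||^2`).
#'
#' `parameter = "auto"` selects the regularization strength from the data:
#' generalized cross-validation for Tikhonov; for TSVD, the discrepancy
#' principle — the smallest truncation whose residual norm falls below
#' `noise_level * sqrt(nrow(A))`. When `noise_level` is not supplied it is
#' estimated as the RMS of the spectral coefficients `u_i' b` in the last
#' tenth of the singular spectrum, where the signal content is weakest.
#'
#' @param record a `steady_state_record` (the spliced multi-rate
#'   observation) or plain numeric vector of length `sum(periods)`.
#' @param system a `fold_system` (optionally carrying a cached SVD from
#'   [with_svd()]).
#' @param method `"tikhonov"` or `"tsvd"`.
#' @param parameter `"auto"`, or a number: the truncation index `k` for
#'   TSVD, or `lambda >= 0` for Tikhonov. `lambda = 0` (or `k = rank`)
#'   gives the unregularized minimum-norm solution.
#' @param noise_level per-sample RMS noise estimate of `b` (µV), used by
#'   the TSVD discrepancy rule.
#' @param fs sampling rate of the estimate; taken from `record` when it is
#'   a `steady_state_record`.
#' @return object of class `reg_solution`: `estimate` (a `transient_aep`),
#'   `method`, `parameter` (the value actually used), `singular_values`,
#'   `residual_norm`, `solution_norm`, `condition_number`.
#' @export
msad_deconvolve <- function(record, system, method = c("tikhonov", "tsvd"),
                            parameter = "auto", noise_level = NULL,
                            fs = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(system, "fold_system"))
  if (inherits(record, "steady_state_record")) {
    if (is.null(fs)) fs <- record$fs
    b <- record$waveform
  } else b <- as.numeric(record)
  if (is.null(fs)) fs <- NA_real_
  if (length(b) != nrow(system$A)) {
    stop("record length (", length(b), ") must equal sum of periods (",
         nrow(system$A), ")")
  }
  sv <- fold_svd(system)
  d <- sv$d
  tol <- max(dim(system$A)) * .Machine$double.eps * d[1]
  rank <- sum(d > tol)
  beta <- drop(crossprod(sv$u, b))          # spectral coefficients
  perp2 <- max(sum(b^2) - sum(beta^2), 0)   # energy outside the column space

  if (method == "tsvd") {
    if (identical(parameter, "auto")) {
      if (is.null(noise_level)) {
        tail_idx <- seq.int(max(1L, floor(0.9 * rank)), rank)
        noise_level <- sqrt(mean(beta[tail_idx]^2))
      }
      target <- noise_level * sqrt(nrow(system$A))
      res2 <- rev(cumsum(rev(c(beta[seq_len(rank)]^2, 0))))[-1] + perp2
      ok <- which(sqrt(res2) <= target)
      k <- if (length(ok) > 0) min(ok) else rank
    } else {
      k <- as.integer(parameter)
      if (k < 1 || k > rank) stop("truncation index must be in 1..rank (", rank, ")")
    }
    x <- sv$v[, seq_len(k), drop = FALSE] %*% (beta[seq_len(k)] / d[seq_len(k)])
    used <- k
  } else {
    if (identical(parameter, "auto")) {
      used <- gcv_lambda(d[seq_len(rank)], beta[seq_len(rank)], perp2,
                         nrow(system$A))
    } else {
      used <- as.numeric(parameter)
      if (used < 0) stop("lambda must be >= 0")
    }
    f <- d[seq_len(rank)] / (d[seq_len(rank)]^2 + used^2)
    x <- sv$v[, seq_len(rank), drop = FALSE] %*% (f * beta[seq_len(rank)])
  }
  x <- drop(x)
  resid <- sqrt(sum((system$A %*% x - b)^2))
  structure(list(
    estimate = transient_aep(x, fs),
    method = method, parameter = used,
    singular_values = d,
    residual_norm = resid, solution_norm = sqrt(sum(x^2)),
    condition_number = d[1] / d[rank]
  ), class = "reg_solution")
}

## GCV for Tikhonov via the SVD: minimize ||Ax - b||^2 / (m - sum f_i)^2
## over a log-spaced lambda grid spanning the singular spectrum.
gcv_lambda <- function(d, beta, perp2, m, n_grid = 80) {
  lams <- exp(seq(log(max(d[length(d)], d[1] * 1e-8)), log(d[1]),
                  length.out = n_grid))
  score <- vapply(lams, function(l) {
    filt <- d^2 / (d^2 + l^2)
    res2 <- sum(((1 - filt) * beta)^2) + perp2
    den <- (m - sum(filt))^2
    if (den <= 0) Inf else res2 / den
  }, numeric(1))
  lams[which.min(score)]
}

#' @export
print.reg_solution <- function(x, ...) {
  cat(sprintf(
    "<reg_solution> %s (parameter %.4g): residual %.4g, norm %.4g, cond %.4g\n",
    x$method, x$parameter, x$residual_norm, x$solution_norm,
    x$condition_number))
  invisible(x)
}

#' Summarize the quality of a regularized reconstruction
#'
#' Always reports the condition number and the norms; when the ground-truth
#' transient is supplied, additionally the RMSE and, per component window,
#' the peak-latency and peak-amplitude errors.
#'
#' @param solution a `reg_solution`.
#' @param truth optional `transient_aep` (must match the estimate length).
#' @param windows optional named list of `[start, end]` windows in ms (see
#'   [component_windows()]); peaks are located as extrema of matching sign.
#' @return list with `condition_number`, `singular_values`,
#'   `residual_norm`, `solution_norm`, and when truth is given `rmse_uv`
#'   plus a data.frame `components` of per-window errors.
#' @export
recovery_report <- function(solution, truth = NULL, windows = NULL) {
  stopifnot(inherits(solution, "reg_solution"))
  out <- list(condition_number = solution$condition_number,
              singular_values = solution$singular_values,
              residual_norm = solution$residual_norm,
              solution_norm = solution$solution_norm)
  if (!is.null(truth)) {
    est <- solution$estimate$waveform
    tw <- truth$waveform
    stopifnot(length(est) == length(tw))
    out$rmse_uv <- sqrt(mean((est - tw)^2))
    if (!is.null(windows)) {
      fs <- solution$estimate$fs
      rows <- lapply(names(windows), function(nm) {
        win <- windows[[nm]]
        idx <- which((seq_along(tw) - 1) / fs * 1000 >= win[1] &
                     (seq_along(tw) - 1) / fs * 1000 <= win[2])
        if (length(idx) == 0) return(NULL)
        pk <- function(w) {
          i <- idx[which.max(abs(w[idx]))]
          c(lat = (i - 1) / fs * 1000, amp = w[i])
        }
        pt <- pk(tw); pe <- pk(est)
        data.frame(component = nm,
                   latency_error_ms = pe["lat"] - pt["lat"],
                   amplitude_error_uv = pe["amp"] - pt["amp"],
                   row.names = NULL)
      })
      out$components <- do.call(rbind, rows)
    }
  }
  out
}
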