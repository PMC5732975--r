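# shared fixtures: everything is generated in code, test rate 2.5 kHz so the
# canonical ISIs are integer samples (paper grid / 8) and sweeps are 512 long

FS_TEST <- 2500
PAPER_ISIS <- c(16.00, 28.80, 19.20, 27.20, 24.00, 32.00, 36.80, 20.80)
PAPER_PERIODS <- as.integer(PAPER_ISIS * FS_TEST / 1000)  # {40,72,...,52}

default_template <- function(fs = FS_TEST, ...) {
  make_template(template_spec(aep_components(...), 204.8, fs))
}

paper_train <- function(fs = FS_TEST) {
  to_impulse_train(make_clad_sequence(PAPER_ISIS), fs)
}

# independent brute-force oracle: steady-state one-cycle response at period P
# by explicit time-domain overlap of wrapped template copies
oracle_fold <- function(x, p) {
  out <- numeric(p)
  for (m in seq_along(x)) {
    out[(m - 1) %% p + 1] <- out[(m - 1) %% p + 1] + x[m]
  }
  out
}

# independent brute-force circular convolution (time domain, O(n^2))
oracle_circ_conv <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (i in 0:(n - 1)) {
    out[i + 1] <- sum(a * b[((i - (0:(n - 1))) %% n) + 1])
  }
  out
}
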