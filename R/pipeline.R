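#' Configuration of a synthetic superposition study
#'
#' Bundles every knob of the end-to-end pipeline. The defaults mirror the
#' reference recording setup: 19 analyzed subjects, 1,500 sweeps per
#' paradigm, 20 kHz sampling, 10–1000 Hz noise band, the canonical 8-ISI
#' jittered sequence, a 25.6 ms isochronic control observed over four
#' cycles, and a 204.8 ms traditional epoch. [fast_profile()] shrinks this
#' to a seconds-scale configuration for tests.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_sweeps sweeps per paradigm: a single number or a named list
#'   (`traditional`, `clad`, `msad`, `control`); for `msad` this is the
#'   sweep count per rate.
#' @param fs sampling rate, Hz.
#' @param isis jittered-sequence ISIs (ms), shared with the multi-rate set.
#' @param control_isi_ms isochronic control ISI (ms).
#' @param trad_isi_ms traditional epoch length (ms).
#' @param n_cycles cycles in the steady-state comparison window.
#' @param noise_rms per-sweep noise RMS, µV.
#' @param noise_band noise passband, Hz.
#' @param artifact_rate per-sweep probability of an injected 50 µV spike.
#' @param threshold_uv artifact-rejection threshold, µV.
#' @param latency_shift_ms,amplitude_scale template overrides: a single
#'   value for a shared template across paradigms (the exact-superposition
#'   world) or a named list keyed by paradigm to plant rate/sequencing
#'   effects (e.g. `amplitude_scale = list(traditional = c(Na = 1.3),
#'   default = 1)`).
#' @param msad_method,msad_parameter regularization settings for the
#'   fold-system solve. The pipeline default is `parameter = 0` (plain
#'   least squares): the support-restricted system is full column rank, and
#'   data-driven shrinkage (`"auto"`) introduces a bias shared across
#'   subjects that inflates the group-level Hotelling type-I error.
#' @param msad_support_ms assumed transient support of the fold-system
#'   unknown, in ms. The multi-rate system only has full column rank up to
#'   about three quarters of the sweep length (beyond that the solution is
#'   non-unique no matter the regularization), so the default, 102.4 ms,
#'   keeps the solve identifiable while comfortably covering the transient
#'   response; the estimate is zero-padded to the template length.
#' @param clad_ridge ridge for the inverse filter (0 = exact division).
#' @param alpha significance level of all tests.
#' @param screen_outliers apply [outlier_policy()] before the Hotelling
#'   tests (needs at least 5 subjects).
#' @param seed master seed; the whole study is a deterministic function of
#'   the configuration.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_subjects = 19, n_sweeps = 1500, fs = 20000,
                         isis = clad_isis(), control_isi_ms = 25.6,
                         trad_isi_ms = 204.8, n_cycles = 4,
                         noise_rms = 1, noise_band = c(10, 1000),
                         artifact_rate = 0, threshold_uv = 40,
                         latency_shift_ms = 0, amplitude_scale = 1,
                         msad_method = "tikhonov", msad_parameter = 0,
                         msad_support_ms = 102.4,
                         clad_ridge = 0, alpha = 0.05,
                         screen_outliers = FALSE, seed = 1) {
  isi_to_samples(c(isis, control_isi_ms, trad_isi_ms), fs)  # validate grid
  structure(as.list(environment()), class = "study_config")
}

#' Seconds-scale study profile for tests and examples
#'
#' @param ... overrides forwarded to [study_config()].
#' @return a `study_config` with `fs = 2500`, 5 subjects, 200 sweeps.
#' @export
fast_profile <- function(...) {
  args <- list(...)
  base <- list(n_subjects = 5, n_sweeps = 200, fs = 2500)
  do.call(study_config, utils::modifyList(base, args))
}

#' Run the full synthetic superposition study
#'
#' simulate -> reject artifacts -> average -> deconvolve (inverse filter
#' for the jittered paradigm, regularized fold-system solve for the
#' multi-rate paradigm) -> synthesize steady-state responses from each
#' template -> compare against the "recorded" control response in time
#' (pointwise t-tests on difference waveforms, significant-fraction
#' metric) and frequency (six-element harmonic difference vectors,
#' one-sample Hotelling T-squared).
#'
#' @param config a `study_config`.
#' @param progress print per-stage messages.
#' @return object of class `study_report`; see Details.
#' @details The report contains: `subjects` (per-subject templates `taep`,
#'   `caep`, `maep`, records `rassr`, `tassr`, `cassr`, `massr`, and
#'   rejection counts), `grand` (grand-average templates and records),
#'   `time_domain` (per-paradigm `diff_trace` objects), `frequency_domain`
#'   (per-paradigm Hotelling results on the harmonic difference vectors,
#'   plus the per-subject vectors), `contributions` (per-paradigm
#'   contribution tables from the grand templates), and `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cf <- config
  say <- function(...) if (progress) message(sprintf(...))
  t_start <- Sys.time()

  n_templ <- round(cf$trad_isi_ms * cf$fs / 1000)
  periods <- isi_to_samples(cf$isis, cf$fs)
  clad_train <- to_impulse_train(make_clad_sequence(cf$isis), cf$fs)
  n_support <- isi_to_samples(cf$msad_support_ms, cf$fs)
  system <- with_svd(build_fold_system(periods, n_support))
  say("fold system %d x %d decomposed (%.1fs)", nrow(system$A),
      ncol(system$A), as.numeric(Sys.time() - t_start, "secs"))

  subjects <- vector("list", cf$n_subjects)
  paradigms <- c("traditional", "clad", "msad", "control")
  for (si in seq_len(cf$n_subjects)) {
    sub <- list(id = si, rejected = list())
    for (p in paradigms) {
      comp <- aep_components(per_paradigm(cf$latency_shift_ms, p),
                             per_paradigm(cf$amplitude_scale, p))
      tmpl <- make_template(template_spec(comp, cf$trad_isi_ms, cf$fs))
      train <- paradigm_train(p, cf$fs, cf$isis, cf$control_isi_ms,
                              cf$trad_isi_ms, cf$n_cycles, "auto", n_templ)
      pseed <- (cf$seed * 7919L + si * 131L + match(p, paradigms)) %%
        2147483647L
      nsw <- per_paradigm(cf$n_sweeps, p)
      if (p == "msad") {
        cycles <- vector("list", length(cf$isis))
        rej <- 0L
        for (ri in seq_along(cf$isis)) {
          set <- simulate_sweeps(tmpl, train[[ri]], nsw, cf$noise_rms,
                                 cf$noise_band, cf$artifact_rate,
                                 paradigm = "msad",
                                 seed = (pseed + ri * 17L) %% 2147483647L)
          kept <- reject_artifacts(set, cf$threshold_uv)
          rej <- rej + kept$report$n_rejected
          avg <- average_sweeps(kept$sweeps)$average
          cycles[[ri]] <- fold_cycles(avg, periods[ri])
        }
        sub$rejected[[p]] <- rej
        sub$multi_rate <- build_multi_rate_assr(cycles, cf$isis, cf$fs)
        sol <- msad_deconvolve(sub$multi_rate, system,
                               method = cf$msad_method,
                               parameter = cf$msad_parameter,
                               noise_level = NULL)
        est <- sol$estimate$waveform
        sub$maep <- transient_aep(c(est, numeric(n_templ - length(est))),
                                  cf$fs)
        sub$msad_solution <- sol[c("method", "parameter", "residual_norm",
                                   "solution_norm", "condition_number")]
      } else {
        set <- simulate_sweeps(tmpl, train, nsw, cf$noise_rms,
                               cf$noise_band, cf$artifact_rate,
                               paradigm = p, seed = pseed)
        kept <- reject_artifacts(set, cf$threshold_uv)
        sub$rejected[[p]] <- kept$report$n_rejected
        avg <- average_sweeps(kept$sweeps)
        sub$consistency[[p]] <- avg$consistency
        if (p == "traditional") {
          sub$taep <- transient_aep(avg$average, cf$fs)
        } else if (p == "clad") {
          sub$multi_isi <- steady_state_record(
            avg$average, cf$fs, segments = periods, isis_ms = cf$isis)
          sub$caep <- clad_deconvolve(sub$multi_isi, clad_train,
                                      ridge = cf$clad_ridge)
        } else {
          sub$rassr <- build_rassr(avg$average, cf$control_isi_ms, cf$fs,
                                   cf$n_cycles)
        }
      }
    }
    for (nm in c("taep", "caep", "maep")) {
      assr <- synthesize_assr(sub[[nm]], cf$control_isi_ms, cf$n_cycles)
      sub[[sub_assr_name(nm)]] <- assr
    }
    subjects[[si]] <- sub
    say("subject %d/%d done (%.1fs)", si, cf$n_subjects,
        as.numeric(Sys.time() - t_start, "secs"))
  }

  grand <- list()
  for (nm in c("taep", "caep", "maep")) {
    grand[[nm]] <- transient_aep(
      rowMeans(vapply(subjects, function(s) s[[nm]]$waveform,
                      numeric(n_templ))), cf$fs)
  }
  rassr_len <- length(subjects[[1]]$rassr$waveform)
  grand$rassr <- subjects[[1]]$rassr
  grand$rassr$waveform <- rowMeans(
    vapply(subjects, function(s) s$rassr$waveform, numeric(rassr_len)))

  time_domain <- list()
  freq_domain <- list(vectors = list(), tests = list())
  for (nm in c("taep", "caep", "maep")) {
    an <- sub_assr_name(nm)
    dm <- t(vapply(subjects, function(s)
      s[[an]]$waveform - s$rassr$waveform, numeric(rassr_len)))
    time_domain[[an]] <- if (cf$n_subjects >= 3)
      pointwise_ttest(dm, cf$alpha) else list(mean = colMeans(dm))
    hv <- t(vapply(subjects, function(s)
      harmonic_vector(harmonic_set(s[[an]])) -
        harmonic_vector(harmonic_set(s$rassr)), numeric(6)))
    freq_domain$vectors[[an]] <- hv
    # differences at numerical-dust level (noiseless identity) are
    # degenerate: covariance singular, test undefined
    if (cf$n_subjects > 6 && max(abs(hv)) > 1e-9) {
      use <- if (cf$screen_outliers && cf$n_subjects >= 5)
        outlier_policy(hv)$kept else seq_len(cf$n_subjects)
      freq_domain$tests[[an]] <-
        if (length(use) > 6) hotelling_one_sample(hv[use, , drop = FALSE],
                                                  cf$alpha) else NULL
      freq_domain$kept[[an]] <- use
    }
  }

  contributions <- lapply(grand[c("taep", "caep", "maep")], function(t)
    contribution_table(t, isi_ms = cf$control_isi_ms,
                       n_cycles = cf$n_cycles))

  structure(list(subjects = subjects, grand = grand,
                 time_domain = time_domain, frequency_domain = freq_domain,
                 contributions = contributions, config = cf),
            class = "study_report")
}

sub_assr_name <- function(nm) {
  c(taep = "tassr", caep = "cassr", maep = "massr")[[nm]]
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects @ %g Hz\n",
              x$config$n_subjects, x$config$fs))
  for (an in names(x$time_domain)) {
    td <- x$time_domain[[an]]
    ht <- x$frequency_domain$tests[[an]]
    cat(sprintf("  %s vs rassr: significant fraction %s%%",
                an, if (inherits(td, "diff_trace"))
                  sprintf("%.2f", td$fraction_pct) else "NA"))
    if (!is.null(ht)) cat(sprintf("; T2 = %.2f, F = %.2f, p = %.3g",
                                  ht$t2, ht$f, ht$p_value))
    cat("\n")
  }
  invisible(x)
}

#' Standard diagnostic figures for a study report
#'
#' Writes waveform overlays, difference traces with significance shading,
#' harmonic amplitude summaries and contribution bars as PNG files.
#'
#' @param report a `study_report` (an empty list produces no files and a
#'   warning).
#' @param dir output directory, created if missing.
#' @return character vector of the files written, invisibly.
#' @export
make_figures <- function(report, dir) {
  if (!inherits(report, "study_report") || length(report) == 0) {
    warning("empty or invalid report: no figures written")
    return(invisible(character(0)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cf <- report$config
  files <- character(0)
  fig <- function(name, fun) {
    f <- file.path(dir, paste0(name, ".png"))
    grDevices::png(f, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    files <<- c(files, f)
  }
  t_ms <- function(w, fs) (seq_along(w) - 1) / fs * 1000
  fig("templates", function() {
    g <- report$grand
    graphics::matplot(t_ms(g$taep$waveform, cf$fs),
            cbind(g$taep$waveform, g$caep$waveform, g$maep$waveform),
            type = "l", lty = 1, xlab = "time (ms)", ylab = "uV",
            main = "grand-average transient templates")
    graphics::legend("topright", c("tAEP", "cAEP", "mAEP"), col = 1:3, lty = 1)
  })
  for (an in c("tassr", "cassr", "massr")) {
    fig(paste0(an, "_vs_rassr"), function() {
      r <- report$grand$rassr$waveform
      s <- rowMeans(vapply(report$subjects, function(x) x[[an]]$waveform,
                           numeric(length(r))))
      tt <- t_ms(r, cf$fs)
      graphics::matplot(tt, cbind(r, s), type = "l", lty = 1,
              xlab = "time (ms)", ylab = "uV",
              main = paste(an, "(red) vs rASSR (black)"))
      td <- report$time_domain[[an]]
      if (inherits(td, "diff_trace") && any(td$mask)) {
        graphics::points(tt[td$mask], rep(min(r, s), sum(td$mask)),
                         pch = 15, col = "red", cex = 0.4)
      }
    })
  }
  fig("difference_traces", function() {
    r <- report$grand$rassr$waveform
    tds <- report$time_domain
    ys <- vapply(tds, function(td) td$mean, numeric(length(r)))
    graphics::matplot(t_ms(r, cf$fs), ys, type = "l", lty = 1,
            xlab = "time (ms)", ylab = "uV",
            main = "mean difference waveforms vs rASSR")
    graphics::abline(h = 0, col = "grey")
    graphics::legend("topright", colnames(ys), col = seq_len(ncol(ys)), lty = 1)
  })
  fig("harmonics", function() {
    tmpl_of <- c(tassr = "taep", cassr = "caep", massr = "maep")
    amp <- vapply(c("tassr", "cassr", "massr"), function(an) {
      h <- harmonic_set(synthesize_assr(report$grand[[tmpl_of[[an]]]],
                                        cf$control_isi_ms, cf$n_cycles))
      Mod(h$coef)
    }, numeric(3))
    amp <- cbind(amp, rassr = Mod(harmonic_set(report$grand$rassr)$coef))
    graphics::barplot(t(amp), beside = TRUE,
                      names.arg = paste0("h", 1:3),
                      legend.text = colnames(amp), ylab = "RMS uV",
                      main = "first three harmonics")
  })
  fig("contributions", function() {
    m <- vapply(report$contributions, function(tb) tb$normalized_pct,
                numeric(5))
    rownames(m) <- report$contributions[[1]]$component
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      ylab = "normalized contribution (%)",
                      main = "component contributions")
  })
  invisible(files)
}
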