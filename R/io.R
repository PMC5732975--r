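#' Read and write sweep sets and waveforms as delimited text
#'
#' Sweep sets are stored as TSV matrices (one row per sweep, one column per
#' sample, no header) with a JSON sidecar `<file>.json` holding `fs_hz`,
#' `paradigm` and dimensions. Waveforms are single-column TSV with the same
#' sidecar scheme.
#'
#' @param x a `sweep_set`.
#' @param path output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sweep_set <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  utils::write.table(format(x$data, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs_hz = x$fs, paradigm = x$paradigm,
                            n_sweeps = nrow(x$data), n_samples = ncol(x$data)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  structure(list(data = data, fs = meta$fs_hz, paradigm = meta$paradigm,
                 noiseless = NULL),
            class = "sweep_set")
}

#' @rdname write_sweep_set
#' @param waveform numeric vector (µV).
#' @param fs sampling rate, Hz.
#' @export
write_waveform <- function(waveform, fs, path) {
  utils::write.table(format(waveform, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs_hz = fs, n_samples = length(waveform)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep_set
#' @export
read_waveform <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- utils::read.table(path, sep = "\t", header = FALSE)[[1]]
  list(waveform = as.numeric(w), fs = meta$fs_hz)
}
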