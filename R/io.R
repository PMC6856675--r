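#' Export and re-import an analysis window as CSV
#'
#' The CSV has a `time_s` column followed by one column per dynamical
#' variable and observable, on the uniform sampling grid of the analysis
#' window.
#'
#' @param sim a `"cv_sim"` object.
#' @param path output file.
#' @return `write_waveforms()` returns `path` invisibly;
#'   `read_waveforms()` returns the waveform data frame (with the `time`
#'   column restored).
#' @export
write_waveforms <- function(sim, path) {
  wf <- if (inherits(sim, "cv_sim")) sim$waveforms else sim
  out <- wf
  names(out)[names(out) == "time"] <- "time_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("expected a time_s column in ", path)
  names(df)[names(df) == "time_s"] <- "time"
  df
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the full parameter set,
#' protocol settings, steadiness outcome and the package version, as JSON.
#'
#' @param sim a `"cv_sim"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sim, path) {
  stopifnot(inherits(sim, "cv_sim"))
  manifest <- list(
    package = "cvloop",
    version = as.character(utils::packageVersion("cvloop")),
    parameters = as.list(unclass(sim$params)),
    protocol = list(duration_s = sim$duration, window_s = sim$window,
                    sampling_dt_s = sim$dt, period_s = sim$period),
    steady = sim$steady)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
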