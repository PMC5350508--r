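#' Load a pipeline configuration
#'
#' A single YAML file keyed by pipeline stage drives end-to-end runs; every
#' function argument of the exported stages can be given a config twin.  The
#' config is echoed verbatim through [regstate_log()] so a run's provenance
#' is recorded at start.
#'
#' @param path path to a YAML config file.
#' @param log echo the config at load time?
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path, log = TRUE) {
    cfg <- yaml::read_yaml(path)
    if (isTRUE(log)) {
        regstate_log("INFO", "config loaded from ", path)
        for (l in strsplit(yaml::as.yaml(cfg), "\n")[[1L]])
            regstate_log("INFO", "config| ", l)
    }
    cfg
}

#' Structured log line
#'
#' Emits `[timestamp] LEVEL message` via [message()]; suppressed entirely
#' when `options(regstate.quiet = TRUE)`.
#'
#' @param level log level string (e.g. "INFO").
#' @param ... message parts, concatenated.
#' @return Invisibly, the formatted line.
#' @export
regstate_log <- function(level, ...) {
    line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, paste0(..., collapse = ""))
    if (!isTRUE(getOption("regstate.quiet", FALSE))) message(line)
    invisible(line)
}
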