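#' Write a JSON run manifest
#'
#' Every command-line run records its provenance: the command, a full echo
#' of the configuration, the seeds used, the package version, MD5 digests
#' of the input files and a timestamp. Digests are stable, so two runs on
#' identical inputs with identical seeds produce manifests differing only
#' in their timestamps.
#'
#' @param path output JSON path.
#' @param command command or subcommand name.
#' @param config list echoing the run configuration.
#' @param seed seed(s) used, or `NULL` for deterministic runs.
#' @param inputs character vector of input/output file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NULL,
                               inputs = character(0)) {
  digests <- if (length(inputs)) {
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package = "dynlogic",
    version = as.character(utils::packageVersion("dynlogic")),
    input_digests = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
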