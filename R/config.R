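# Layered configuration (defaults < YAML < explicit flags) and run
# manifests, shared by the command-line interface and scripted pipelines.

#' Resolve a layered training configuration
#'
#' Merges, in increasing precedence: the package defaults
#' ([dazzle_config()]), an optional YAML file, and a named list of explicit
#' overrides (e.g. parsed command-line flags). Unknown keys in either layer
#' raise an error listing the valid keys.
#'
#' @param yaml_path Optional path to a YAML file of config keys.
#' @param flags Optional named list of overrides (highest precedence).
#' @return A validated [dazzle_config()].
#' @export
resolve_config <- function(yaml_path = NULL, flags = list()) {
  cfg <- unclass(dazzle_config())
  valid <- names(cfg)
  apply_layer <- function(cfg, layer, origin) {
    if (length(layer) == 0) return(cfg)
    bad <- setdiff(names(layer), valid)
    if (length(bad) > 0) {
      stop("unknown config key(s) in ", origin, ": ",
           paste(bad, collapse = ", "),
           "\nvalid keys: ", paste(valid, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(cfg, layer)
  }
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) {
      stop("config file not found: ", yaml_path, call. = FALSE)
    }
    cfg <- apply_layer(cfg, yaml::read_yaml(yaml_path), yaml_path)
  }
  cfg <- apply_layer(cfg, flags, "flags")
  cfg <- structure(cfg, class = c("dazzle_config", "list"))
  validate_config(cfg)
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-identically in
#' deterministic mode: the resolved configuration, seeds, package version,
#' MD5 checksums of the inputs, the list of output files (with checksums),
#' and per-stage wall times.
#'
#' @param path Output JSON path.
#' @param config The resolved [dazzle_config()].
#' @param inputs Character vector of input file paths.
#' @param outputs Character vector of output file paths.
#' @param timings Named list/vector of per-stage wall times (seconds).
#' @param extra Optional named list merged into the manifest.
#' @return The manifest (a list), invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(),
                           outputs = character(), timings = list(),
                           extra = list()) {
  checksum <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  manifest <- c(list(
    package = "dazzle",
    version = as.character(utils::packageVersion("dazzle")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    seed = config$seed,
    inputs = checksum(inputs),
    outputs = checksum(outputs),
    timings = as.list(timings)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a run manifest
#'
#' @param path Manifest JSON path.
#' @return The manifest as a list; its `config` element can be passed to
#'   [resolve_config()]'s `flags` argument to re-run with identical
#'   settings.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
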