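## Configuration resolution and run manifests for the command-line entry
## point (inst/cli/lmp.R) and for scripted use: command-line flags
## override YAML values, which override package defaults; every run can be
## described by a manifest whose deterministic commands are
## hash-reproducible.

#' Resolve a configuration from defaults, YAML and explicit overrides
#'
#' Precedence: \code{overrides} (e.g. parsed CLI flags) > \code{yaml} file
#' values > \code{defaults}.  Unknown keys are rejected by name so typos
#' fail loudly.
#'
#' @param defaults named list of documented defaults.
#' @param yaml optional path to a YAML file.
#' @param overrides named list of explicit overrides (NULL entries are
#'   ignored).
#' @return named list: the resolved configuration.
#' @export
resolveConfig <- function(defaults, yaml = NULL, overrides = list()) {
  cfg <- defaults
  if (!is.null(yaml)) {
    v <- tryCatch(yaml::read_yaml(yaml), error = function(e)
      stop(sprintf("malformed yaml '%s': %s", yaml, conditionMessage(e)),
           call. = FALSE))
    bad <- setdiff(names(v), names(defaults))
    if (length(bad))
      stop(sprintf("unknown config key(s) in %s: %s", yaml,
                   paste(bad, collapse = ", ")), call. = FALSE)
    cfg[names(v)] <- v
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop(sprintf("unknown option(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Write a run manifest
#'
#' Records the command, the fully resolved configuration, seeds, package
#' version, input/output paths and content hashes of emitted artifacts.
#' Re-running a deterministic command (transform/cost/synth/describe) with
#' an identical manifest reproduces identical hashes.
#'
#' @param command subcommand name.
#' @param config resolved configuration list.
#' @param outputs character vector of produced files.
#' @param path manifest destination (JSON).
#' @param seed the seed used.
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(command, config, outputs, path, seed = NULL) {
  hashes <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  m <- list(command = command, config = config, seed = seed,
            package_version = as.character(utils::packageVersion("lmppm")),
            outputs = as.list(outputs), md5 = hashes)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(m)
}

#' Serialize an OMNet-family configuration as YAML
#'
#' @param cfg an \code{\link{omnetConfig}}.
#' @param path YAML destination.
#' @return the path, invisibly.
#' @export
writeOmnetConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "omnetConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeOmnetConfig
#' @export
readOmnetConfig <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(omnetConfig, v)
}
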