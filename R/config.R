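# YAML configuration: registry / valuation / dynamics / render sections
# merged over package defaults, mainly for the command-line entry point.

#' Default configuration
#'
#' @return Nested list with sections `registry` (synonym map), `valuation`
#'   (log base, epsilon, relative values, color anchors, size/width clamps),
#'   `dynamics` (alpha decay and floor), and `render` (canvas, labels,
#'   legend, format).
#' @export
default_config <- function() {
  p <- valuation_params()
  list(
    registry = list(synonyms = list()),
    valuation = list(
      log_base = p$log_base, epsilon = p$epsilon, rv = as.list(p$rv),
      anchors = lapply(p$anchors, as.integer),
      node_area = as.list(p$node_area), edge_width = as.list(p$edge_width)
    ),
    dynamics = list(decay = p$decay, alpha_floor = p$alpha_floor),
    render = list(width = 900, height = 700, margin = 70, labels = TRUE,
                  legend = TRUE, format = "svg")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the package defaults section-wise;
#' everything else keeps its default.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) rlang::abort(sprintf("no such config file: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Build valuation parameters from a configuration list
#'
#' @param config A list from [read_config()].
#' @return An [valuation_params()] list.
#' @export
config_params <- function(config) {
  v <- config$valuation
  d <- config$dynamics
  valuation_params(
    log_base = v$log_base, epsilon = v$epsilon,
    rv = unlist(v$rv), anchors = lapply(v$anchors, as.numeric),
    node_area = unlist(v$node_area), edge_width = unlist(v$edge_width),
    decay = d$decay, alpha_floor = d$alpha_floor
  )
}

config_synonyms <- function(config) {
  syn <- config$registry$synonyms
  if (!length(syn)) return(character())
  stats::setNames(as.character(unlist(syn)), names(syn))
}
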