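#' Assemble the tool configuration
#'
#' Bundles the three parameter sets the pipeline uses. Unknown keys are
#' rejected by name, so a typo in a config file fails loudly instead of
#' silently using a default.
#'
#' @param trim A [trim_params()].
#' @param purity A [purity_params()].
#' @param quality_model A [quality_model_params()].
#' @return An object of class `tool_config`.
#' @export
tool_config <- function(trim = trim_params(), purity = purity_params(),
                        quality_model = quality_model_params()) {
  stopifnot(inherits(trim, "trim_params"),
            inherits(purity, "purity_params"),
            inherits(quality_model, "quality_model_params"))
  structure(list(trim = trim, purity = purity,
                 quality_model = quality_model),
            class = "tool_config")
}

#' Read a tool configuration from YAML
#'
#' The file may contain any subset of the sections `trim`, `purity` and
#' `quality_model`; omitted sections and keys take their defaults. Unknown
#' sections or keys raise an error naming the offending key.
#'
#' @param path Path to a YAML file.
#' @return A [tool_config()].
#' @export
read_tool_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- list(trim = trim_params, purity = purity_params,
                quality_model = quality_model_params)
  extra <- setdiff(names(raw), names(known))
  if (length(extra)) {
    abort(paste0("unknown config section: ", extra[[1L]]))
  }
  built <- lapply(names(known), function(sec) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(known[[sec]])))
    if (length(bad)) {
      abort(paste0("unknown config key: ", sec, ".", bad[[1L]]))
    }
    do.call(known[[sec]], args)
  })
  names(built) <- names(known)
  tool_config(built$trim, built$purity, built$quality_model)
}

#' Write a tool configuration as YAML
#'
#' @param config A [tool_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tool_config <- function(config, path) {
  stopifnot(inherits(config, "tool_config"))
  yaml::write_yaml(lapply(config, unclass), path)
  invisible(path)
}

#' Read simulation configurations from YAML
#'
#' The file holds a list of simulation entries under `simulations:`, each
#' accepting the arguments of [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A list of [sim_config()]s.
#' @export
read_sim_configs <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$simulations)) raw$simulations else raw
  lapply(entries, function(e) {
    bad <- setdiff(names(e), names(formals(sim_config)))
    if (length(bad)) abort(paste0("unknown config key: ", bad[[1L]]))
    do.call(sim_config, e)
  })
}
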