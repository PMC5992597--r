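# Versioned model configuration files.  The frozen reference parameter
# set ships with the package; runs driven by a config file are exactly
# reproducible from that file alone.

#' Write a model configuration to YAML
#'
#' @param params a [model_parameters()].
#' @param geometry a [cell_file_geometry()].
#' @param path output file.
#' @param version config version string recorded in the file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, geometry, path, version = "1") {
  obj <- list(version = version,
              parameters = lapply(unclass(params), identity),
              geometry = list(n_cells = geometry$n_cells,
                              prif = as.list(geometry$prif)))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a model configuration
#'
#' With no `path`, loads the package's frozen reference configuration
#' (version 1), which is identical to the [model_parameters()] and
#' [cell_file_geometry()] defaults.
#'
#' @param path a YAML file written by [write_model_config()], or `NULL`
#'   for the shipped reference set.
#' @return list with `params`, `geometry` and `version`.
#' @export
#' @examples
#' cfg <- read_model_config()
#' cfg$version
read_model_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "boundary-model-params-v1.yaml",
                        package = "stmgrn")
  }
  obj <- yaml::read_yaml(path)
  params <- do.call(model_parameters, obj$parameters)
  geometry <- cell_file_geometry(obj$geometry$n_cells,
                                 prif = unlist(obj$geometry$prif))
  list(params = params, geometry = geometry, version = obj$version)
}
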