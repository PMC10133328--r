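# YAML round trip for the scenario configuration.

#' Write / read a scenario configuration as YAML
#'
#' The YAML file is a faithful, human-editable rendering of
#' [default_scenario_config()]; `read_scenario_config()` restores the
#' named numeric vectors that YAML flattens to lists.
#'
#' @param config A `scenario_config` list.
#' @param path File path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(config, path) {
  # yaml serialises named atomic vectors as bare sequences; promote
  # them to named lists so the keys survive the round trip
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(prep(unclass(config)), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  raw$years <- as.integer(unlist(raw$years))
  raw$ndvi_range <- num(raw$ndvi_range)
  raw$flow_exceeds_capacity_units <-
    as.integer(unlist(raw$flow_exceeds_capacity_units))
  for (g in names(raw$groups)) {
    gr <- raw$groups[[g]]
    gr$class_props <- num(gr$class_props)
    gr$roughness <- num(gr$roughness)
    gr$habitat_fractions <- num(gr$habitat_fractions)
    gr$latent <- num(gr$latent)
    gr$record_means <- num(gr$record_means)
    gr$n_patches <- lapply(gr$n_patches, function(x) as.numeric(unlist(x)))
    raw$groups[[g]] <- gr
  }
  class(raw) <- c("scenario_config", "list")
  raw
}
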