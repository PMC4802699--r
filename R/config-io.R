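#' Write a model configuration to JSON
#'
#' Serializes the configuration field-for-field so that
#' `read_config(write_config(cfg, path))` round-trips. The bundled default
#' file (`system.file("extdata", "default_config.json", package = "tdmcost")`)
#' reproduces the published model inputs.
#'
#' @param config A `tdm_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$regimens <- lapply(x$regimens, function(rg) {
    rg$lor_range <- as.numeric(rg$lor_range)
    rg$ae_range <- as.numeric(rg$ae_range)
    if (!is.null(rg$response_range)) rg$response_range <- as.numeric(rg$response_range)
    rg
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read and validate a model configuration from JSON
#'
#' @param path Path to a JSON file written by [write_config()] (or edited by
#'   hand with the same shape).
#' @return A validated `tdm_config`.
#' @seealso [build_default_config()]
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$regimens <- lapply(x$regimens, function(rg) {
    rg$cycle_weeks <- as.integer(rg$cycle_weeks)
    rg$lor_range <- prob_range(rg$lor_range[1], rg$lor_range[2])
    rg$ae_range <- prob_range(rg$ae_range[1], rg$ae_range[2])
    if (!is.null(rg$response_range))
      rg$response_range <- prob_range(rg$response_range[1], rg$response_range[2])
    rg
  })
  for (side in c("ifx_test", "ada_test")) {
    x[[side]] <- lapply(x[[side]], function(o) {
      o$routed_regimen <- if (is.null(o$routed_regimen)) NA_character_ else o$routed_regimen
      o$efficacy_horizon_weeks <- as.integer(unlist(o$efficacy_horizon_weeks))
      o$efficacy_retention <- as.numeric(unlist(o$efficacy_retention))
      o
    })
  }
  x$horizons_weeks <- as.integer(x$horizons_weeks)
  x$cohort_sizes <- as.integer(x$cohort_sizes)
  cfg <- structure(x, class = "tdm_config")
  v <- validate_config(cfg)
  if (length(v) > 0)
    stop("invalid configuration in '", path, "': ", paste(v, collapse = "; "))
  cfg
}
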