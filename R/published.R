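# Access to the bundled published coefficient sets.

#' Published pooled coefficient sets
#'
#' Loads one of the pooled coefficient sets shipped with the package --
#' device-stratified compositional Cox coefficients from a federated
#' mortality analysis of six accelerometer cohorts -- as a
#' `pooled_model` usable in all effect-estimation functions.  Only
#' coefficient point estimates and marginal 95% bounds are published, so
#' the covariance is diagonal; hazard-ratio point estimates are exact
#' while interval widths ignore the (unpublished) between-coordinate
#' correlation.
#'
#' @param stratum `"hip"` (waking-day balances z2, z3) or `"wrist"`
#'   (24-h balances z1, z2, z3).
#' @return A `pooled_model`.
#' @examples
#' hip <- published_pooled_model("hip")
#' unit_hazard_ratios(hip)
#' @export
published_pooled_model <- function(stratum = c("hip", "wrist")) {
  stratum <- match.arg(stratum)
  path <- system.file("extdata",
                      paste0("pooled_", stratum, "_published.json"),
                      package = "codasurv", mustWork = TRUE)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pooled_model_from_coefficients(
    gamma = unlist(o$gamma),
    ci_lower = unlist(o$ci_lower),
    ci_upper = unlist(o$ci_upper),
    stratum = o$stratum)
}
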