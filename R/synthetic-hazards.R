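#' Synthetic age-specific hazard curves
#'
#' Builds a [hazard_model()] from a small parametric template emulating the
#' qualitative shape of registry hazard curves for a late-onset disease:
#' a disease hazard that is negligible in childhood and rises with age
#' (logistic ramp), and Gompertz-shaped death hazards with the affected
#' population at a constant excess multiple of the unaffected one. Rates
#' are evaluated at yearly bin midpoints, so the model is deterministic
#' given the specification.
#'
#' The default disease hazard integrates to a lifetime risk of roughly 10%,
#' at the common-cancer end of registry rates and deliberately higher than
#' rates for rarer cancers, so that ascertained families are produced
#' quickly at simulation scale; the shape, not the level, drives the
#' package's qualitative behaviour.
#'
#' @param onset_base floor of the disease hazard (events/person-year).
#' @param onset_peak asymptotic increment of the disease hazard at old age.
#' @param onset_rise_age age (years) at which the logistic ramp is halfway.
#' @param onset_slope width (years) of the logistic ramp.
#' @param gompertz_a,gompertz_b Gompertz parameters of the unaffected death
#'   hazard `a * exp(b * age)`.
#' @param excess_mult multiplier giving the affected death hazard as a
#'   multiple of the unaffected one (`>= 1`).
#' @param max_age final partition boundary in years.
#' @return A `hazard_model` with yearly bins `0..max_age`.
#' @examples
#' h <- synthetic_hazards()
#' plot(0:99 + 0.5, h$onset_pop, type = "l", xlab = "age", ylab = "hazard")
#' @export
synthetic_hazards <- function(onset_base = 5e-5,
                              onset_peak = 0.002,
                              onset_rise_age = 50,
                              onset_slope = 10,
                              gompertz_a = 4e-5,
                              gompertz_b = 0.085,
                              excess_mult = 2,
                              max_age = 100) {
  if (excess_mult < 1) stop("excess_mult must be >= 1")
  mid <- seq(0.5, max_age - 0.5, by = 1)
  onset <- onset_base + onset_peak / (1 + exp(-(mid - onset_rise_age) /
                                                onset_slope))
  death_u <- gompertz_a * exp(gompertz_b * mid)
  hazard_model(data.frame(onset_pop = onset,
                          death_unaffected = death_u,
                          death_affected = excess_mult * death_u),
               partition = 0:max_age)
}
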