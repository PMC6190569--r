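#' Baseline (sporadic) onset hazard from the population hazard
#'
#' The population onset hazard is a mixture over carriers and non-carriers of
#' a causal variant: non-carriers experience the baseline hazard
#' \eqn{\lambda_o(t)} and carriers experience \eqn{\kappa \lambda_o(t)}, so
#' \deqn{\lambda_{onset}(t) = (1 - p_c)\,\lambda_o(t) +
#'       \kappa\, p_c\, \lambda_o(t).}
#' Given the population hazard, the baseline is recovered as
#' \eqn{\lambda_o(t) = \lambda_{onset}(t) / (1 + p_c(\kappa - 1))}.
#'
#' @param pop_hazard numeric vector of per-bin population onset rates.
#' @param kappa genetic relative-risk of disease for carriers, `kappa >= 1`.
#' @param carrier_prob carrier probability of all causal variants as a group,
#'   in `[0, 1]`.
#' @return Numeric vector of per-bin baseline onset rates; a carrier's hazard
#'   is `kappa` times the result.
#' @examples
#' baseline_onset(0.001, kappa = 11, carrier_prob = 0.1)  # 0.0005
#' @export
baseline_onset <- function(pop_hazard, kappa, carrier_prob) {
  if (kappa < 1) stop("kappa must be >= 1")
  if (carrier_prob < 0 || carrier_prob > 1) {
    stop("carrier_prob must lie in [0, 1]")
  }
  pop_hazard / (1 + carrier_prob * (kappa - 1))
}

#' Disease model: relative risk, carrier probability and baseline hazard
#'
#' Couples a [hazard_model()] with the genetic parameters of the disease: the
#' genetic relative-risk `kappa` and the carrier probability `carrier_prob`.
#' The per-bin baseline onset hazard is derived once, by
#' [baseline_onset()], and reused by the waiting-time samplers.
#'
#' @param hazards a `hazard_model`.
#' @inheritParams baseline_onset
#' @return An object of class `disease_model`: a list with elements
#'   `hazards`, `kappa`, `carrier_prob`, `onset_baseline`.
#' @export
disease_model <- function(hazards, kappa, carrier_prob) {
  stopifnot(inherits(hazards, "hazard_model"))
  structure(
    list(hazards = hazards,
         kappa = kappa,
         carrier_prob = carrier_prob,
         onset_baseline = baseline_onset(hazards$onset_pop, kappa,
                                         carrier_prob)),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat("<disease_model> kappa = ", x$kappa,
      ", carrier_prob = ", x$carrier_prob, "\n", sep = "")
  print(x$hazards)
  invisible(x)
}
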