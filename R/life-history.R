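#' Reproduction model parameters
#'
#' Offspring number follows a negative-binomial model (trials ~ 2, success
#' probability ~ 4/7), realised as a Poisson-Gamma mixture: at birth each
#' individual draws a lifetime birth rate `gamma` from a Gamma distribution
#' with shape 2 and scale 4/3, spread over a personal reproductive span
#' `[a1, a2)`. After disease onset the birth rate is rescaled by `onset_scale`
#' (`f`, in `[0, 1]`; the default 1 leaves it unchanged).
#'
#' @param gamma_shape,gamma_scale parameters of the lifetime birth-rate
#'   Gamma distribution.
#' @param onset_scale post-onset birth-rate rescaling factor `f` in `[0, 1]`.
#' @param a1_range range (years) from which the reproductive-span start `a1`
#'   is drawn uniformly.
#' @param span_range range (years) from which the span length `a2 - a1` is
#'   drawn uniformly.
#' @return An object of class `reproduction_model`.
#' @export
reproduction_model <- function(gamma_shape = 2, gamma_scale = 4 / 3,
                               onset_scale = 1,
                               a1_range = c(16, 27),
                               span_range = c(10, 18)) {
  if (onset_scale < 0 || onset_scale > 1) {
    stop("onset_scale (f) must lie in [0, 1]")
  }
  structure(
    list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         onset_scale = onset_scale,
         a1_range = a1_range, span_range = span_range),
    class = "reproduction_model"
  )
}

#' Draw an individual's lifetime reproductive traits
#'
#' Assigned once, at birth: the lifetime birth rate `gamma ~ Gamma(2, 4/3)`,
#' the reproductive-span start `a1 ~ U(16, 27)` and the span end
#' `a2 = a1 + U(10, 18)`.
#'
#' @param repro a [reproduction_model()].
#' @return A list with elements `gamma`, `a1`, `a2`.
#' @export
birth_traits <- function(repro = reproduction_model()) {
  a1 <- stats::runif(1, repro$a1_range[1], repro$a1_range[2])
  list(gamma = stats::rgamma(1, shape = repro$gamma_shape,
                             scale = repro$gamma_scale),
       a1 = a1,
       a2 = a1 + stats::runif(1, repro$span_range[1], repro$span_range[2]))
}

#' Waiting time to disease onset
#'
#' Samples the waiting time from current age `age` under the
#' non-homogeneous Poisson onset process with intensity
#' \eqn{\lambda_{onset}(t|x)}: the baseline hazard for a non-carrier, `kappa`
#' times the baseline for a carrier. Sampling inverts the cumulative hazard
#' at an Exp(1) target, so the draw is exact for piecewise-constant rates.
#'
#' @param age current age in years.
#' @param carrier logical or 0/1 rare-variant carrier status.
#' @param disease a [disease_model()].
#' @return Waiting time in years; `Inf` when no onset occurs before the
#'   maximum modelled age.
#' @export
draw_onset_wait <- function(age, carrier, disease) {
  stopifnot(inherits(disease, "disease_model"))
  mult <- if (isTRUE(carrier == 1 || isTRUE(carrier))) disease$kappa else 1
  pc_invert(disease$hazards$partition,
            mult * disease$onset_baseline,
            age, stats::rexp(1))
}

#' Waiting time to death
#'
#' Uses the unaffected death hazard while `affected` is `FALSE` and the
#' affected death hazard afterwards (no remission is modelled). Always
#' finite: an individual who exhausts the hazard mass before the final
#' partition boundary dies at the maximum modelled age.
#'
#' @param age current age in years.
#' @param affected logical or 0/1 disease status.
#' @param hazards a [hazard_model()].
#' @return Waiting time in years (finite).
#' @export
draw_death_wait <- function(age, affected, hazards) {
  stopifnot(inherits(hazards, "hazard_model"))
  col <- if (isTRUE(affected == 1 || isTRUE(affected)))
    hazards$death_affected else hazards$death_unaffected
  w <- pc_invert(hazards$partition, col, age, stats::rexp(1))
  if (is.infinite(w)) w <- max_age(hazards) - age
  w
}

#' Waiting time to the next reproduction event
#'
#' Draws the unconditional wait `w ~ Exp(rate)` with
#' `rate = gamma * (f if affected else 1) / (a2 - a1)` and conditions on the
#' current age: before the reproductive span the event lands at `a1 + w`
#' (provided that is still inside the span); within the span the residual
#' wait `w` applies (provided `age + w < a2`); otherwise no further
#' reproduction is possible and the wait is `Inf`.
#'
#' @param age current age in years.
#' @param affected logical or 0/1 disease status.
#' @param traits list as returned by [birth_traits()].
#' @param repro a [reproduction_model()].
#' @return Waiting time in years, possibly `Inf`.
#' @export
draw_repro_wait <- function(age, affected, traits,
                            repro = reproduction_model()) {
  a1 <- traits$a1
  a2 <- traits$a2
  f <- if (isTRUE(affected == 1 || isTRUE(affected))) repro$onset_scale else 1
  rate <- traits$gamma * f / (a2 - a1)
  if (rate <= 0) return(Inf)
  if (age >= a2) return(Inf)
  w <- stats::rexp(1, rate)
  if (age < a1) {
    if (a1 + w < a2) a1 + w - age else Inf
  } else {
    if (age + w < a2) w else Inf
  }
}

#' Simulate one individual's life events
#'
#' From `start_age` (birth by default) the three competing events -- disease
#' onset, death, reproduction -- are drawn repeatedly; the event with the
#' shortest waiting time occurs, the age advances, and the process repeats
#' until death or until the next event's calendar year would exceed
#' `stop_year`, in which case the individual is censored at the study stop
#' year. Onset flips the disease status, switching the death hazard to the
#' affected column and rescaling the birth rate by `f`; onset can occur at
#' most once.
#'
#' @param birth_year calendar year of birth.
#' @param carrier logical or 0/1 rare-variant carrier status.
#' @param disease a [disease_model()].
#' @param repro a [reproduction_model()].
#' @param stop_year last calendar year of follow-up.
#' @param traits reproductive traits from [birth_traits()]; drawn afresh if
#'   `NULL`.
#' @param start_age age at which simulation starts (default 0).
#' @param start_affected disease status at `start_age`.
#' @return A data frame of events, one row each, with columns `kind` (one of
#'   `"onset"`, `"reproduction"`, `"death"`, `"censored"`), `age` (years) and
#'   `year` (integer calendar year, `floor(birth_year + age)`). Events are
#'   nondecreasing in age; nothing follows death or censoring.
#' @export
simulate_life <- function(birth_year, carrier, disease,
                          repro = reproduction_model(),
                          stop_year, traits = NULL,
                          start_age = 0, start_affected = FALSE) {
  stopifnot(inherits(disease, "disease_model"))
  if (is.null(traits)) traits <- birth_traits(repro)
  age <- start_age
  affected <- isTRUE(start_affected == 1 || isTRUE(start_affected))
  kinds <- character()
  ages <- numeric()
  repeat {
    w_death <- draw_death_wait(age, affected, disease$hazards)
    w_onset <- if (affected) Inf else draw_onset_wait(age, carrier, disease)
    w_repro <- draw_repro_wait(age, affected, traits, repro)
    # tie order (probability zero for continuous draws): death, onset, repro
    waits <- c(death = w_death, onset = w_onset, reproduction = w_repro)
    k <- which.min(waits)
    new_age <- age + waits[[k]]
    if (floor(birth_year + new_age) > stop_year) {
      kinds <- c(kinds, "censored")
      ages <- c(ages, stop_year - birth_year)
      break
    }
    kinds <- c(kinds, names(waits)[k])
    ages <- c(ages, new_age)
    if (names(waits)[k] == "death") break
    age <- new_age
    if (names(waits)[k] == "onset") affected <- TRUE
  }
  years <- floor(birth_year + ages)
  years[kinds == "censored"] <- stop_year
  data.frame(kind = kinds, age = ages, year = as.integer(years),
             stringsAsFactors = FALSE)
}
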