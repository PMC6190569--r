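#' Study configuration
#'
#' Collects the family-study settings used to simulate and ascertain
#' pedigrees. Defaults mirror a registry-style study of a late-onset disease:
#' families ascertained 2000--2015 through a proband who is at least the
#' second affected relative, followed to 2017, with the variant introduced by
#' the eldest founder born uniformly between 1900 and 1980.
#'
#' @param kappa genetic relative-risk of disease for carriers (`>= 1`).
#' @param carrier_prob carrier probability `p_c` of all causal variants as a
#'   group.
#' @param num_affected minimum number of disease-affected relatives required
#'   for ascertainment (`>= 1`).
#' @param ascertain_span length-2 vector `(start, stop)` of calendar years
#'   during which the family can be ascertained through the proband's onset.
#' @param stop_year last calendar year of follow-up
#'   (`>= ascertain_span[2]`).
#' @param recall_probs `NULL` for the default rule (recall probability equals
#'   four times the kinship coefficient with the proband), or a numeric
#'   vector `(p_1, ..., p_q)`: `p_i` is the recall probability for relatives
#'   of degree `i`, with `p_q` applying to degree `q` or greater.
#' @param variant_mode `"eldest_founder"` (the starting founder always
#'   carries the variant) or `"bernoulli"` (the founder carries it with
#'   probability `carrier_prob`, so fully sporadic families can be
#'   ascertained).
#' @param founder_birth_range length-2 vector of calendar years; the starting
#'   founder's birth year is uniform over this range.
#' @param onset_scale post-onset birth-rate rescaling factor `f` in `[0, 1]`.
#' @param max_attempts ceiling on the discard-and-retry loop per family.
#' @param seed optional integer seed recorded in the configuration (used by
#'   the command-line interface; [simulate_study()] also accepts a seed
#'   directly).
#' @return An object of class `study_config`.
#' @export
study_config <- function(kappa = 1,
                         carrier_prob = 0.002,
                         num_affected = 2,
                         ascertain_span = c(2000, 2015),
                         stop_year = 2017,
                         recall_probs = NULL,
                         variant_mode = c("eldest_founder", "bernoulli"),
                         founder_birth_range = c(1900, 1980),
                         onset_scale = 1,
                         max_attempts = 10000,
                         seed = NULL) {
  variant_mode <- match.arg(variant_mode)
  if (kappa < 1) stop("kappa must be >= 1")
  if (carrier_prob < 0 || carrier_prob > 1) {
    stop("carrier_prob must lie in [0, 1]")
  }
  if (num_affected < 1) stop("num_affected must be >= 1")
  if (length(ascertain_span) != 2L || ascertain_span[1] > ascertain_span[2]) {
    stop("ascertain_span must be (start, stop) with start <= stop")
  }
  if (stop_year < ascertain_span[2]) {
    stop("stop_year must be >= the end of the ascertainment span")
  }
  if (!is.null(recall_probs)) {
    if (any(recall_probs < 0 | recall_probs > 1)) {
      stop("recall probabilities must lie in [0, 1]")
    }
  }
  if (founder_birth_range[1] > founder_birth_range[2]) {
    stop("founder_birth_range must be (earliest, latest)")
  }
  structure(
    list(kappa = kappa, carrier_prob = carrier_prob,
         num_affected = num_affected,
         ascertain_span = as.numeric(ascertain_span),
         stop_year = stop_year,
         recall_probs = recall_probs,
         variant_mode = variant_mode,
         founder_birth_range = as.numeric(founder_birth_range),
         onset_scale = onset_scale,
         max_attempts = max_attempts,
         seed = seed),
    class = "study_config"
  )
}

#' Variant introduction at the starting founder
#'
#' A causal variant is introduced by at most one founder. Under
#' `"eldest_founder"` the starting founder always carries it; under
#' `"bernoulli"` the founder carries it with probability `carrier_prob`,
#' allowing fully sporadic families.
#'
#' @param mode `"eldest_founder"` or `"bernoulli"`.
#' @param carrier_prob carrier probability used by the Bernoulli mode.
#' @return 0 or 1: the starting founder's carrier status.
#' @export
introduce_variant <- function(mode = c("eldest_founder", "bernoulli"),
                              carrier_prob = 0.002) {
  mode <- match.arg(mode)
  if (mode == "eldest_founder") 1L
  else stats::rbinom(1, 1, carrier_prob)
}

#' Mendelian transmission of the causal variant
#'
#' With at most one carrier parent (the single-variant model excludes
#' homozygous carriers), each offspring inherits the variant independently
#' with probability 1/2 if a parent carries it, and never otherwise.
#'
#' @param parent_carrier 0/1 carrier status of the (at most one) carrier
#'   parent.
#' @param n number of offspring statuses to draw.
#' @return Integer vector of 0/1 carrier statuses.
#' @export
transmit_variant <- function(parent_carrier, n = 1) {
  if (isTRUE(parent_carrier == 1)) stats::rbinom(n, 1, 0.5)
  else integer(n)
}

#' Simulate a full pedigree from a starting founder
#'
#' Grows a pedigree recursively: the starting founder's birth year is uniform
#' over the configured range and their carrier status is set by
#' [introduce_variant()]; life events are simulated by [simulate_life()];
#' each reproduction event adds an offspring (sex a fair coin, carrier status
#' by [transmit_variant()]) whose life is then simulated in turn, until all
#' descendants are processed or events run past the study stop year. A
#' married-in co-parent (one per individual, created at first reproduction)
#' is recorded as a non-carrier with no simulated life history.
#'
#' @param config a [study_config()].
#' @param hazards a [hazard_model()].
#' @param famid family identifier for the output rows.
#' @return An `rv_ped` data frame (see [as_rv_ped()]) with `proband` all
#'   `FALSE`.
#' @export
simulate_pedigree <- function(config, hazards, famid = 1L) {
  stopifnot(inherits(config, "study_config"), inherits(hazards, "hazard_model"))
  disease <- disease_model(hazards, config$kappa, config$carrier_prob)
  repro <- reproduction_model(onset_scale = config$onset_scale)
  r <- config$founder_birth_range
  founder_birth <- floor(stats::runif(1, r[1], r[2] + 1))
  founder_carrier <- introduce_variant(config$variant_mode,
                                       config$carrier_prob)

  ## flat per-member storage, grown as members are created
  id <- integer(); sex <- integer(); dad <- integer(); mom <- integer()
  da <- integer(); birth <- integer(); onset <- integer(); death <- integer()
  modelled <- logical()  # FALSE for married-in co-parents (no life history)
  spouse_of <- integer() # spouse id per member, NA until first reproduction

  new_member <- function(sex_, dad_, mom_, da_, birth_, modelled_) {
    i <- length(id) + 1L
    id[i] <<- i; sex[i] <<- sex_; dad[i] <<- dad_; mom[i] <<- mom_
    da[i] <<- da_; birth[i] <<- birth_
    onset[i] <<- NA_integer_; death[i] <<- NA_integer_
    modelled[i] <<- modelled_; spouse_of[i] <<- NA_integer_
    i
  }

  founder <- new_member(sex_ = sample(1:2, 1), dad_ = NA_integer_,
                        mom_ = NA_integer_, da_ = founder_carrier,
                        birth_ = as.integer(founder_birth), modelled_ = TRUE)
  queue <- founder
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    events <- simulate_life(birth_year = birth[i], carrier = da[i],
                            disease = disease, repro = repro,
                            stop_year = config$stop_year)
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      if (ev$kind == "onset") {
        onset[i] <- ev$year
      } else if (ev$kind == "death") {
        death[i] <- ev$year
      } else if (ev$kind == "reproduction") {
        if (is.na(spouse_of[i])) {
          spouse_of[i] <- new_member(sex_ = 3L - sex[i], dad_ = NA_integer_,
                                     mom_ = NA_integer_, da_ = 0L,
                                     birth_ = NA_integer_, modelled_ = FALSE)
        }
        s <- spouse_of[i]
        child <- new_member(sex_ = sample(1:2, 1),
                            dad_ = if (sex[i] == 1L) i else s,
                            mom_ = if (sex[i] == 1L) s else i,
                            da_ = transmit_variant(da[i]),
                            birth_ = ev$year, modelled_ = TRUE)
        queue <- c(queue, child)
      }
      ## "censored": nothing to record; life history simply stops
    }
  }

  ped <- data.frame(
    FamID = as.integer(famid), ID = id, sex = sex, dadID = dad, momID = mom,
    affected = ifelse(modelled, as.integer(!is.na(onset)), NA_integer_),
    DA = ifelse(modelled, da, NA_integer_),
    birthYr = birth, onsetYr = onset, deathYr = death,
    RR = ifelse(modelled & da == 1L, config$kappa, 1),
    available = TRUE, proband = FALSE,
    stringsAsFactors = FALSE
  )
  ## married-in co-parents: history not modelled, but they are known
  ## non-carriers by construction (the variant enters by one founder only)
  ped$DA[!modelled] <- 0L
  ped$affected[!modelled] <- 0L
  ped$RR[!modelled] <- 1
  as_rv_ped(ped)
}
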