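#' Age-specific hazard model
#'
#' Bundles an age partition with three columns of age-specific hazard rates:
#' the population hazard of disease onset, the hazard of death in the
#' unaffected population, and the hazard of death in the affected population.
#' Rates are piecewise constant over half-open yearly (or coarser) age bins
#' `[partition[k], partition[k+1])`; the final partition boundary is the
#' maximum modelled age, at which any survivor is recorded as dying.
#'
#' @param hazard_table data frame (or matrix) with three non-negative numeric
#'   columns: population disease-onset hazard, death hazard for unaffected
#'   individuals, death hazard for affected individuals (events/person-year).
#'   One row per age bin.
#' @param partition numeric vector of age-bin boundaries in years, strictly
#'   increasing, starting at 0, of length `nrow(hazard_table) + 1`.
#'
#' @return An object of class `hazard_model`: a list with elements
#'   `partition`, `onset_pop`, `death_unaffected`, `death_affected`.
#' @examples
#' h <- hazard_model(data.frame(onset = rep(0.001, 100),
#'                              du = rep(0.01, 100),
#'                              da = rep(0.02, 100)),
#'                   partition = 0:100)
#' cumulative_hazard(h, "onset_pop", from_age = 30, to_age = 40)
#' @export
hazard_model <- function(hazard_table, partition) {
  hazard_table <- as.data.frame(hazard_table)
  if (ncol(hazard_table) != 3L) {
    stop("hazard_table must have exactly 3 columns ",
         "(onset_pop, death_unaffected, death_affected); got ",
         ncol(hazard_table))
  }
  partition <- as.numeric(partition)
  if (length(partition) < 2L) {
    stop("partition must contain at least two boundaries")
  }
  if (partition[1L] != 0) {
    stop("partition must start at 0")
  }
  if (any(diff(partition) <= 0)) {
    stop("partition must be strictly increasing")
  }
  if (nrow(hazard_table) != length(partition) - 1L) {
    stop("hazard_table has ", nrow(hazard_table), " rows but partition ",
         "defines ", length(partition) - 1L, " age bins")
  }
  cols <- c("onset_pop", "death_unaffected", "death_affected")
  for (j in seq_along(cols)) {
    v <- as.numeric(hazard_table[[j]])
    if (any(!is.finite(v))) {
      stop("non-finite hazard rate in column ", cols[j])
    }
    if (any(v < 0)) {
      stop("negative hazard rate in column ", cols[j],
           " (row ", which(v < 0)[1L], ")")
    }
    hazard_table[[j]] <- v
  }
  structure(
    list(partition = partition,
         onset_pop = hazard_table[[1L]],
         death_unaffected = hazard_table[[2L]],
         death_affected = hazard_table[[3L]]),
    class = "hazard_model"
  )
}

#' @export
print.hazard_model <- function(x, ...) {
  nb <- length(x$partition) - 1L
  cat("<hazard_model> ", nb, " age bins on [0, ", max_age(x), ")\n", sep = "")
  cat("  onset_pop:        ", format(range(x$onset_pop), digits = 4), "\n")
  cat("  death_unaffected: ", format(range(x$death_unaffected), digits = 4), "\n")
  cat("  death_affected:   ", format(range(x$death_affected), digits = 4), "\n")
  invisible(x)
}

#' Maximum modelled age of a hazard model
#'
#' @param model a `hazard_model`.
#' @return The final partition boundary, in years.
#' @export
max_age <- function(model) {
  model$partition[length(model$partition)]
}

hazard_column <- function(model, column) {
  column <- match.arg(column,
                      c("onset_pop", "death_unaffected", "death_affected"))
  model[[column]]
}

## Piecewise-constant cumulative hazard over [from, to), exact (no quadrature).
pc_cumhaz <- function(partition, rates, from, to) {
  lo <- pmax(partition[-length(partition)], from)
  hi <- pmin(partition[-1L], to)
  sum(rates * pmax(hi - lo, 0))
}

## Smallest w such that the cumulative hazard over [from, from + w) equals
## `target`; +Inf when the remaining mass up to the final boundary is smaller.
pc_invert <- function(partition, rates, from, target) {
  if (target <= 0) return(0)
  n <- length(rates)
  lo <- pmax(partition[-length(partition)], from)
  hi <- pmin(partition[-1L], max(partition))
  widths <- pmax(hi - lo, 0)
  mass <- rates * widths
  cum <- cumsum(mass)
  k <- which(cum >= target - 1e-15 & mass > 0)
  if (length(k) == 0L) return(Inf)
  k <- k[1L]
  prev <- if (k == 1L) 0 else cum[k - 1L]
  within <- (target - prev) / rates[k]
  (lo[k] + within) - from
}

#' Cumulative hazard over an age interval
#'
#' Exact integral of a piecewise-constant hazard column over `[from_age,
#' to_age)`, optionally scaled by a multiplier (e.g. the genetic relative-risk
#' applied to a carrier's onset hazard).
#'
#' @param model a `hazard_model`.
#' @param column one of `"onset_pop"`, `"death_unaffected"`,
#'   `"death_affected"`.
#' @param from_age,to_age interval endpoints in years, with
#'   `0 <= from_age <= to_age <= max_age(model)`.
#' @param kappa_mult non-negative multiplier applied to the hazard column.
#' @return The dimensionless cumulative hazard.
#' @export
cumulative_hazard <- function(model, column, from_age, to_age,
                              kappa_mult = 1) {
  stopifnot(inherits(model, "hazard_model"))
  if (from_age < 0 || to_age < from_age || to_age > max_age(model)) {
    stop("ages must satisfy 0 <= from_age <= to_age <= ", max_age(model))
  }
  kappa_mult * pc_cumhaz(model$partition, hazard_column(model, column),
                         from_age, to_age)
}

#' Invert a cumulative hazard to a waiting time
#'
#' Returns the smallest waiting time `w` such that the cumulative hazard of
#' the chosen column over `[from_age, from_age + w)` equals `target`, or
#' `Inf` when the hazard mass remaining before the final partition boundary
#' is less than `target`. With `target` drawn from Exp(1) this is the
#' standard inversion sampler for a non-homogeneous Poisson process.
#'
#' @inheritParams cumulative_hazard
#' @param target non-negative cumulative-hazard target (an Exp(1) draw for
#'   sampling).
#' @return Waiting time in years, possibly `Inf`.
#' @export
invert_cumulative_hazard <- function(model, column, from_age, target,
                                     kappa_mult = 1) {
  stopifnot(inherits(model, "hazard_model"))
  if (target < 0) stop("target must be >= 0")
  if (from_age < 0 || from_age > max_age(model)) {
    stop("from_age outside modelled age range [0, ", max_age(model), "]")
  }
  pc_invert(model$partition,
            kappa_mult * hazard_column(model, column),
            from_age, target)
}

#' Read / write a hazard model as CSV
#'
#' The CSV dialect has header `age_lo,onset_pop,death_unaffected,
#' death_affected` with one row per age bin; the partition is reconstructed
#' from `age_lo` plus a final `max_age` boundary. The reader is strict:
#' `age_lo` must start at 0 and be strictly increasing with no gaps relative
#' to the declared boundaries.
#'
#' @param path file path.
#' @param max_age final partition boundary appended after the last `age_lo`.
#' @return `read_hazard_csv` returns a `hazard_model`; `write_hazard_csv`
#'   invisibly returns `path`.
#' @export
read_hazard_csv <- function(path, max_age = 100) {
  if (!file.exists(path)) stop("hazard file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("age_lo", "onset_pop", "death_unaffected", "death_affected")
  if (!identical(names(df), need)) {
    stop("hazard CSV must have header exactly: ", paste(need, collapse = ","))
  }
  if (max_age <= df$age_lo[length(df$age_lo)]) {
    stop("max_age must exceed the last age_lo (",
         df$age_lo[length(df$age_lo)], ")")
  }
  hazard_model(df[, c("onset_pop", "death_unaffected", "death_affected")],
               partition = c(df$age_lo, max_age))
}

#' @rdname read_hazard_csv
#' @param model a `hazard_model` to serialize.
#' @export
write_hazard_csv <- function(model, path) {
  stopifnot(inherits(model, "hazard_model"))
  df <- data.frame(age_lo = model$partition[-length(model$partition)],
                   onset_pop = model$onset_pop,
                   death_unaffected = model$death_unaffected,
                   death_affected = model$death_affected)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
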