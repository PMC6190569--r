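#' Pedigree data frame
#'
#' A pedigree is stored as a data frame of class `rv_ped` with one row per
#' member and columns:
#' \describe{
#'   \item{FamID}{family identifier}
#'   \item{ID}{individual identifier, unique within the family, assigned in
#'     creation order (parents before offspring)}
#'   \item{sex}{1 = male, 2 = female (linkage convention)}
#'   \item{dadID, momID}{parent identifiers, both present or both `NA`}
#'   \item{affected}{0/1 disease status; `NA` for trimmed connectors}
#'   \item{DA}{0/1 carrier status of the causal (disease) allele; `NA` for
#'     trimmed connectors and for married-in members with unmodelled history}
#'   \item{birthYr, onsetYr, deathYr}{integer calendar years, `NA` when the
#'     event did not occur or the information is missing}
#'   \item{RR}{relative risk of disease: `kappa` for carriers, 1 otherwise}
#'   \item{available}{`FALSE` for connectors retained only to specify
#'     relationships}
#'   \item{proband}{`TRUE` for the proband (at most one per family)}
#' }
#'
#' @param df data frame with the columns above.
#' @param validate run structural checks (default `TRUE`).
#' @return The data frame with class `c("rv_ped", "data.frame")`.
#' @export
as_rv_ped <- function(df, validate = TRUE) {
  need <- ped_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  for (col in c("FamID", "ID", "sex", "dadID", "momID", "affected", "DA",
                "birthYr", "onsetYr", "deathYr")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$RR <- as.numeric(df$RR)
  df$available <- as.logical(df$available)
  df$proband <- as.logical(df$proband)
  class(df) <- c("rv_ped", "data.frame")
  if (validate) validate_ped(df)
  df
}

ped_columns <- function() {
  c("FamID", "ID", "sex", "dadID", "momID", "affected", "DA",
    "birthYr", "onsetYr", "deathYr", "RR", "available", "proband")
}

#' Validate pedigree structure
#'
#' Checks identifier uniqueness, parent resolution (both parents present or
#' both absent, referencing rows of the same family), acyclicity of the
#' parent graph, and event-year ordering (birth <= onset <= death where
#' known).
#'
#' @param ped an `rv_ped` data frame.
#' @return `ped`, invisibly; errors name the offending family/individual.
#' @export
validate_ped <- function(ped) {
  for (fid in unique(ped$FamID)) {
    fam <- ped[ped$FamID == fid, , drop = FALSE]
    if (anyDuplicated(fam$ID)) {
      stop("duplicate individual ID in family ", fid, ": ",
           fam$ID[duplicated(fam$ID)][1L])
    }
    one_parent <- xor(is.na(fam$dadID), is.na(fam$momID))
    if (any(one_parent)) {
      stop("individual ", fam$ID[one_parent][1L], " in family ", fid,
           " has exactly one parent recorded; need both or neither")
    }
    for (col in c("dadID", "momID")) {
      ref <- fam[[col]][!is.na(fam[[col]])]
      dangling <- setdiff(ref, fam$ID)
      if (length(dangling)) {
        stop("family ", fid, ": ", col, " ", dangling[1L],
             " does not reference a member of the family")
      }
    }
    if (ped_has_cycle(fam)) {
      stop("family ", fid, ": parent graph contains a cycle")
    }
    bad <- which(!is.na(fam$birthYr) & !is.na(fam$onsetYr) &
                   fam$onsetYr < fam$birthYr)
    if (length(bad)) {
      stop("family ", fid, ", individual ", fam$ID[bad[1L]],
           ": onset year precedes birth year")
    }
    bad <- which(!is.na(fam$onsetYr) & !is.na(fam$deathYr) &
                   fam$deathYr < fam$onsetYr)
    if (length(bad)) {
      stop("family ", fid, ", individual ", fam$ID[bad[1L]],
           ": death year precedes onset year")
    }
    if (sum(fam$proband, na.rm = TRUE) > 1L) {
      stop("family ", fid, ": more than one proband")
    }
  }
  invisible(ped)
}

ped_has_cycle <- function(fam) {
  idx <- match(fam$ID, fam$ID)
  dad <- match(fam$dadID, fam$ID)
  mom <- match(fam$momID, fam$ID)
  colour <- integer(nrow(fam))  # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    stack <- i
    path <- integer()
    while (length(stack)) {
      j <- stack[length(stack)]
      if (colour[j] == 1L) {
        colour[j] <<- 2L
        stack <- stack[-length(stack)]
        next
      }
      if (colour[j] == 2L) {
        stack <- stack[-length(stack)]
        next
      }
      colour[j] <<- 1L
      for (p in c(dad[j], mom[j])) {
        if (!is.na(p)) {
          if (colour[p] == 1L) return(TRUE)
          if (colour[p] == 0L) stack <- c(stack, p)
        }
      }
    }
    FALSE
  }
  for (i in seq_along(idx)) {
    if (colour[i] == 0L && visit(i)) return(TRUE)
  }
  FALSE
}

#' @export
print.rv_ped <- function(x, ...) {
  cat("<rv_ped> family ", paste(unique(x$FamID), collapse = ", "),
      ": ", nrow(x), " members, ",
      sum(x$affected == 1, na.rm = TRUE), " affected",
      if (any(x$DA == 1, na.rm = TRUE)) ", segregating causal variant" else "",
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Does the pedigree segregate the causal variant?
#'
#' @param ped an `rv_ped`.
#' @return `TRUE` iff at least one member with known carrier status carries
#'   the variant.
#' @export
seg_variant <- function(ped) {
  any(ped$DA == 1, na.rm = TRUE)
}
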