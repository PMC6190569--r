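#' Select the proband
#'
#' The proband is the affected family member through whom the family enters
#' the study, presumed to make contact at disease onset. Eligible members
#' are those whose onset year falls within the ascertainment span and whose
#' onset is at least the `num_affected`-th onset in the family (onset-order
#' ties break by onset age, then ID, for determinism). One eligible member
#' is chosen uniformly at random.
#'
#' @param ped an `rv_ped`.
#' @param config a [study_config()].
#' @return An individual ID, or `NA` if no member is eligible.
#' @export
find_proband <- function(ped, config) {
  aff <- which(!is.na(ped$affected) & ped$affected == 1 & !is.na(ped$onsetYr))
  if (length(aff) < config$num_affected) return(NA_integer_)
  onset_age <- ped$onsetYr[aff] - ped$birthYr[aff]
  ord <- order(ped$onsetYr[aff], onset_age, ped$ID[aff])
  rank <- integer(length(aff))
  rank[ord] <- seq_along(aff)
  span <- config$ascertain_span
  eligible <- aff[rank >= config$num_affected &
                    ped$onsetYr[aff] >= span[1] &
                    ped$onsetYr[aff] <= span[2]]
  if (!length(eligible)) return(NA_integer_)
  ped$ID[eligible[sample.int(length(eligible), 1L)]]
}

#' Default recall probabilities: four times the kinship coefficient
#'
#' The proband recalls each blood relative with probability
#' `min(1, 4 * phi)` where `phi` is their kinship coefficient with the
#' proband: 1 for first-degree relatives (parents, siblings, offspring),
#' 0.5 for second-degree, 0.25 for third-degree, and so on.
#'
#' @param ped an `rv_ped`.
#' @param proband proband's individual ID.
#' @return Named numeric vector of recall probabilities (names are IDs; the
#'   proband gets 1, unrelated married-in members get 0).
#' @export
default_recall <- function(ped, proband) {
  phi <- kinship_matrix(ped)[as.character(proband), ]
  p <- pmin(4 * phi, 1)  # names come from the first argument
  p[as.character(proband)] <- 1
  p
}

## recall probabilities from a user vector (p_1, ..., p_q) applied by
## relationship degree; degree >= q gets p_q, unrelated members get 0
recall_from_degrees <- function(ped, proband, probs) {
  phi <- kinship_matrix(ped)[as.character(proband), ]
  d <- relationship_degree(phi)
  q <- length(probs)
  p <- numeric(length(phi))
  related <- is.finite(d) & d >= 1
  p[related] <- probs[pmin(d[related], q)]
  names(p) <- names(phi)
  p[as.character(proband)] <- 1
  p
}

#' Trim relatives by the proband's recall probabilities
#'
#' Each blood relative of the proband is independently retained with its
#' recall probability; the proband is always retained. Dropped individuals
#' that are needed to specify the relationships among the recalled members
#' (connectors on the paths joining them to their most recent common
#' ancestor) are re-added, marked unavailable, with disease status, carrier
#' status, relative risk and event years set to missing. Married-in
#' co-parents are retained exactly when at least one of their offspring is
#' retained alongside the blood co-parent; members whose parents are both
#' absent from the trimmed pedigree become parentless.
#'
#' @param ped an `rv_ped`.
#' @param proband proband's individual ID.
#' @param recall_probs `NULL` for the default four-times-kinship rule, or a
#'   numeric vector `(p_1, ..., p_q)` applied by relationship degree.
#' @return The trimmed `rv_ped` with the proband flagged.
#' @export
trim_by_recall <- function(ped, proband, recall_probs = NULL) {
  p <- if (is.null(recall_probs)) default_recall(ped, proband)
       else recall_from_degrees(ped, proband, recall_probs)
  dad <- match(ped$dadID, ped$ID)
  has_parents <- !is.na(dad)
  blood <- ped$ID == proband | has_parents |
    kinship_matrix(ped)[as.character(proband), ] > 0
  ## independent retention of blood relatives; proband always kept
  keep <- blood & (stats::runif(nrow(ped)) < p[as.character(ped$ID)])
  keep[ped$ID == proband] <- TRUE

  ## connectors: blood-tree paths from each recalled member to the MRCA of
  ## the recalled set (minimal subtree of a rooted tree). Parentless
  ## co-parents (the founder's spouse, recalled ancestors who married in)
  ## ride on their blood spouse's chain: a couple counts as one generation.
  bs <- blood_structure(ped)
  dadi <- match(ped$dadID, ped$ID)
  momi <- match(ped$momID, ped$ID)
  ext_chain <- function(i) {
    if (!is.na(dadi[i])) return(blood_chain(bs, i))
    kids <- which((!is.na(dadi) & dadi == i) | (!is.na(momi) & momi == i))
    if (!length(kids)) return(i)
    bp <- bs$parent[kids[1L]]
    if (is.na(bp) || bp == i) blood_chain(bs, i)
    else c(i, blood_chain(bs, bp))
  }
  recalled <- which(keep)
  chains <- lapply(recalled, ext_chain)
  common <- Reduce(intersect, chains)  # ordered nearest-first
  if (!length(common)) {
    stop("recalled members share no common ancestor within the pedigree")
  }
  mrca <- common[1L]
  present <- unique(unlist(lapply(chains, function(ch) {
    ch[seq_len(which(ch == mrca)[1L])]
  })))

  ## pair closure: whenever one parent of a present member is present, the
  ## other must be too (parent links resolve in pairs); the missing one is
  ## always a married-in co-parent, so a single pass reaches the fixpoint
  for (i in present) {
    d <- dadi[i]
    if (is.na(d)) next
    m <- momi[i]
    if (d %in% present && !(m %in% present)) present <- c(present, m)
    if (m %in% present && !(d %in% present)) present <- c(present, d)
  }

  ## present members that were not recalled: relatives of the proband
  ## return as unavailable connectors with all their information masked;
  ## married-in co-parents outside the proband's kinship (never subject to
  ## recall) are retained as ordinary members
  out <- ped[sort(present), , drop = FALSE]
  is_conn <- !(out$ID %in% ped$ID[recalled]) & blood[match(out$ID, ped$ID)]
  out$affected[is_conn] <- NA_integer_
  out$DA[is_conn] <- NA_integer_
  out$RR[is_conn] <- NA_real_
  out$birthYr[is_conn] <- NA_integer_
  out$onsetYr[is_conn] <- NA_integer_
  out$deathYr[is_conn] <- NA_integer_
  out$available <- !is_conn

  ## members whose parents were cut above the retained subtree lose their
  ## parent references (they head the trimmed pedigree)
  drop_parents <- !is.na(out$dadID) &
    !(out$dadID %in% out$ID & out$momID %in% out$ID)
  out$dadID[drop_parents] <- NA_integer_
  out$momID[drop_parents] <- NA_integer_
  out$proband <- out$ID == proband
  rownames(out) <- NULL
  as_rv_ped(out)
}

#' Simulate one ascertained pedigree (discard-and-retry)
#'
#' Repeats simulate -> select proband -> trim until the trimmed pedigree
#' still contains at least `num_affected` members with known affected
#' status (recall trimming can drop affecteds below the threshold, in which
#' case the whole pedigree is discarded and a new one simulated).
#'
#' @param config a [study_config()].
#' @param hazards a [hazard_model()].
#' @param famid family identifier.
#' @return An object of class `rv_ped_pair`: a list with `full_ped` (the
#'   pedigree before trimming, proband flagged), `ascertained_ped` (after
#'   trimming) and `attempts` (number of pedigrees simulated).
#' @export
ascertain_pedigree <- function(config, hazards, famid = 1L) {
  for (attempt in seq_len(config$max_attempts)) {
    ped <- simulate_pedigree(config, hazards, famid = famid)
    proband <- find_proband(ped, config)
    if (is.na(proband)) next
    trimmed <- trim_by_recall(ped, proband, config$recall_probs)
    n_aff <- sum(trimmed$affected == 1, na.rm = TRUE)
    if (n_aff < config$num_affected) next
    ped$proband <- ped$ID == proband
    return(structure(list(full_ped = ped, ascertained_ped = trimmed,
                          attempts = attempt),
                     class = "rv_ped_pair"))
  }
  stop("no pedigree met the ascertainment criteria after ",
       config$max_attempts, " attempts; check the configuration")
}

#' @export
print.rv_ped_pair <- function(x, ...) {
  cat("<rv_ped_pair> ascertained after ", x$attempts, " attempt(s)\n",
      "full pedigree: ", nrow(x$full_ped), " members; ascertained: ",
      nrow(x$ascertained_ped), " members, ",
      sum(x$ascertained_ped$affected == 1, na.rm = TRUE), " affected\n",
      sep = "")
  invisible(x)
}

#' Simulate a study sample of ascertained pedigrees
#'
#' Simulates `n_families` independent ascertained pedigrees with family IDs
#' `1..n_families`. Each family draws its own sub-seed, derived once from
#' the master seed, so results are reproducible and independent of
#' execution order.
#'
#' @param config a [study_config()].
#' @param hazards a [hazard_model()].
#' @param n_families number of ascertained families required.
#' @param seed optional master seed; defaults to `config$seed`.
#' @param progress print a dot per family (for long runs).
#' @return A list of `rv_ped_pair` objects, class `rv_study`.
#' @export
simulate_study <- function(config, hazards, n_families, seed = NULL,
                           progress = FALSE) {
  stopifnot(n_families >= 1)
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, n_families)
  study <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    set.seed(subseeds[i])
    study[[i]] <- ascertain_pedigree(config, hazards, famid = i)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(study, class = c("rv_study", "list"))
}

#' @export
print.rv_study <- function(x, ...) {
  n_aff <- vapply(x, function(p) {
    sum(p$ascertained_ped$affected == 1, na.rm = TRUE)
  }, numeric(1))
  cat("<rv_study> ", length(x), " ascertained families; affected per family: ",
      paste(range(n_aff), collapse = "-"),
      "; segregating: ",
      sum(vapply(x, function(p) seg_variant(p$ascertained_ped), logical(1))),
      "\n", sep = "")
  invisible(x)
}
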