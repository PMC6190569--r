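#' Kinship coefficients for a pedigree
#'
#' Computes the full matrix of kinship coefficients by the standard
#' recursion, with founders assumed non-inbred and mutually unrelated:
#' \eqn{\phi(i,i) = 1/2 + \phi(f_i, m_i)/2} and, for `j` processed before
#' `i`, \eqn{\phi(i,j) = (\phi(f_i, j) + \phi(m_i, j))/2}, where `f_i`,
#' `m_i` are `i`'s parents (zero terms for founders).
#'
#' @param ped an `rv_ped` data frame for a single family.
#' @return A symmetric numeric matrix with dimnames `ped$ID`.
#' @examples
#' ped <- as_rv_ped(data.frame(
#'   FamID = 1, ID = 1:3, sex = c(1, 2, 1),
#'   dadID = c(NA, NA, 1), momID = c(NA, NA, 2),
#'   affected = 0, DA = 0, birthYr = NA, onsetYr = NA, deathYr = NA,
#'   RR = 1, available = TRUE, proband = FALSE))
#' kinship_matrix(ped)["1", "3"]  # parent-child: 0.25
#' @export
kinship_matrix <- function(ped) {
  stopifnot(length(unique(ped$FamID)) == 1L)
  n <- nrow(ped)
  ord <- ped_topological_order(ped)
  dad <- match(ped$dadID, ped$ID)
  mom <- match(ped$momID, ped$ID)
  phi <- matrix(0, n, n, dimnames = list(ped$ID, ped$ID))
  for (i in ord) {
    if (is.na(dad[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 + 0.5 * phi[dad[i], mom[i]]
      for (j in seq_len(n)) {
        if (j == i) next
        v <- 0.5 * (phi[dad[i], j] + phi[mom[i], j])
        if (v > phi[i, j]) { phi[i, j] <- v; phi[j, i] <- v }
      }
    }
  }
  phi
}

## members ordered so that parents always precede their offspring
ped_topological_order <- function(ped) {
  dad <- match(ped$dadID, ped$ID)
  mom <- match(ped$momID, ped$ID)
  n <- nrow(ped)
  placed <- logical(n)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (is.na(dad) | dad %in% ord) &
                     (is.na(mom) | mom %in% ord))
    if (!length(ready)) stop("parent graph contains a cycle")
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Kinship coefficient between two members
#'
#' @param ped an `rv_ped` for a single family.
#' @param a,b individual IDs.
#' @return \eqn{\phi(a, b) \in [0, 1/2]} (1/2 + inbreeding/2 on the
#'   diagonal).
#' @export
kinship <- function(ped, a, b) {
  ids <- as.character(ped$ID)
  if (!as.character(a) %in% ids) stop("unknown individual ID: ", a)
  if (!as.character(b) %in% ids) stop("unknown individual ID: ", b)
  kinship_matrix(ped)[as.character(a), as.character(b)]
}

#' Mean pairwise IBD sharing among affected relatives
#'
#' The familial-clustering statistic: the average over unordered pairs of
#' disease-affected members of the pairwise IBD probability \eqn{2\phi}
#' (the expected genome fraction shared identical by descent for non-inbred
#' pairs). An affected parent-child or sibling pair gives 0.5; an avuncular
#' or grandparent-grandchild pair gives 0.25.
#'
#' @param ped an `rv_ped` for a single family.
#' @param members IDs over which to average; defaults to all members with
#'   known affected status 1.
#' @return Mean pairwise IBD probability in `[0, 1]`.
#' @export
a_ibd <- function(ped, members = NULL) {
  if (is.null(members)) {
    members <- ped$ID[!is.na(ped$affected) & ped$affected == 1]
  }
  if (length(members) < 2L) {
    stop("a_ibd requires at least two affected members")
  }
  phi <- kinship_matrix(ped)
  idx <- as.character(members)
  pairs <- utils::combn(idx, 2)
  mean(2 * phi[cbind(pairs[1, ], pairs[2, ])])
}

#' Relationship degree from the kinship coefficient
#'
#' Degree `d` of a non-inbred relative pair satisfies `2 * phi = (1/2)^d`,
#' so `d = round(-log2(2 * phi))`; unrelated pairs (`phi = 0`) get `Inf`.
#'
#' @param phi kinship coefficient(s).
#' @return Integer degree(s); `Inf` where `phi == 0`.
#' @export
relationship_degree <- function(phi) {
  d <- rep(Inf, length(phi))
  pos <- phi > 0
  d[pos] <- round(-log2(2 * phi[pos]))
  d
}

## Within the single-founder model (no inbreeding, one union per member)
## blood relatives form a tree: each member with recorded parents has
## exactly one blood-line parent -- the parent who has parents of their own,
## or, at the root couple where neither does, the earlier-created member
## (married-in co-parents are always created after their blood spouse, so
## they carry the larger ID). Returns the blood-parent pointer and the
## depth of each member along blood-parent links (parentless members: 0).
blood_structure <- function(ped) {
  dad <- match(ped$dadID, ped$ID)
  mom <- match(ped$momID, ped$ID)
  hp <- !is.na(dad)
  n <- nrow(ped)
  bp <- rep(NA_integer_, n)
  depth <- numeric(n)
  for (i in ped_topological_order(ped)) {
    if (!hp[i]) next
    d <- dad[i]
    m <- mom[i]
    bp[i] <- if (hp[d]) d
             else if (hp[m]) m
             else if (ped$ID[d] < ped$ID[m]) d else m
    depth[i] <- depth[bp[i]] + 1
  }
  list(parent = bp, depth = depth)
}

## indices of i's ancestors-or-self along blood-parent links, nearest first
blood_chain <- function(bs, i) {
  out <- i
  while (!is.na(bs$parent[out[length(out)]])) {
    out <- c(out, bs$parent[out[length(out)]])
  }
  out
}

#' Generation numbers for anticipation analysis
#'
#' Assigns generation numbers anchored at the most recent common ancestor
#' (MRCA) with whom all affected members could share a variant identical by
#' descent; an affected member may be their own MRCA. The MRCA gets
#' generation 1 and every descendant's generation is 1 plus its depth below
#' the MRCA along parent links. An affected parent-child pair is thus
#' assigned generations 1 and 2; an affected sibling pair both get 2.
#' Members who are not the MRCA or its descendants (married-in co-parents,
#' relatives above the MRCA) get `NA`.
#'
#' @param ped an `rv_ped` for a single family.
#' @param affecteds IDs anchoring the MRCA; defaults to members with known
#'   affected status 1.
#' @return Named numeric vector of generation numbers (names are IDs), `NA`
#'   for members outside the MRCA's descent.
#' @export
assign_generation <- function(ped, affecteds = NULL) {
  if (is.null(affecteds)) {
    affecteds <- ped$ID[!is.na(ped$affected) & ped$affected == 1]
  }
  if (!length(affecteds)) stop("no affected members to anchor the MRCA")
  bs <- blood_structure(ped)
  idx <- match(affecteds, ped$ID)
  if (anyNA(idx)) stop("unknown individual ID among affecteds")
  chains <- lapply(idx, function(i) blood_chain(bs, i))
  common <- Reduce(intersect, chains)
  if (!length(common)) {
    stop("affected members share no common ancestor within the pedigree")
  }
  mrca <- common[which.max(bs$depth[common])]
  ## generation defined only for the MRCA and its blood descendants
  gen <- rep(NA_real_, nrow(ped))
  for (i in seq_len(nrow(ped))) {
    ch <- blood_chain(bs, i)
    if (mrca %in% ch) gen[i] <- 1 + bs$depth[i] - bs$depth[mrca]
  }
  names(gen) <- ped$ID
  gen
}

#' Onset-age and death-age tables by assigned generation
#'
#' For each family the affected members' onset ages are tabulated by
#' generation number (see [assign_generation()]); ages of death of
#' unaffected relatives in the same descent are tabulated in parallel as a
#' negative control for right-censoring. Trimmed connectors (missing
#' status) are excluded from both tables.
#'
#' @param study a list of ascertained pairs from [simulate_study()], or a
#'   list of `rv_ped` data frames.
#' @return A list of two data frames: `onset` with columns `FamID`, `ID`,
#'   `generation`, `onset_age`, and `death_control` with columns `FamID`,
#'   `ID`, `generation`, `death_age`.
#' @export
anticipation_tables <- function(study) {
  stopifnot(length(study) >= 1L)
  onset_rows <- list()
  death_rows <- list()
  for (el in study) {
    ped <- if (inherits(el, "rv_ped_pair")) el$ascertained_ped else el
    gen <- assign_generation(ped)
    aff <- !is.na(ped$affected) & ped$affected == 1 &
      !is.na(ped$onsetYr) & !is.na(ped$birthYr)
    if (any(aff)) {
      onset_rows[[length(onset_rows) + 1L]] <- data.frame(
        FamID = ped$FamID[aff], ID = ped$ID[aff],
        generation = unname(gen[aff]),
        onset_age = ped$onsetYr[aff] - ped$birthYr[aff])
    }
    un <- !is.na(ped$affected) & ped$affected == 0 &
      !is.na(ped$deathYr) & !is.na(ped$birthYr) & !is.na(gen)
    if (any(un)) {
      death_rows[[length(death_rows) + 1L]] <- data.frame(
        FamID = ped$FamID[un], ID = ped$ID[un],
        generation = unname(gen[un]),
        death_age = ped$deathYr[un] - ped$birthYr[un])
    }
  }
  list(onset = do.call(rbind, onset_rows),
       death_control = do.call(rbind, death_rows))
}

#' Per-family and per-affected summary tables
#'
#' `summarize_family()` reduces one ascertained family to a one-row family
#' summary plus one row per disease-affected relative. The family table
#' carries: family ID, total number of relatives, number of affected
#' relatives, their average onset age, the mean pairwise IBD statistic
#' [a_ibd()], the ascertainment year (the proband's onset year), and whether
#' the family segregates the causal variant. The affected table carries
#' birth/onset/death years, relative risk, proband flag and carrier status.
#'
#' @param pair an `rv_ped_pair` from [ascertain_pedigree()], or an `rv_ped`
#'   with a marked proband.
#' @return A list of two data frames, `family_info` (columns `FamID`,
#'   `totalRelatives`, `numAffected`, `aveOnsetAge`, `aveIBD`,
#'   `ascertainYear`, `segRV`) and `affected_info` (columns `FamID`, `ID`,
#'   `birthYr`, `onsetYr`, `deathYr`, `RR`, `proband`, `RVstatus`).
#' @export
summarize_family <- function(pair) {
  ped <- if (inherits(pair, "rv_ped_pair")) pair$ascertained_ped else pair
  aff <- !is.na(ped$affected) & ped$affected == 1
  onset_ages <- ped$onsetYr[aff] - ped$birthYr[aff]
  fam <- data.frame(
    FamID = ped$FamID[1L],
    totalRelatives = nrow(ped),
    numAffected = sum(aff),
    aveOnsetAge = if (any(aff)) mean(onset_ages, na.rm = TRUE) else NA_real_,
    aveIBD = if (sum(aff) >= 2L) a_ibd(ped) else NA_real_,
    ascertainYear = if (any(ped$proband)) ped$onsetYr[ped$proband][1L]
                    else NA_integer_,
    segRV = seg_variant(ped))
  affected <- data.frame(
    FamID = ped$FamID[aff], ID = ped$ID[aff],
    birthYr = ped$birthYr[aff], onsetYr = ped$onsetYr[aff],
    deathYr = ped$deathYr[aff], RR = ped$RR[aff],
    proband = ped$proband[aff], RVstatus = ped$DA[aff])
  list(family_info = fam, affected_info = affected)
}

#' Summary tables for a whole study
#'
#' Row-binds [summarize_family()] across the families of a study.
#'
#' @param study a list of `rv_ped_pair` objects (or `rv_ped` data frames).
#' @return A list of two data frames, `family_info` and `affected_info`.
#' @export
summarize_study <- function(study) {
  per <- lapply(study, summarize_family)
  list(family_info = do.call(rbind, lapply(per, `[[`, "family_info")),
       affected_info = do.call(rbind, lapply(per, `[[`, "affected_info")))
}

#' Proportion of ascertained families segregating a causal variant
#'
#' Among families with at least `min_affected` relatives of known affected
#' status 1, the fraction whose pedigree carries the causal variant. Used
#' with studies simulated under the Bernoulli variant-introduction mode,
#' where fully sporadic families can be ascertained.
#'
#' @param study a list of `rv_ped_pair` objects (or `rv_ped` data frames).
#' @param min_affected threshold `n_A` on the number of affected relatives.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when no family
#'   meets the threshold.
#' @export
proportion_segregating <- function(study, min_affected = 2) {
  info <- summarize_study(study)$family_info
  keep <- info$numAffected >= min_affected
  if (!any(keep)) {
    warning("no family has >= ", min_affected, " affected relatives; ",
            "proportion undefined")
    return(NA_real_)
  }
  mean(info$segRV[keep])
}
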