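## Shared fixtures: hand-built pedigrees, tiny hazard models, and a
## gene-dropping Monte Carlo oracle for kinship.

make_ped <- function(ID, dadID = NA, momID = NA, sex = NULL,
                     affected = 0, DA = 0, birthYr = NA, onsetYr = NA,
                     deathYr = NA, RR = 1, available = TRUE,
                     proband = FALSE, FamID = 1) {
  n <- length(ID)
  if (is.null(sex)) sex <- rep(c(1L, 2L), length.out = n)
  as_rv_ped(data.frame(FamID = FamID, ID = ID, sex = sex,
                       dadID = dadID, momID = momID,
                       affected = affected, DA = DA, birthYr = birthYr,
                       onsetYr = onsetYr, deathYr = deathYr, RR = RR,
                       available = available, proband = proband))
}

## 1-2 couple, child 3
ped_parent_child <- function(affected = c(1, 0, 1)) {
  make_ped(ID = 1:3, dadID = c(NA, NA, 1), momID = c(NA, NA, 2),
           sex = c(1, 2, 1), affected = affected)
}

## 1-2 couple, children 3 and 4
ped_sibs <- function(affected = c(0, 0, 1, 1)) {
  make_ped(ID = 1:4, dadID = c(NA, NA, 1, 1), momID = c(NA, NA, 2, 2),
           sex = c(1, 2, 1, 2), affected = affected)
}

## grandparents 1-2; sons 3 (uncle) and 4; 4 x 5 -> nephew 6
ped_avuncular <- function(affected = c(0, 0, 1, 0, 0, 1)) {
  make_ped(ID = 1:6,
           dadID = c(NA, NA, 1, 1, NA, 4),
           momID = c(NA, NA, 2, 2, NA, 5),
           sex = c(1, 2, 1, 1, 2, 1), affected = affected)
}

## grandparents 1-2; child 3; spouse 4; grandchild 5
ped_grandparent <- function(affected = c(1, 0, 0, 0, 1)) {
  make_ped(ID = 1:5,
           dadID = c(NA, NA, 1, NA, 3),
           momID = c(NA, NA, 2, NA, 4),
           sex = c(1, 2, 1, 2, 2), affected = affected)
}

## grandparents 1-2; sibs 3, 5; spouses 4, 6; first cousins 7 and 8
ped_cousins <- function(affected = c(0, 0, 0, 0, 0, 0, 1, 1)) {
  make_ped(ID = 1:8,
           dadID = c(NA, NA, 1, NA, 1, NA, 3, 5),
           momID = c(NA, NA, 2, NA, 2, NA, 4, 6),
           sex = c(1, 2, 1, 2, 1, 2, 1, 2), affected = affected)
}

## constant-rate hazard model on yearly bins 0..max_age
flat_hazards <- function(onset = 0.01, death_u = 0.01, death_a = 0.02,
                         max_age = 100) {
  hazard_model(data.frame(onset_pop = rep(onset, max_age),
                          death_unaffected = rep(death_u, max_age),
                          death_affected = rep(death_a, max_age)),
               partition = 0:max_age)
}

## Monte Carlo kinship oracle: drop founder alleles down the pedigree and
## count identity by descent between random alleles of a and b
gene_drop_kinship <- function(ped, a, b, ndrops = 1e5) {
  n <- nrow(ped)
  dad <- match(ped$dadID, ped$ID)
  mom <- match(ped$momID, ped$ID)
  ord <- rvpedsim:::ped_topological_order(ped)
  pat <- matrix(0L, ndrops, n)
  mat <- matrix(0L, ndrops, n)
  for (i in ord) {
    if (is.na(dad[i])) {
      pat[, i] <- 2L * i - 1L
      mat[, i] <- 2L * i
    } else {
      from_dad <- stats::runif(ndrops) < 0.5
      pat[, i] <- ifelse(from_dad, pat[, dad[i]], mat[, dad[i]])
      from_mom <- stats::runif(ndrops) < 0.5
      mat[, i] <- ifelse(from_mom, pat[, mom[i]], mat[, mom[i]])
    }
  }
  ia <- match(a, ped$ID)
  ib <- match(b, ped$ID)
  mean((pat[, ia] == pat[, ib]) + (pat[, ia] == mat[, ib]) +
         (mat[, ia] == pat[, ib]) + (mat[, ia] == mat[, ib])) / 4
}

## offspring count from the event loop: repeated conditional repro waits
## from birth for an unaffected survivor of the full reproductive span
count_offspring <- function(traits, repro = reproduction_model()) {
  age <- 0
  count <- 0L
  repeat {
    w <- draw_repro_wait(age, affected = FALSE, traits = traits,
                         repro = repro)
    if (is.infinite(w)) return(count)
    age <- age + w
    count <- count + 1L
  }
}
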