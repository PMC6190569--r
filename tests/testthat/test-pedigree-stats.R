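test_that("kinship recursion gives textbook coefficients", {
  expect_equal(kinship(ped_parent_child(), 1, 3), 0.25)
  expect_equal(kinship(ped_sibs(), 3, 4), 0.25)
  expect_equal(kinship(ped_grandparent(), 1, 5), 0.125)
  expect_equal(kinship(ped_avuncular(), 3, 6), 0.125)
  expect_equal(kinship(ped_cousins(), 7, 8), 1 / 16)
  # unrelated married-in founders
  expect_equal(kinship(ped_avuncular(), 2, 5), 0)
  expect_equal(kinship(ped_parent_child(), 3, 3), 0.5)  # non-inbred self
  expect_error(kinship(ped_sibs(), 1, 99), "unknown")
})

test_that("kinship agrees with a gene-dropping Monte Carlo oracle", {
  set.seed(1405)
  peds <- list(ped_cousins(), ped_avuncular(), ped_grandparent())
  pairs <- list(c(7, 8), c(3, 6), c(1, 5))
  for (k in seq_along(peds)) {
    phi <- kinship(peds[[k]], pairs[[k]][1], pairs[[k]][2])
    est <- gene_drop_kinship(peds[[k]], pairs[[k]][1], pairs[[k]][2],
                             ndrops = 1e5)
    expect_lt(abs(est - phi), 3 * sqrt(phi * (1 - phi) / 1e5))
  }
  # a randomly simulated 3-4 generation pedigree
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 10, founder_birth_range = c(1900, 1925))
  repeat {
    ped <- simulate_pedigree(cfg, h)
    if (nrow(ped) >= 10) break
  }
  ids <- sample(ped$ID, 2)
  phi <- kinship(ped, ids[1], ids[2])
  est <- gene_drop_kinship(ped, ids[1], ids[2], ndrops = 1e5)
  tol <- 3 * sqrt(max(phi * (1 - phi), 1e-4) / 1e5)
  expect_lt(abs(est - phi), tol)
})

test_that("mean pairwise IBD among affecteds matches analytic values", {
  expect_equal(a_ibd(ped_parent_child()), 0.5)
  expect_equal(a_ibd(ped_sibs()), 0.5)
  expect_equal(a_ibd(ped_avuncular()), 0.25)
  expect_equal(a_ibd(ped_grandparent()), 0.25)
  # two affected sibs plus their affected first cousin:
  # pairwise 2*phi values are 0.5, 0.125, 0.125
  ped <- make_ped(ID = 1:9,
                  dadID = c(NA, NA, 1, NA, 1, NA, 3, 3, 5),
                  momID = c(NA, NA, 2, NA, 2, NA, 4, 4, 6),
                  sex = c(1, 2, 1, 2, 1, 2, 1, 1, 2),
                  affected = c(0, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_equal(a_ibd(ped), mean(c(0.5, 0.125, 0.125)))
  expect_error(a_ibd(ped_parent_child(affected = c(0, 0, 1))),
               "at least two")
})

test_that("generation assignment is anchored at the affecteds' common ancestor", {
  gen <- assign_generation(ped_parent_child())
  expect_equal(unname(gen[c("1", "3")]), c(1, 2))  # parent 1, child 2
  gen <- assign_generation(ped_sibs())
  expect_equal(unname(gen[c("3", "4")]), c(2, 2))  # both siblings 2
  # a single affected is their own most recent common ancestor
  gen <- assign_generation(ped_parent_child(affected = c(0, 0, 1)))
  expect_equal(unname(gen["3"]), 1)
  # avuncular pair: MRCA is the grandparent couple (generation 1)
  gen <- assign_generation(ped_avuncular())
  expect_equal(unname(gen[c("3", "6")]), c(2, 3))
  # married-in spouse is outside the MRCA descent
  expect_true(is.na(gen["5"]))
  # invariant to relabelling of member IDs
  ped <- ped_avuncular()
  relab <- c(10, 20, 31, 44, 52, 66)
  ped2 <- ped
  ped2$ID <- relab[match(ped$ID, 1:6)]
  ped2$dadID <- relab[match(ped$dadID, 1:6)]
  ped2$momID <- relab[match(ped$momID, 1:6)]
  gen2 <- assign_generation(as_rv_ped(ped2))
  expect_equal(unname(gen2[as.character(relab)]), unname(gen[as.character(1:6)]))
})

test_that("family summaries carry the documented columns and values", {
  ped <- ped_parent_child()
  ped$birthYr <- c(1940L, 1945L, 1970L)
  ped$onsetYr <- c(1995L, NA, 2005L)
  ped$DA <- c(1L, 0L, 1L)
  ped$RR <- c(10, 1, 10)
  ped$proband <- c(FALSE, FALSE, TRUE)
  s <- summarize_family(as_rv_ped(ped))
  expect_named(s$family_info,
               c("FamID", "totalRelatives", "numAffected", "aveOnsetAge",
                 "aveIBD", "ascertainYear", "segRV"))
  expect_named(s$affected_info,
               c("FamID", "ID", "birthYr", "onsetYr", "deathYr", "RR",
                 "proband", "RVstatus"))
  expect_equal(s$family_info$aveIBD, 0.5)
  expect_equal(s$family_info$numAffected, 2)
  expect_equal(s$family_info$aveOnsetAge, mean(c(55, 35)))
  expect_equal(s$family_info$ascertainYear, 2005)
  expect_true(s$family_info$segRV)
  expect_equal(nrow(s$affected_info), 2)
})

test_that("proportion segregating handles degenerate studies", {
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 20, carrier_prob = 0,
                      variant_mode = "bernoulli", num_affected = 2)
  set.seed(1506)
  study <- simulate_study(cfg, h, n_families = 5)
  expect_equal(proportion_segregating(study, 2), 0)  # p_c = 0: no carriers
  cfg2 <- study_config(kappa = 20, variant_mode = "eldest_founder",
                       recall_probs = c(1))
  study2 <- simulate_study(cfg2, h, n_families = 5)
  expect_equal(proportion_segregating(study2, 2), 1)  # forced introduction
  expect_warning(p <- proportion_segregating(study2, 50), "no family")
  expect_true(is.na(p))
})

test_that("anticipation tables exclude connectors and missing years", {
  ped <- ped_grandparent()
  ped$birthYr <- c(1900L, 1905L, 1930L, 1932L, 1960L)
  ped$onsetYr <- c(1970L, NA, NA, NA, 2005L)
  ped$deathYr <- c(1980L, 1985L, NA, 2000L, NA)
  ped <- as_rv_ped(ped)
  tabs <- anticipation_tables(list(ped))
  expect_equal(nrow(tabs$onset), 2)
  expect_equal(tabs$onset$generation, c(1, 3))
  expect_equal(tabs$onset$onset_age, c(70, 45))
  # unaffected death control: member 3 has no death year, member 2 and 4 are
  # married-in (outside the MRCA descent) -> no control rows here
  expect_null(tabs$death_control)
  # an unaffected death inside the descent shows up
  ped$deathYr[3] <- 1990L
  tabs <- anticipation_tables(list(as_rv_ped(ped)))
  expect_equal(tabs$death_control$ID, 3)
  expect_equal(tabs$death_control$generation, 2)
  expect_equal(tabs$death_control$death_age, 60)
})
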