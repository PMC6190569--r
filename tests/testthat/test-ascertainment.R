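test_that("proband eligibility follows onset order and the ascertainment span", {
  cfg <- study_config(num_affected = 2, ascertain_span = c(2000, 2010),
                      stop_year = 2016)
  ped <- ped_sibs()
  ped$birthYr <- c(1940L, 1945L, 1970L, 1972L)
  # onsets 1995 and 2005: only the 2005 member is at least the 2nd affected
  ped$onsetYr <- c(NA, NA, 1995L, 2005L)
  ped <- as_rv_ped(ped)
  set.seed(1)
  expect_identical(find_proband(ped, cfg), 4L)
  # both onsets in span: the later one is always eligible, the earlier never
  ped$onsetYr <- c(NA, NA, 2003L, 2007L)
  expect_true(all(replicate(20, find_proband(ped, cfg)) == 4L))
  # a single onset cannot be the second affected
  ped$affected <- c(0L, 0L, 0L, 1L)
  ped$onsetYr <- c(NA, NA, NA, 2005L)
  expect_identical(find_proband(ped, cfg), NA_integer_)
  # second onset outside the span: no proband
  ped$affected <- c(0L, 0L, 1L, 1L)
  ped$onsetYr <- c(NA, NA, 1995L, 2014L)
  cfg2 <- study_config(num_affected = 2, ascertain_span = c(2000, 2010),
                       stop_year = 2016)
  expect_identical(find_proband(ped, cfg2), NA_integer_)
})

test_that("default recall ladder is four times the kinship coefficient", {
  # sibling (1st degree) 1; grandparent (2nd) 0.5; cousin (3rd) 0.25
  p <- default_recall(ped_sibs(), proband = 3)
  expect_equal(unname(p["4"]), 1)
  expect_equal(unname(p["1"]), 1)   # parent
  p <- default_recall(ped_grandparent(), proband = 5)
  expect_equal(unname(p["1"]), 0.5)
  p <- default_recall(ped_cousins(), proband = 7)
  expect_equal(unname(p["8"]), 0.25)
  expect_equal(unname(p["1"]), 0.5)  # grandparent
  expect_equal(unname(p["5"]), 0.5)  # uncle: 2nd degree
})

test_that("user recall vectors apply by relationship degree with tail rule", {
  ped <- ped_cousins()
  p <- rvpedsim:::recall_from_degrees(ped, proband = 7, probs = c(1, 0.4))
  expect_equal(unname(p["3"]), 1)    # parent: degree 1
  expect_equal(unname(p["1"]), 0.4)  # grandparent: degree 2
  expect_equal(unname(p["8"]), 0.4)  # cousin: degree 3 >= q gets p_q
  expect_equal(unname(p["4"]), 1)    # other parent: degree 1
  expect_equal(unname(p["6"]), 0)    # married-in aunt: unrelated
})

test_that("recall probability 1 retains the full pedigree", {
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 10, recall_probs = c(1))
  set.seed(1607)
  pair <- ascertain_pedigree(cfg, h)
  expect_setequal(pair$ascertained_ped$ID, pair$full_ped$ID)
  expect_true(all(pair$ascertained_ped$available))
  expect_identical(sum(pair$ascertained_ped$proband), 1L)
  # trimming with recall 1 does not alter any recorded field
  asc <- pair$ascertained_ped[order(pair$ascertained_ped$ID), ]
  full <- pair$full_ped[order(pair$full_ped$ID), ]
  expect_equal(asc$onsetYr, full$onsetYr)
  expect_equal(asc$DA, full$DA)
})

test_that("zero recall keeps only the proband", {
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 10)
  set.seed(1708)
  repeat {
    ped <- simulate_pedigree(cfg, h)
    pb <- find_proband(ped, cfg)
    if (!is.na(pb)) break
  }
  tr <- trim_by_recall(ped, pb, recall_probs = c(0))
  expect_true(all(tr$available == tr$proband))
  expect_identical(sum(tr$affected == 1, na.rm = TRUE), 1L)
  expect_true(tr$proband[tr$ID == pb])
})

test_that("dropped connectors are re-added unavailable with missing data", {
  # 3 generations: grandparent couple 1-2, parent 3 (spouse 4), child 5;
  # proband is the grandchild, the grandparent 1 is affected and recalled,
  # the intermediate parent 3 is dropped -> must return as a connector
  ped <- ped_grandparent(affected = c(1, 0, 0, 0, 1))
  ped$birthYr <- c(1900L, 1902L, 1930L, 1931L, 1958L)
  ped$onsetYr <- c(1960L, NA, NA, NA, 2004L)
  ped <- as_rv_ped(ped)
  found_connector <- FALSE
  set.seed(1809)
  for (i in 1:50) {
    # never recall 1st-degree relatives (the parent), always recall 2nd
    # degree (the affected grandparent): forces a dropped intermediate
    tr <- trim_by_recall(ped, proband = 5, recall_probs = c(0, 1))
    if (1 %in% tr$ID && 3 %in% tr$ID && !tr$available[tr$ID == 3]) {
      found_connector <- TRUE
      conn <- tr[tr$ID == 3, ]
      expect_true(is.na(conn$affected))
      expect_true(is.na(conn$RR))
      expect_true(is.na(conn$birthYr) && is.na(conn$onsetYr) &&
                    is.na(conn$deathYr))
      # spouse of the connector is retained so parent links resolve
      expect_true(4 %in% tr$ID)
      expect_silent(validate_ped(tr))
    }
  }
  expect_true(found_connector)
})

test_that("ascertained pairs satisfy the ascertainment contract", {
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 10, num_affected = 2)
  set.seed(1910)
  study <- simulate_study(cfg, h, n_families = 15)
  for (pair in study) {
    asc <- pair$ascertained_ped
    expect_identical(sum(asc$proband), 1L)
    pb <- asc[asc$proband, ]
    expect_identical(pb$affected, 1L)
    expect_true(pb$available)
    expect_true(pb$onsetYr >= 2000 && pb$onsetYr <= 2015)
    expect_gte(sum(asc$affected == 1, na.rm = TRUE), 2)
    expect_silent(validate_ped(asc))
    expect_gte(pair$attempts, 1)
  }
})

test_that("study simulation is reproducible and label-stable", {
  h <- synthetic_hazards()
  cfg <- study_config(kappa = 20)
  s1 <- simulate_study(cfg, h, n_families = 4, seed = 77)
  s2 <- simulate_study(cfg, h, n_families = 4, seed = 77)
  expect_identical(lapply(s1, `[[`, "ascertained_ped"),
                   lapply(s2, `[[`, "ascertained_ped"))
  expect_identical(vapply(s1, function(p) p$full_ped$FamID[1], integer(1)),
                   1:4)
})

test_that("impossible criteria fail loudly at the attempt ceiling", {
  h0 <- flat_hazards(onset = 0)  # no onsets can ever occur
  cfg <- study_config(kappa = 1, max_attempts = 25)
  set.seed(3)
  expect_error(ascertain_pedigree(cfg, h0), "25 attempts")
})
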