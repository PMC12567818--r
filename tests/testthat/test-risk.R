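test_that("risk assessment returns the full reporting structure", {
  s <- generate_samples(generator_config(seed = 31L))
  rr <- run_risk_assessment(s)
  expect_s3_class(rr, "risk_result")
  expect_setequal(unique(rr$hi$group), dust_seasons())
  expect_setequal(unique(rr$hi$receptor), c("adult", "child"))
  # HQ metals are those with an RfD; CR metals those with a slope factor
  expect_setequal(unique(rr$hq$metal), c("Cd", "Ni", "As", "Zn", "Cu", "Cr"))
  expect_setequal(unique(rr$total_cr$metal), c("Cd", "Ni", "As", "Pb"))
  expect_true(all(rr$hq$lower <= rr$hq$upper))
  expect_true(all(rr$cr$lower >= 0))
  expect_true(all(rr$total_cr$level %in% default_risk_levels()$label))
})

test_that("HI endpoints equal the sum of constituent HQ endpoints", {
  s <- generate_samples(generator_config(seed = 32L))
  rr <- run_risk_assessment(s)
  for (i in seq_len(nrow(rr$hi))) {
    sub <- rr$hq[rr$hq$group == rr$hi$group[i] &
                   rr$hq$receptor == rr$hi$receptor[i], ]
    expect_equal(sum(sub$lower), rr$hi$lower[i], tolerance = 1e-12)
    expect_equal(sum(sub$upper), rr$hi$upper[i], tolerance = 1e-12)
  }
})

test_that("membership degrees per metal sum to 1 and match the assignment", {
  s <- generate_samples(generator_config(seed = 33L))
  rr <- run_risk_assessment(s)
  key <- paste(rr$membership$group, rr$membership$receptor,
               rr$membership$metal)
  for (k in unique(key)) {
    mem <- rr$membership[key == k, ]
    expect_equal(sum(mem$membership), 1, tolerance = 1e-12)
    tot <- rr$total_cr[paste(rr$total_cr$group, rr$total_cr$receptor,
                             rr$total_cr$metal) == k, ]
    expect_equal(tot$level,
                 assign_level(stats::setNames(mem$membership, mem$level)))
  }
})

test_that("total CR dominates each single-pathway CR componentwise", {
  s <- generate_samples(generator_config(seed = 34L))
  rr <- run_risk_assessment(s)
  for (i in seq_len(nrow(rr$total_cr))) {
    sub <- rr$cr[rr$cr$group == rr$total_cr$group[i] &
                   rr$cr$receptor == rr$total_cr$receptor[i] &
                   rr$cr$metal == rr$total_cr$metal[i], ]
    expect_true(all(rr$total_cr$upper[i] >= sub$upper - 1e-18))
    expect_true(all(rr$total_cr$lower[i] >= sub$lower - 1e-18))
  }
})

test_that("oral ingestion dominates CR for Cd, As and Pb", {
  s <- generate_samples(generator_config(seed = 35L))
  rr <- run_risk_assessment(s)
  dom <- rr$total_cr[rr$total_cr$metal %in% c("Cd", "As", "Pb"), ]
  expect_true(all(dom$dominant_pathway == "ingestion"))
  # Ni carries only an inhalation slope factor
  ni <- rr$total_cr[rr$total_cr$metal == "Ni", ]
  expect_true(all(ni$dominant_pathway == "inhalation"))
})

test_that("a fully degenerate configuration reproduces the crisp model", {
  cfg <- generator_config(cv = 0, rd_concentration = Inf,
                          site_effects = matrix(
                            1, nrow = 7, ncol = 4,
                            dimnames = list(dust_metals(),
                                            c("S1", "S2", "S3", "S4"))),
                          seed = 36L)
  s <- generate_samples(cfg)
  set.seed(37)
  p <- random_classic_params()
  scn <- crisp_scenario_from_params("adult", p)
  tox <- default_toxicity()
  rr <- run_risk_assessment(s, scenarios = list(adult = scn), tox = tox)
  long <- samples_long(s)
  for (g in unique(rr$hi$group)) {
    want_hi <- 0
    for (m in dust_metals()) {
      cdba <- unique(long$cdba[long$metal == m & long$season == g])
      expect_length(cdba, 1) # degenerate by construction
      out <- classic_model(cdba, p, rfd = tox[[m]]$rfd, sf = tox[[m]]$sf)
      if (!is.null(tox[[m]]$rfd)) want_hi <- want_hi + out$hq
      if (!is.null(tox[[m]]$sf)) {
        tot <- rr$total_cr[rr$total_cr$group == g & rr$total_cr$metal == m, ]
        expect_equal(tot$lower, out$cr, tolerance = 1e-12)
        expect_equal(tot$upper, out$cr, tolerance = 1e-12)
      }
    }
    hi <- rr$hi[rr$hi$group == g, ]
    expect_equal(hi$lower, want_hi, tolerance = 1e-12)
    expect_equal(hi$upper, want_hi, tolerance = 1e-12)
  }
})

test_that("pooled grouping collapses to a single group", {
  s <- generate_samples(generator_config(seed = 38L))
  rr <- run_risk_assessment(s, grouping = "pooled")
  expect_equal(unique(rr$hi$group), "pooled")
  expect_equal(nrow(rr$hi), 2)
})

test_that("the Eq-13 style normalization flows through the pipeline", {
  s <- generate_samples(generator_config(seed = 39L))
  rr <- run_risk_assessment(s, normalization = "level_interval")
  key <- paste(rr$membership$group, rr$membership$receptor,
               rr$membership$metal)
  sums <- tapply(rr$membership$membership, key, sum)
  # with the level-width denominator the degrees need not sum to 1
  expect_false(all(abs(sums - 1) < 1e-9))
})
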