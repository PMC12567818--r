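crisp_test_scenario <- function(ABS = 0.001, SA = 2800, EF = 350) {
  exposure_scenario("child", IngR = 200, InhR = 7.5, BW = 20,
                    ED = 6, EF = EF, AT_nc = 2190, AT_ca = 2190,
                    SA = SA, SSAR = 0.2, ABS = ABS, PEF = 1.36e9)
}

test_that("exposure scenarios validate their parameters", {
  expect_error(crisp_test_scenario(EF = 400), "366")
  expect_error(exposure_scenario("adult", IngR = 100, InhR = 14.5, BW = 0,
                                 ED = 24, EF = 350, AT_nc = 8760,
                                 AT_ca = 25550, SA = 5700, SSAR = 0.07,
                                 ABS = 0.001, PEF = 1.36e9),
               "positive")
  expect_error(crisp_test_scenario(ABS = -0.1), "ABS")
  scns <- default_exposure_scenarios()
  expect_setequal(names(scns), c("adult", "child"))
  for (s in scns) {
    expect_s3_class(s$IngR, "tfn")
    expect_s3_class(s$BW, "tfn")
    expect_gt(s$BW[["a1"]], 0)
  }
})

test_that("degenerate ingestion intake matches hand arithmetic", {
  scn <- crisp_test_scenario()
  itv <- intake_ingestion(tfn(100, 100, 100), scn, alpha = 0.9)
  want <- 100 * 6 * 350 * 200 / (20 * 2190) * 1e-6 # 9.589041e-4
  expect_equal(interval_lower(itv), want, tolerance = 1e-12)
  expect_equal(interval_upper(itv), want, tolerance = 1e-12)
  # zero concentration gives a zero interval
  z <- intake_ingestion(tfn(0, 0, 0), scn)
  expect_equal(c(interval_lower(z), interval_upper(z)), c(0, 0))
})

test_that("degenerate inhalation intake matches hand arithmetic", {
  scn <- crisp_test_scenario()
  itv <- intake_inhalation(tfn(100, 100, 100), scn)
  want <- 100 * 6 * 350 * 7.5 / (20 * 2190 * 1.36e9) # 2.644e-8
  expect_equal(interval_upper(itv), want, tolerance = 1e-12)
  expect_equal(round(want, 10), 2.64e-8, tolerance = 1e-3)
})

test_that("dermal intake switches off at ABS = 0 and scales in SA", {
  c100 <- tfn(100, 100, 100)
  z <- intake_dermal(c100, crisp_test_scenario(ABS = 0))
  expect_equal(c(interval_lower(z), interval_upper(z)), c(0, 0))
  base <- intake_dermal(c100, crisp_test_scenario(SA = 2800))
  dbl <- intake_dermal(c100, crisp_test_scenario(SA = 5600))
  expect_equal(interval_lower(dbl), 2 * interval_lower(base), tolerance = 1e-12)
  expect_equal(interval_upper(dbl), 2 * interval_upper(base), tolerance = 1e-12)
})

test_that("intakes are homogeneous in EF", {
  c100 <- tfn(80, 100, 120)
  for (f in list(intake_ingestion, intake_inhalation, intake_dermal)) {
    base <- f(c100, crisp_test_scenario(EF = 150))
    dbl <- f(c100, crisp_test_scenario(EF = 300))
    expect_equal(interval_upper(dbl), 2 * interval_upper(base),
                 tolerance = 1e-12)
  }
})

test_that("fuzzifying BW widens the interval and keeps the crisp value inside", {
  scn_crisp <- crisp_test_scenario()
  scn_fuzzy <- exposure_scenario("child", IngR = 200, InhR = 7.5,
                                 BW = tfn(16, 20, 24), ED = 6, EF = 350,
                                 AT_nc = 2190, AT_ca = 2190, SA = 2800,
                                 SSAR = 0.2, ABS = 0.001, PEF = 1.36e9)
  c100 <- tfn(100, 100, 100)
  a <- intake_ingestion(c100, scn_crisp, 0.9)
  b <- intake_ingestion(c100, scn_fuzzy, 0.9)
  crisp_val <- interval_lower(a)
  expect_lt(interval_lower(b), crisp_val)
  expect_gt(interval_upper(b), crisp_val)
})

test_that("HQ and CR are interval scalings; HI sums endpoints exactly", {
  itv <- fuzzy_interval(1e-4, 2e-4, 0.9)
  hq <- hazard_quotient(itv, 1e-3)
  expect_equal(c(interval_lower(hq), interval_upper(hq)), c(0.1, 0.2))
  expect_error(hazard_quotient(itv, 0), "positive")
  cr <- carcinogenic_risk(fuzzy_interval(1e-6, 2e-6), 1.5)
  expect_equal(c(interval_lower(cr), interval_upper(cr)), c(1.5e-6, 3e-6))
  expect_error(carcinogenic_risk(itv, -1), "positive")

  set.seed(505)
  hqs <- lapply(1:5, function(i) {
    e <- sort(stats::runif(2)); fuzzy_interval(e[1], e[2], 0.9)
  })
  hi <- hazard_index(hqs)
  expect_equal(interval_lower(hi),
               sum(vapply(hqs, interval_lower, numeric(1))), tolerance = 1e-15)
  expect_equal(interval_upper(hi),
               sum(vapply(hqs, interval_upper, numeric(1))), tolerance = 1e-15)
  # permutation invariance
  hi2 <- hazard_index(rev(hqs))
  expect_equal(unclass(hi2)[1:2], unclass(hi)[1:2])
  expect_warning(empty <- hazard_index(list()), "empty")
  expect_equal(c(interval_lower(empty), interval_upper(empty)), c(0, 0))
})

test_that("degenerate fuzzy intakes equal the scalar classical model", {
  set.seed(606)
  for (i in 1:20) {
    p <- random_classic_params()
    scn <- crisp_scenario_from_params("adult", p)
    C <- stats::runif(1, 0.1, 500)
    want_nc <- classic_intakes(C, p, p$AT_nc)
    want_ca <- classic_intakes(C, p, p$AT_ca)
    ctfn <- tfn(C, C, C)
    for (a in c(0, 0.9, 1)) {
      expect_equal(interval_upper(intake_ingestion(ctfn, scn, a)),
                   want_nc$ingestion, tolerance = 1e-12)
      expect_equal(interval_upper(intake_inhalation(ctfn, scn, a)),
                   want_nc$inhalation, tolerance = 1e-12)
      expect_equal(interval_upper(
        intake_dermal(ctfn, scn, a, endpoint = "carcinogenic")),
        want_ca$dermal, tolerance = 1e-12)
    }
  }
})

test_that("monotonicity: larger concentration support never shrinks intakes", {
  scn <- default_exposure_scenarios()$adult
  base <- intake_ingestion(tfn(50, 80, 100), scn, 0.9)
  wider <- intake_ingestion(tfn(50, 80, 150), scn, 0.9)
  expect_gte(interval_upper(wider), interval_upper(base))
  # raising the body-weight minimum never grows the upper endpoint
  scn_hi_bw <- scn
  scn_hi_bw$BW <- tfn(scn$BW[["a1"]] * 1.2, max(scn$BW[["a2"]],
                                                scn$BW[["a1"]] * 1.2),
                      max(scn$BW[["a3"]], scn$BW[["a2"]]))
  shrunk <- intake_ingestion(tfn(50, 80, 100), scn_hi_bw, 0.9)
  expect_lte(interval_upper(shrunk), interval_upper(base))
})
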