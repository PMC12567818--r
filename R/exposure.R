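#' Receptor exposure scenario
#'
#' Bundles the exposure parameters for one receptor class. The sensitive
#' parameters — ingestion rate `IngR`, inhalation rate `InhR` and body
#' weight `BW` — are triangular fuzzy numbers; the remaining parameters are
#' crisp, following the convention that standard-default parameters (ED,
#' EF, AT, ...) carry low sensitivity. Averaging time differs by endpoint:
#' `AT_nc` (non-carcinogenic, ED x 365 days) and `AT_ca` (carcinogenic,
#' lifetime).
#'
#' @param receptor `"adult"` or `"child"`.
#' @param IngR dust ingestion rate, mg/day (TFN or scalar).
#' @param InhR inhalation rate, m3/day (TFN or scalar).
#' @param BW body weight, kg (TFN or scalar).
#' @param ED exposure duration, yr.
#' @param EF exposure frequency, days/yr (at most 366).
#' @param AT_nc,AT_ca averaging times, days, for non-carcinogenic and
#'   carcinogenic endpoints.
#' @param SA exposed skin area, cm2.
#' @param SSAR skin adherence rate, mg/(cm2 day).
#' @param ABS dermal absorption fraction.
#' @param PEF particulate emission factor, m3/kg.
#' @return An object of class `"exposure_scenario"`.
#' @export
exposure_scenario <- function(receptor, IngR, InhR, BW, ED, EF,
                              AT_nc, AT_ca, SA, SSAR, ABS, PEF) {
  receptor <- match.arg(receptor, c("adult", "child"))
  crisp <- c(ED = ED, EF = EF, AT_nc = AT_nc, AT_ca = AT_ca,
             SA = SA, SSAR = SSAR, PEF = PEF)
  if (any(!is.finite(crisp)) || any(crisp <= 0)) {
    bad <- names(crisp)[which(!is.finite(crisp) | crisp <= 0)[1L]]
    stop("exposure parameter '", bad, "' must be strictly positive",
         call. = FALSE)
  }
  # ABS = 0 is legal: it just switches the dermal pathway off
  if (!is.finite(ABS) || ABS < 0) {
    stop("exposure parameter 'ABS' must be non-negative", call. = FALSE)
  }
  if (EF > 366) stop("EF cannot exceed 366 days/yr; got ", EF, call. = FALSE)
  scn <- list(receptor = receptor,
              IngR = as_tfn(IngR), InhR = as_tfn(InhR), BW = as_tfn(BW),
              ED = ED, EF = EF, AT_nc = AT_nc, AT_ca = AT_ca,
              SA = SA, SSAR = SSAR, ABS = ABS, PEF = PEF)
  for (p in c("IngR", "InhR", "BW")) {
    if (scn[[p]][["a1"]] <= 0) {
      stop("fuzzy parameter '", p, "' must have strictly positive support",
           call. = FALSE)
    }
  }
  structure(scn, class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> %s\n", x$receptor))
  cat(sprintf("  IngR (%g,%g,%g) mg/d  InhR (%g,%g,%g) m3/d  BW (%g,%g,%g) kg\n",
              x$IngR[1], x$IngR[2], x$IngR[3],
              x$InhR[1], x$InhR[2], x$InhR[3],
              x$BW[1], x$BW[2], x$BW[3]))
  cat(sprintf("  ED %g yr  EF %g d/yr  AT_nc %g d  AT_ca %g d\n",
              x$ED, x$EF, x$AT_nc, x$AT_ca))
  cat(sprintf("  SA %g cm2  SSAR %g mg/cm2/d  ABS %g  PEF %g m3/kg\n",
              x$SA, x$SSAR, x$ABS, x$PEF))
  invisible(x)
}

scenario_from_list <- function(receptor, p) {
  exposure_scenario(receptor,
                    IngR = as_tfn(unlist(p$IngR)),
                    InhR = as_tfn(unlist(p$InhR)),
                    BW = as_tfn(unlist(p$BW)),
                    ED = p$ED, EF = p$EF, AT_nc = p$AT_nc, AT_ca = p$AT_ca,
                    SA = p$SA, SSAR = p$SSAR, ABS = p$ABS, PEF = p$PEF)
}

#' Bundled receptor scenarios and toxicity parameters
#'
#' Read the standards-derived defaults shipped with the package (or a user
#' file in the same YAML layout). The bundled values follow HJ 25.3-2019 /
#' USEPA conventions; none is a site-specific measurement and all may be
#' overridden by supplying a custom file.
#'
#' @param path YAML file; defaults to the bundled configuration.
#' @return For `default_exposure_scenarios()`, a named list of
#'   `"exposure_scenario"` objects (adult, child); for `default_toxicity()`,
#'   a nested list `metal -> rfd/sf -> pathway -> value`.
#' @export
default_exposure_scenarios <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exposure_defaults.yaml",
                                package = "fuzzydust", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  stats::setNames(
    lapply(names(cfg), function(r) scenario_from_list(r, cfg[[r]])),
    names(cfg)
  )
}

#' @rdname default_exposure_scenarios
#' @export
default_toxicity <- function(path = NULL) {
  path <- path %||% system.file("extdata", "toxicity_defaults.yaml",
                                package = "fuzzydust", mustWork = TRUE)
  tox <- yaml::read_yaml(path)
  for (m in names(tox)) {
    for (kind in intersect(c("rfd", "sf"), names(tox[[m]]))) {
      vals <- unlist(tox[[m]][[kind]])
      if (any(vals <= 0)) {
        stop("toxicity value must be positive: ", m, " ", kind, call. = FALSE)
      }
      bad <- setdiff(names(vals), c("ingestion", "inhalation", "dermal"))
      if (length(bad) > 0L) {
        stop("unknown pathway '", bad[1L], "' for metal ", m, call. = FALSE)
      }
    }
  }
  tox
}

#' Read a risk-level scheme from YAML
#'
#' @param path YAML file: an ordered list of `{label, lower, upper}` maps;
#'   defaults to the bundled five-level scheme.
#' @return A `"risk_level_scheme"`.
#' @export
read_risk_levels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "risk_levels.yaml",
                                package = "fuzzydust", mustWork = TRUE)
  lv <- yaml::read_yaml(path)
  risk_level_scheme(labels = vapply(lv, `[[`, character(1), "label"),
                    lower = vapply(lv, `[[`, numeric(1), "lower"),
                    upper = vapply(lv, `[[`, numeric(1), "upper"))
}

# ---- fuzzy intake equations -------------------------------------------------

select_at <- function(scn, endpoint) {
  switch(match.arg(endpoint, c("noncarcinogenic", "carcinogenic")),
         noncarcinogenic = scn$AT_nc, carcinogenic = scn$AT_ca)
}

#' Fuzzy daily intake via ingestion, inhalation and dermal contact
#'
#' Alpha-cut propagation of the bioaccessibility-adjusted exposure
#' equations. With bioaccessible concentration `C` (mg/kg, fuzzy), the
#' intakes in mg/(kg d) are:
#' * ingestion: `C * ED * EF * IngR / (BW * AT) * 1e-6`
#' * inhalation: `C * ED * EF * InhR / (BW * AT * PEF)`
#' * dermal: `C * ED * EF * SA * SSAR * ABS / (BW * AT) * 1e-6`
#'
#' The averaging time is chosen by `endpoint`: `AT_nc` for hazard-quotient
#' use, `AT_ca` for carcinogenic-risk use.
#'
#' @param cdba bioaccessible concentration as a `"tfn"` (mg/kg).
#' @param scn an `"exposure_scenario"`.
#' @param alpha confidence level of the cut (default 0.9).
#' @param endpoint `"noncarcinogenic"` or `"carcinogenic"`.
#' @return A `"fuzzy_interval"` intake in mg/(kg d).
#' @export
intake_ingestion <- function(cdba, scn, alpha = 0.9,
                             endpoint = "noncarcinogenic") {
  at <- select_at(scn, endpoint)
  num <- interval_mul(alpha_cut(cdba, alpha), alpha_cut(scn$IngR, alpha))
  q <- interval_div(num, alpha_cut(scn$BW, alpha))
  interval_scale(scn$ED * scn$EF * 1e-6 / at, q)
}

#' @rdname intake_ingestion
#' @export
intake_inhalation <- function(cdba, scn, alpha = 0.9,
                              endpoint = "noncarcinogenic") {
  at <- select_at(scn, endpoint)
  num <- interval_mul(alpha_cut(cdba, alpha), alpha_cut(scn$InhR, alpha))
  q <- interval_div(num, alpha_cut(scn$BW, alpha))
  interval_scale(scn$ED * scn$EF / (at * scn$PEF), q)
}

#' @rdname intake_ingestion
#' @export
intake_dermal <- function(cdba, scn, alpha = 0.9,
                          endpoint = "noncarcinogenic") {
  at <- select_at(scn, endpoint)
  q <- interval_div(alpha_cut(cdba, alpha), alpha_cut(scn$BW, alpha))
  interval_scale(scn$ED * scn$EF * scn$SA * scn$SSAR * scn$ABS * 1e-6 / at, q)
}

#' Hazard quotient, hazard index and carcinogenic risk
#'
#' `hazard_quotient()` divides an intake interval by the pathway reference
#' dose RfD. `hazard_index()` sums hazard-quotient intervals endpointwise;
#' HI below 1 indicates no significant non-carcinogenic risk, and the
#' result carries a `below_one` attribute (`upper < 1`).
#' `carcinogenic_risk()` multiplies an intake interval by the slope factor
#' SF.
#'
#' @param intake a `"fuzzy_interval"` intake, mg/(kg d).
#' @param rfd reference dose, mg/(kg d), strictly positive.
#' @param hqs list of hazard-quotient `"fuzzy_interval"`s.
#' @param sf slope factor, (kg d)/mg, strictly positive.
#' @return A `"fuzzy_interval"`.
#' @export
hazard_quotient <- function(intake, rfd) {
  if (!is.numeric(rfd) || length(rfd) != 1L || is.na(rfd) || rfd <= 0) {
    stop("RfD must be a single strictly positive number", call. = FALSE)
  }
  interval_scale(1 / rfd, intake)
}

#' @rdname hazard_quotient
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0L) {
    warning("empty hazard-quotient set; HI is [0, 0]", call. = FALSE)
    return(structure(fuzzy_interval(0, 0), below_one = TRUE))
  }
  hi <- Reduce(interval_add, hqs)
  attr(hi, "below_one") <- interval_upper(hi) < 1
  hi
}

#' @rdname hazard_quotient
#' @export
carcinogenic_risk <- function(intake, sf) {
  if (!is.numeric(sf) || length(sf) != 1L || is.na(sf) || sf <= 0) {
    stop("slope factor must be a single strictly positive number",
         call. = FALSE)
  }
  interval_scale(sf, intake)
}
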