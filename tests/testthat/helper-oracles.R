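# Independent oracles used across the suite. These deliberately avoid the
# package's interval and exposure code paths.

# Brute-force min/max of op(x, y) over a dense endpoint-inclusive grid of
# the two intervals.
grid_interval_op <- function(op, a_lo, a_hi, b_lo, b_hi, n = 41L) {
  xs <- seq(a_lo, a_hi, length.out = n)
  ys <- seq(b_lo, b_hi, length.out = n)
  f <- switch(op, add = `+`, mul = `*`, div = `/`)
  vals <- outer(xs, ys, f)
  c(min(vals), max(vals))
}

# Scalar classical exposure-risk model (crisp USEPA-style equations),
# written directly in arithmetic. `p` is a list of scalar parameters.
classic_intakes <- function(C, p, at) {
  list(
    ingestion  = C * p$ED * p$EF * p$IngR / (p$BW * at) * 1e-6,
    inhalation = C * p$ED * p$EF * p$InhR / (p$BW * at * p$PEF),
    dermal     = C * p$ED * p$EF * p$SA * p$SSAR * p$ABS / (p$BW * at) * 1e-6
  )
}

classic_model <- function(C, p, rfd = NULL, sf = NULL) {
  nc <- classic_intakes(C, p, p$AT_nc)
  ca <- classic_intakes(C, p, p$AT_ca)
  hq <- if (!is.null(rfd)) {
    sum(vapply(names(rfd), function(pw) nc[[pw]] / rfd[[pw]], numeric(1)))
  } else NA_real_
  cr <- if (!is.null(sf)) {
    sum(vapply(names(sf), function(pw) ca[[pw]] * sf[[pw]], numeric(1)))
  } else NA_real_
  list(intake_nc = nc, intake_ca = ca, hq = hq, cr = cr)
}

# Random scalar parameter set in physically plausible ranges.
random_classic_params <- function() {
  ed <- stats::runif(1, 1, 40)
  list(IngR = stats::runif(1, 20, 300),
       InhR = stats::runif(1, 4, 25),
       BW = stats::runif(1, 10, 90),
       ED = ed,
       EF = stats::runif(1, 100, 366),
       AT_nc = ed * 365,
       AT_ca = stats::runif(1, 60, 80) * 365,
       SA = stats::runif(1, 1000, 8000),
       SSAR = stats::runif(1, 0.01, 0.5),
       ABS = stats::runif(1, 1e-4, 1e-2),
       PEF = stats::runif(1, 5e8, 5e9))
}

crisp_scenario_from_params <- function(receptor, p) {
  exposure_scenario(receptor, IngR = p$IngR, InhR = p$InhR, BW = p$BW,
                    ED = p$ED, EF = p$EF, AT_nc = p$AT_nc, AT_ca = p$AT_ca,
                    SA = p$SA, SSAR = p$SSAR, ABS = p$ABS, PEF = p$PEF)
}

# Random non-negative TFN with occasional degenerate segments.
random_tfn <- function(scale = 10) {
  v <- sort(stats::runif(3, 0, scale))
  if (stats::runif(1) < 0.1) v[2] <- v[1]
  if (stats::runif(1) < 0.1) v[3] <- v[2]
  tfn(v[1], v[2], v[3])
}

# Tiny hand-built sample table (2 sites x 2 seasons), all constraints valid.
tiny_samples <- function() {
  df <- expand.grid(site = c("S1", "S2"), season = c("winter", "summer"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  n <- nrow(df)
  set.seed(42)
  for (m in dust_metals()) {
    ct <- stats::runif(n, 10, 100)
    df[[paste0("ct_", tolower(m))]] <- ct
    df[[paste0("cdba_", tolower(m))]] <- ct * stats::runif(n, 0.05, 0.4)
  }
  dust_samples(df)
}
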