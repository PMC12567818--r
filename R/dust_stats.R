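#' Seasonal and pooled concentration summary
#'
#' Arithmetic mean, minimum, maximum and count of total concentration per
#' metal, per season and pooled across seasons.
#'
#' @param samples a `"dust_samples"` table.
#' @return A data frame of class `"seasonal_summary"` with columns `metal`,
#'   `season` (one of the four seasons or `"pooled"`), `n`, `mean`, `min`,
#'   `max`, all concentrations in mg/kg.
#' @export
seasonal_summary <- function(samples) {
  long <- samples_long(samples)
  metals <- unique(long$metal)
  grp <- function(sub, season) {
    data.frame(metal = sub$metal[1L], season = season, n = nrow(sub),
               mean = mean(sub$ct), min = min(sub$ct), max = max(sub$ct),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (m in metals) {
    subm <- long[long$metal == m, , drop = FALSE]
    rows[[length(rows) + 1L]] <- grp(subm, "pooled")
    for (s in intersect(dust_seasons(), unique(subm$season))) {
      rows[[length(rows) + 1L]] <- grp(subm[subm$season == s, , drop = FALSE], s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("seasonal_summary", "data.frame")
  out
}

#' Pooled means from a seasonal summary
#'
#' @param summary a `"seasonal_summary"`.
#' @return Named numeric vector of pooled mean concentrations per metal.
#' @export
pooled_means <- function(summary) {
  stopifnot(inherits(summary, "seasonal_summary"))
  sub <- summary[summary$season == "pooled", , drop = FALSE]
  stats::setNames(sub$mean, sub$metal)
}

#' Screening-value exceedance per metal
#'
#' Fraction of samples whose total concentration strictly exceeds the
#' risk-screening value, and the maximum exceedance multiple
#' `max(CT) / screening`. Screening values (e.g. from GB 15618-2018) depend
#' on land use and soil pH and must be supplied by the user; there is no
#' default.
#'
#' @param samples a `"dust_samples"` table.
#' @param screening named numeric vector, mg/kg per metal; must be strictly
#'   positive. Metals without a screening value are skipped with a warning.
#' @return A data frame with columns `metal`, `screening`, `n`, `rate`,
#'   `max_multiple`.
#' @examples
#' # exceedance(samples, c(Ni = 70, As = 20))
#' @export
exceedance <- function(samples, screening) {
  if (is.null(names(screening)) || any(names(screening) == "")) {
    stop("screening values must be a named vector (metal = mg/kg)",
         call. = FALSE)
  }
  if (any(screening <= 0)) {
    stop("screening values must be strictly positive", call. = FALSE)
  }
  long <- samples_long(samples)
  present <- unique(long$metal)
  skipped <- setdiff(present, names(screening))
  if (length(skipped) > 0L) {
    warning("no screening value for metal(s): ",
            paste(skipped, collapse = ", "), "; skipped", call. = FALSE)
  }
  rows <- lapply(intersect(present, names(screening)), function(m) {
    ct <- long$ct[long$metal == m]
    data.frame(metal = m, screening = unname(screening[[m]]), n = length(ct),
               rate = mean(ct > screening[[m]]),
               max_multiple = max(ct) / screening[[m]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise ratios of pooled mean concentrations
#'
#' `ratio[i, j] = mean_i / mean_j`, e.g. how many times higher the Zn mean
#' is than the Cd mean.
#'
#' @param means a `"seasonal_summary"` (pooled means are extracted) or a
#'   named numeric vector of strictly positive means.
#' @return A square matrix of ratios with metal names on both dimensions.
#' @examples
#' mean_ratio_matrix(c(Zn = 703, Cd = 0.68))["Zn", "Cd"] # 1033.8
#' @export
mean_ratio_matrix <- function(means) {
  if (inherits(means, "seasonal_summary")) means <- pooled_means(means)
  stopifnot(is.numeric(means), !is.null(names(means)))
  if (any(means <= 0)) {
    stop("all means must be strictly positive to form ratios", call. = FALSE)
  }
  outer(means, means, "/")
}
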