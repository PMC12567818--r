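#' Carcinogenic risk-level scheme
#'
#' An ordered set of contiguous, lower-closed upper-open intervals that
#' partition the carcinogenic-risk axis into labelled severity levels. The
#' default follows the widely used five-level classification:
#' I very low / negligible `(-Inf, 1e-6)`; II low `[1e-6, 1e-5)`;
#' III moderate `[1e-5, 5e-5)`; IV high `[5e-5, 1e-4)`; V very high
#' `[1e-4, 1)`.
#'
#' @param labels character vector of level labels, ordered from least to most
#'   severe.
#' @param lower,upper numeric bounds per level; each level is `[lower, upper)`.
#' @return A data frame of class `"risk_level_scheme"` with columns `label`,
#'   `lower`, `upper`.
#' @export
risk_level_scheme <- function(labels, lower, upper) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper))
  if (length(labels) == 0L) stop("scheme must have at least one level", call. = FALSE)
  if (anyDuplicated(labels)) stop("level labels must be unique", call. = FALSE)
  if (any(lower >= upper)) {
    stop("each level must satisfy lower < upper", call. = FALSE)
  }
  if (length(labels) > 1L &&
      any(abs(utils::head(upper, -1L) - lower[-1L]) > 0)) {
    stop("levels must be contiguous: each upper bound must equal the next ",
         "lower bound", call. = FALSE)
  }
  structure(
    data.frame(label = as.character(labels), lower = lower, upper = upper,
               stringsAsFactors = FALSE),
    class = c("risk_level_scheme", "data.frame")
  )
}

#' @rdname risk_level_scheme
#' @export
default_risk_levels <- function() {
  risk_level_scheme(
    labels = c("I", "II", "III", "IV", "V"),
    lower  = c(-Inf, 1e-6, 1e-5, 5e-5, 1e-4),
    upper  = c(1e-6, 1e-5, 5e-5, 1e-4, 1)
  )
}

#' Classify a risk interval into level memberships
#'
#' The membership degree of a computed risk interval in each level is the
#' length of the overlap between the interval and the level, divided by a
#' normalizing length. Two normalizations are in use:
#' `"computed_interval"` (default) divides by the length of the computed
#' interval itself, so the degrees over a contiguous scheme sum to 1;
#' `"level_interval"` divides by the length of each level, in which case the
#' degrees need not sum to 1 (and an unbounded level contributes 0).
#'
#' A zero-width (crisp) interval gets membership 1 in the level containing
#' the point (levels are lower-closed, upper-open). Risk values at or above
#' the top of the scheme are clamped into the most severe level with a
#' warning.
#'
#' @param interval a `"fuzzy_interval"` (e.g. a carcinogenic-risk alpha-cut).
#' @param scheme a `"risk_level_scheme"`; defaults to [default_risk_levels()].
#' @param normalization `"computed_interval"` or `"level_interval"`.
#' @return A named numeric vector of class `"membership_vector"`, one degree
#'   per level.
#' @examples
#' classify_interval(fuzzy_interval(5e-7, 5.5e-6)) # I: 0.1, II: 0.9
#' @export
classify_interval <- function(interval,
                              scheme = default_risk_levels(),
                              normalization = c("computed_interval",
                                                "level_interval")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(scheme, "risk_level_scheme"))
  lo <- interval_lower(interval)
  hi <- interval_upper(interval)
  top <- max(scheme$upper)
  if (hi >= top) {
    warning("risk interval reaches ", hi, ", at or above the scheme maximum ",
            top, "; clamping into the most severe level", call. = FALSE)
    hi <- top
    lo <- min(lo, hi)
  }

  if (lo == hi) {
    # crisp value: point mass on the containing level (half-open [lower, upper))
    idx <- which(lo >= scheme$lower & lo < scheme$upper)
    if (length(idx) == 0L) idx <- nrow(scheme) # clamped exactly onto top bound
    deg <- numeric(nrow(scheme))
    deg[idx[1L]] <- 1
  } else {
    overlap <- pmax(0, pmin(hi, scheme$upper) - pmax(lo, scheme$lower))
    denom <- switch(normalization,
                    computed_interval = rep(hi - lo, nrow(scheme)),
                    level_interval = scheme$upper - scheme$lower)
    deg <- overlap / denom
    deg[!is.finite(deg)] <- 0 # unbounded level under level_interval
  }
  structure(stats::setNames(deg, scheme$label), class = "membership_vector")
}

#' @export
print.membership_vector <- function(x, ...) {
  cat("<membership>", paste(sprintf("%s: %.4g", names(x), unclass(x)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Assign a risk level by the maximum-membership principle
#'
#' Returns the label with the largest membership degree. Ties are broken
#' toward the later (more severe) level, the conservative choice for health
#' protection.
#'
#' @param mv a `"membership_vector"` or named numeric vector, ordered from
#'   least to most severe.
#' @return The winning level label.
#' @examples
#' assign_level(c(I = 0.1, II = 0.9)) # "II"
#' @export
assign_level <- function(mv) {
  if (length(mv) == 0L) stop("empty membership vector", call. = FALSE)
  v <- unclass(mv)
  if (all(v == 0)) {
    stop("all membership degrees are zero; nothing to assign", call. = FALSE)
  }
  # last index achieving the max = most severe among ties
  names(v)[max(which(v == max(v)))]
}
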