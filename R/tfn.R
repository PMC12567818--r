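#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) represents an uncertain non-negative
#' quantity by three values: the minimum `a1`, the most-expected value `a2`,
#' and the maximum `a3`. Its membership function rises linearly from 0 at
#' `a1` to 1 at `a2` and falls linearly back to 0 at `a3`. A degenerate TFN
#' with `a1 == a2 == a3` is a crisp (exact) value.
#'
#' @param a1 minimum value (non-negative).
#' @param a2 most-expected value, `a1 <= a2 <= a3`.
#' @param a3 maximum value.
#' @return An object of class `"tfn"`: a numeric vector `c(a1, a2, a3)`.
#' @examples
#' tfn(0, 1, 2)
#' tfn(5, 5, 5) # crisp 5
#' @export
tfn <- function(a1, a2, a3) {
  stopifnot(is.numeric(a1), is.numeric(a2), is.numeric(a3),
            length(a1) == 1L, length(a2) == 1L, length(a3) == 1L)
  if (any(!is.finite(c(a1, a2, a3)))) {
    stop("TFN components must be finite numbers", call. = FALSE)
  }
  if (a1 < 0) {
    stop("TFN components must be non-negative: a1 = ", a1, call. = FALSE)
  }
  if (a1 > a2) {
    stop("invalid TFN ordering: a1 > a2 (", a1, " > ", a2, ")", call. = FALSE)
  }
  if (a2 > a3) {
    stop("invalid TFN ordering: a2 > a3 (", a2, " > ", a3, ")", call. = FALSE)
  }
  structure(c(a1 = a1, a2 = a2, a3 = a3), class = "tfn")
}

#' Coerce to a triangular fuzzy number
#'
#' Numeric scalars become degenerate (crisp) TFNs; length-3 numerics are
#' interpreted as `(a1, a2, a3)`.
#'
#' @param x object to coerce.
#' @return A `"tfn"` object.
#' @export
as_tfn <- function(x) {
  if (inherits(x, "tfn")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(tfn(x, x, x))
  if (is.numeric(x) && length(x) == 3L) return(tfn(x[[1L]], x[[2L]], x[[3L]]))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to tfn", call. = FALSE)
}

#' @export
print.tfn <- function(x, ...) {
  if (x[["a1"]] == x[["a3"]]) {
    cat(sprintf("<tfn> crisp %g\n", x[["a2"]]))
  } else {
    cat(sprintf("<tfn> (%g, %g, %g)\n", x[["a1"]], x[["a2"]], x[["a3"]]))
  }
  invisible(x)
}

#' Is a TFN crisp (degenerate)?
#'
#' @param x a `"tfn"` object.
#' @return `TRUE` if `a1 == a2 == a3`.
#' @export
is_crisp <- function(x) {
  x <- as_tfn(x)
  x[["a1"]] == x[["a3"]]
}

#' Build a TFN from observed sample values
#'
#' The support is the observed range (`a1 = min`, `a3 = max`) and the
#' most-expected value `a2` is the sample mean (default) or median, clamped
#' into the support. A single observation yields a crisp TFN.
#'
#' @param values numeric vector of non-negative observations.
#' @param center_rule how to estimate `a2`: `"mean"` (default) or `"median"`.
#' @return A `"tfn"` object.
#' @examples
#' tfn_from_samples(c(2, 4, 9))            # (2, 5, 9)
#' tfn_from_samples(c(1, 2, 3, 10), "median")
#' @export
tfn_from_samples <- function(values, center_rule = c("mean", "median")) {
  center_rule <- match.arg(center_rule)
  if (length(values) == 0L) {
    stop("cannot build a TFN from an empty sample", call. = FALSE)
  }
  if (anyNA(values) || !is.numeric(values)) {
    stop("sample values must be numeric and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("sample values must be non-negative; found ",
         min(values), call. = FALSE)
  }
  a1 <- min(values)
  a3 <- max(values)
  a2 <- switch(center_rule, mean = mean(values), median = stats::median(values))
  a2 <- min(max(a2, a1), a3)
  tfn(a1, a2, a3)
}

#' Membership degree of a value in a TFN
#'
#' Piecewise-linear membership: 0 outside the support, rising on
#' `[a1, a2)`, falling on `[a2, a3]`, and 1 at the apex. Zero-width segments
#' return 1 at the point itself.
#'
#' @param x a `"tfn"` object.
#' @param value numeric vector of points to evaluate.
#' @return Membership degrees in `[0, 1]`, same length as `value`.
#' @examples
#' membership(tfn(0, 1, 2), c(0.5, 1, 3)) # 0.5, 1, 0
#' @export
membership <- function(x, value) {
  x <- as_tfn(x)
  a1 <- x[["a1"]]; a2 <- x[["a2"]]; a3 <- x[["a3"]]
  vapply(value, function(v) {
    if (!is.finite(v)) return(0)
    if (v < a1 || v > a3) return(0)
    if (v == a2) return(1)
    if (v < a2) {
      # a2 > a1 here, else v == a2 above or v < a1
      (v - a1) / (a2 - a1)
    } else {
      if (a3 == a2) 1 else (a3 - v) / (a3 - a2)
    }
  }, numeric(1))
}

# ---- alpha-cut intervals ----------------------------------------------------

#' Construct an alpha-cut interval
#'
#' The unit of fuzzy arithmetic: a closed interval `[lower, upper]` carrying
#' the confidence level `alpha` at which it was cut.
#'
#' @param lower,upper interval endpoints, `lower <= upper`.
#' @param alpha confidence level in `[0, 1]`.
#' @return An object of class `"fuzzy_interval"`.
#' @export
fuzzy_interval <- function(lower, upper, alpha = NA_real_) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) {
    stop("alpha must lie in [0, 1]; got ", alpha, call. = FALSE)
  }
  if (lower > upper) {
    stop("interval endpoints out of order: lower ", lower, " > upper ", upper,
         call. = FALSE)
  }
  structure(c(lower = lower, upper = upper),
            alpha = as.numeric(alpha), class = "fuzzy_interval")
}

#' @export
print.fuzzy_interval <- function(x, ...) {
  cat(sprintf("<interval> [%g, %g] (alpha = %s)\n",
              x[["lower"]], x[["upper"]], format(attr(x, "alpha"))))
  invisible(x)
}

#' Interval endpoint accessors
#' @param x a `"fuzzy_interval"`.
#' @return The endpoint or confidence level.
#' @export
interval_lower <- function(x) unname(x[["lower"]])

#' @rdname interval_lower
#' @export
interval_upper <- function(x) unname(x[["upper"]])

#' @rdname interval_lower
#' @export
interval_alpha <- function(x) attr(x, "alpha")

#' Cut a TFN at confidence level alpha
#'
#' The alpha-cut of a TFN is the interval of values with membership at least
#' `alpha`: `[(a2 - a1) * alpha + a1, a3 - (a3 - a2) * alpha]`. Cuts nest as
#' alpha grows; the cut at 1 is the crisp mode and the cut at 0 is the full
#' support.
#'
#' @param x a `"tfn"` object.
#' @param alpha confidence level in `[0, 1]` (0.9 is the conventional choice).
#' @return A `"fuzzy_interval"`.
#' @examples
#' alpha_cut(tfn(0, 1, 2), 0.9) # [0.9, 1.1]
#' @export
alpha_cut <- function(x, alpha = 0.9) {
  x <- as_tfn(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  }
  lo <- (x[["a2"]] - x[["a1"]]) * alpha + x[["a1"]]
  hi <- x[["a3"]] - (x[["a3"]] - x[["a2"]]) * alpha
  if (lo > hi) {
    # both endpoints converge on a2; rounding can cross them by one ulp
    lo <- hi <- (lo + hi) / 2
  }
  fuzzy_interval(lo, hi, alpha)
}

check_alpha_match <- function(a, b) {
  aa <- attr(a, "alpha"); ab <- attr(b, "alpha")
  if (!is.na(aa) && !is.na(ab) && aa != ab) {
    stop("cannot combine intervals cut at different alpha (",
         aa, " vs ", ab, ")", call. = FALSE)
  }
  if (is.na(aa)) ab else aa
}

check_nonneg_operand <- function(x, what) {
  if (interval_lower(x) < 0) {
    stop(what, " requires non-negative interval operands; got lower endpoint ",
         interval_lower(x), call. = FALSE)
  }
}

#' Interval arithmetic on alpha-cuts
#'
#' Endpointwise fuzzy interval algebra for non-negative operands:
#' addition `[l1 + l2, u1 + u2]`, multiplication `[l1 * l2, u1 * u2]`, and
#' division `[l1 / u2, u1 / l2]`. Both operands must carry the same alpha.
#' The product and quotient formulas are exact only for non-negative
#' intervals, which is all this model needs (concentrations, rates, body
#' weights); negative endpoints are rejected rather than silently mishandled.
#'
#' @param a,b `"fuzzy_interval"` objects with matching alpha.
#' @return A `"fuzzy_interval"` with the shared alpha.
#' @examples
#' interval_add(fuzzy_interval(1, 2), fuzzy_interval(3, 5)) # [4, 7]
#' interval_div(fuzzy_interval(2, 4), fuzzy_interval(1, 2)) # [1, 4]
#' @export
interval_add <- function(a, b) {
  alpha <- check_alpha_match(a, b)
  fuzzy_interval(interval_lower(a) + interval_lower(b),
                 interval_upper(a) + interval_upper(b), alpha)
}

#' @rdname interval_add
#' @export
interval_mul <- function(a, b) {
  alpha <- check_alpha_match(a, b)
  check_nonneg_operand(a, "interval multiplication")
  check_nonneg_operand(b, "interval multiplication")
  fuzzy_interval(interval_lower(a) * interval_lower(b),
                 interval_upper(a) * interval_upper(b), alpha)
}

#' @rdname interval_add
#' @export
interval_div <- function(a, b) {
  alpha <- check_alpha_match(a, b)
  check_nonneg_operand(a, "interval division")
  if (interval_lower(b) <= 0) {
    stop("interval division requires a strictly positive divisor; got lower ",
         "endpoint ", interval_lower(b), call. = FALSE)
  }
  fuzzy_interval(interval_lower(a) / interval_upper(b),
                 interval_upper(a) / interval_lower(b), alpha)
}

#' Scale an interval by a non-negative constant
#'
#' @param k non-negative scalar.
#' @param a a `"fuzzy_interval"`.
#' @return `[k * lower, k * upper]` at the same alpha.
#' @examples
#' interval_scale(2, fuzzy_interval(1, 3)) # [2, 6]
#' @export
interval_scale <- function(k, a) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (is.na(k) || k < 0) {
    stop("scaling constant must be non-negative; got ", k, call. = FALSE)
  }
  fuzzy_interval(k * interval_lower(a), k * interval_upper(a),
                 attr(a, "alpha"))
}
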