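#' Metals covered by the model
#'
#' The seven toxic metals tracked in the road-dust workflow, in canonical
#' order.
#'
#' @return Character vector of metal symbols.
#' @export
dust_metals <- function() c("Cd", "Ni", "As", "Pb", "Zn", "Cu", "Cr")

#' @rdname dust_metals
#' @export
dust_seasons <- function() c("winter", "spring", "summer", "autumn")

ct_col <- function(metal) paste0("ct_", tolower(metal))
cdba_col <- function(metal) paste0("cdba_", tolower(metal))

#' Construct a validated dust-sample table
#'
#' One row per site x season x replicate, with per-metal total (`ct_<metal>`)
#' and bioaccessible (`cdba_<metal>`) concentrations in mg/kg. Validation
#' enforces positive totals and `0 <= CDBA <= CT` for every metal, and
#' normalizes season labels (case-insensitively; "fall" is accepted for
#' autumn).
#'
#' @param df a data frame with columns `site`, `season`, `replicate`, then
#'   `ct_cd`, `cdba_cd`, ... for each metal in [dust_metals()].
#' @param metals metals expected in the table.
#' @return The validated data frame with class `"dust_samples"`.
#' @export
dust_samples <- function(df, metals = dust_metals()) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stop("sample table is empty", call. = FALSE)
  needed <- c("site", "season", "replicate",
              ct_col(metals), cdba_col(metals))
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("sample table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$season <- normalize_season(df$season)
  for (m in metals) {
    ct <- df[[ct_col(m)]]
    ba <- df[[cdba_col(m)]]
    for (col in list(c(ct_col(m), "ct"), c(cdba_col(m), "cdba"))) {
      v <- df[[col[[1L]]]]
      if (!is.numeric(v) || anyNA(v)) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
        stop("non-numeric value in column '", col[[1L]], "' at row ",
             ifelse(is.na(bad), 1L, bad), call. = FALSE)
      }
    }
    if (any(ct <= 0)) {
      stop("non-positive total concentration in column '", ct_col(m),
           "' at row ", which(ct <= 0)[1L], call. = FALSE)
    }
    if (any(ba < 0)) {
      stop("negative bioaccessible concentration in column '", cdba_col(m),
           "' at row ", which(ba < 0)[1L], call. = FALSE)
    }
    if (any(ba > ct)) {
      stop("bioaccessible exceeds total concentration (", cdba_col(m), " > ",
           ct_col(m), ") at row ", which(ba > ct)[1L],
           "; measurement inconsistency", call. = FALSE)
    }
  }
  df$site <- as.character(df$site)
  class(df) <- c("dust_samples", "data.frame")
  attr(df, "metals") <- metals
  df
}

normalize_season <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x == "fall"] <- "autumn"
  bad <- which(!x %in% dust_seasons())
  if (length(bad) > 0L) {
    stop("unknown season label '", x[bad[1L]], "' at row ", bad[1L],
         "; expected one of ", paste(dust_seasons(), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Reshape a sample table to long format
#'
#' @param samples a `"dust_samples"` table.
#' @return A data frame with columns `site`, `season`, `replicate`, `metal`,
#'   `ct`, `cdba`.
#' @export
samples_long <- function(samples) {
  metals <- attr(samples, "metals") %||% dust_metals()
  out <- do.call(rbind, lapply(metals, function(m) {
    data.frame(site = samples$site, season = samples$season,
               replicate = samples$replicate, metal = m,
               ct = samples[[ct_col(m)]], cdba = samples[[cdba_col(m)]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
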