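#' Bioaccessibility rate of a metal in dust
#'
#' The bioaccessibility rate RD is the fraction of a metal's total
#' concentration that dissolves under simulated gastric conditions (SBET)
#' and is therefore available for absorption: `RD = CDBA / CT`. Vectorized
#' over paired measurements.
#'
#' @param ct total concentration (mg/kg), strictly positive.
#' @param cdba bioaccessible concentration (mg/kg), `0 <= cdba <= ct`.
#' @return RD as a fraction in `[0, 1]`.
#' @examples
#' bioaccessibility_rate(100, 42.32) # 0.4232
#' @export
bioaccessibility_rate <- function(ct, cdba) {
  stopifnot(is.numeric(ct), is.numeric(cdba), length(ct) == length(cdba))
  if (any(ct <= 0)) {
    stop("total concentration must be strictly positive; got ",
         min(ct), call. = FALSE)
  }
  if (any(cdba < 0)) {
    stop("bioaccessible concentration must be non-negative", call. = FALSE)
  }
  if (any(cdba > ct)) {
    stop("bioaccessible concentration exceeds total (CDBA > CT): ",
         "measurement inconsistency", call. = FALSE)
  }
  cdba / ct
}

#' Mean bioaccessibility rate per metal
#'
#' Computes each sample's RD, averages per metal, and reports the metals in
#' descending order of mean rate. Metals absent from the table are omitted
#' with a warning.
#'
#' @param samples a `"dust_samples"` table.
#' @param metals metals to summarize (default all present).
#' @return A data frame with columns `metal`, `n`, `mean_rd`, sorted by
#'   descending `mean_rd`.
#' @export
mean_rd_by_metal <- function(samples, metals = dust_metals()) {
  long <- samples_long(samples)
  present <- intersect(metals, unique(long$metal))
  absent <- setdiff(metals, present)
  if (length(absent) > 0L) {
    warning("no records for metal(s): ", paste(absent, collapse = ", "),
            "; omitted", call. = FALSE)
  }
  rows <- lapply(present, function(m) {
    sub <- long[long$metal == m, , drop = FALSE]
    rd <- bioaccessibility_rate(sub$ct, sub$cdba)
    data.frame(metal = m, n = nrow(sub), mean_rd = mean(rd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_rd), , drop = FALSE]
  rownames(out) <- NULL
  out
}
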