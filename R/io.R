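#' Read and write dust-sample tables
#'
#' Comma-delimited text with a header row: `site`, `season`, `replicate`,
#' then `ct_<metal>` and `cdba_<metal>` columns (lower-case metal symbols),
#' concentrations in mg/kg. Reading validates every record — unknown season
#' labels, missing columns, non-numeric cells and `CDBA > CT` are rejected
#' with row/column coordinates.
#'
#' @param path file path.
#' @param samples a `"dust_samples"` table.
#' @param metals metals expected in the file.
#' @return `read_samples()` returns a `"dust_samples"` table;
#'   `write_samples()` returns `path` invisibly.
#' @export
read_samples <- function(path, metals = dust_metals()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse sample table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) stop("sample table '", path, "' is empty", call. = FALSE)
  dust_samples(df, metals = metals)
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "dust_samples"))
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Read screening values from YAML
#'
#' @param path YAML file mapping metal symbol to screening value (mg/kg).
#' @return Named numeric vector.
#' @export
read_screening <- function(path) {
  v <- unlist(yaml::read_yaml(path))
  if (is.null(names(v)) || !is.numeric(v)) {
    stop("screening YAML must map metal symbols to numbers", call. = FALSE)
  }
  v
}

#' Write a run manifest for provenance
#'
#' Records the inputs, resolved configuration hashes, seed, alpha, grouping
#' and package version of a pipeline run as plain text, so a run can be
#' reproduced bit-for-bit for its deterministic stages.
#'
#' @param dir output directory (created if needed).
#' @param inputs named character vector of input file paths (hashed if they
#'   exist).
#' @param seed integer seed used, if any.
#' @param alpha confidence level used.
#' @param grouping grouping choice used.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, inputs = character(), seed = NA_integer_,
                               alpha = NA_real_, grouping = NA_character_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.txt")
  lines <- c(
    paste0("package: fuzzydust ",
           as.character(utils::packageVersion("fuzzydust"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed: ", seed),
    paste0("alpha: ", alpha),
    paste0("grouping: ", grouping)
  )
  for (nm in names(inputs)) {
    p <- inputs[[nm]]
    h <- if (file.exists(p)) unname(tools::md5sum(p)) else "missing"
    lines <- c(lines, paste0("input ", nm, ": ", p, " md5=", h))
  }
  writeLines(lines, path)
  invisible(path)
}
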