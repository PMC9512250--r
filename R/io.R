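#' Write and read prediction-curve summaries as CSV
#'
#' The summary CSV has columns `distance`, `mean`, `q25`, `q75`; the
#' raw-sample CSV is long format with columns `distance`, `rep`,
#' `y_pred`.  Values round-trip exactly (full double precision).
#'
#' @param curve A `pps_curve` (or, for [write_curve_csv()], a summary
#'   data frame with those columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  s <- .curve_summary(curve)
  if (!all(c("q25", "q75") %in% names(s))) {
    stop("curve summary must contain `q25` and `q75` columns",
         call. = FALSE)
  }
  utils::write.csv(format(s, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
write_samples_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pps_curve"))
  long <- data.frame(
    distance = rep(curve$config$distances, each = nrow(curve$samples)),
    rep = rep(seq_len(nrow(curve$samples)), ncol(curve$samples)),
    y_pred = as.vector(curve$samples)
  )
  utils::write.csv(format(long, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("distance", "mean", "q25", "q75")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("malformed curve CSV: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("malformed curve CSV: non-numeric value in `%s` (row %d)",
                   col, bad), call. = FALSE)
    }
  }
  df
}

#' Serialise boundary metrics of a curve to JSON
#'
#' Computes the threshold-rule boundary, and where the curve admits them
#' the sigmoid-midpoint boundary and the central slope, and writes them
#' as a JSON object.
#'
#' @param curve A `pps_curve` or summary data frame.
#' @param path Output JSON path; when `NULL` the metrics list is returned
#'   without writing.
#' @param threshold Threshold for [boundary_threshold()].
#' @return The metrics list, invisibly when written.
#' @export
write_metrics_json <- function(curve, path = NULL, threshold = 0.01) {
  metrics <- list(
    boundary_threshold = suppressWarnings(
      boundary_threshold(curve, threshold)),
    threshold = threshold
  )
  sig <- tryCatch(boundary_sigmoid(curve), error = function(e) NULL)
  if (!is.null(sig)) {
    metrics$boundary_sigmoid <- sig$boundary
    metrics$sigmoid_amplitude <- sig$amplitude
    metrics$sigmoid_steepness <- sig$steepness
  }
  slope <- tryCatch(boundary_slope(curve), error = function(e) NULL)
  if (!is.null(slope)) metrics$slope <- slope
  if (is.null(path)) return(metrics)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(metrics)
}

#' Run manifest for reproducibility
#'
#' Records the preset or configuration label, seed, package version,
#' timestamp and output paths of a simulation run, so that every emitted
#' result file is traceable to the seed that produced it.
#'
#' @param config A [sweep_config()] (its label and seed are recorded).
#' @param outputs Named character vector or list of output paths.
#' @param preset Optional preset name.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, outputs = list(), preset = NULL) {
  stopifnot(inherits(config, "sweep_config"))
  structure(
    list(
      preset = preset,
      label = config$label,
      seed = config$seed,
      n_reps = config$n_reps,
      distances = range(config$distances),
      version = as.character(utils::packageVersion("ppsimpact")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.list(outputs)
    ),
    class = "run_manifest"
  )
}

#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @rdname run_manifest
#' @export
write_manifest_json <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
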