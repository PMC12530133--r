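#' Read a paired sample from a delimited file
#'
#' Reads a comma-delimited file with a header row and assembles the named
#' columns into a [paired_sample()]. Rows containing missing values in the
#' selected columns are dropped with a reported count; non-numeric cells and
#' unknown columns raise typed errors.
#'
#' @param path Path to a CSV file (header mandatory, `.` decimal, UTF-8).
#' @param x_cols,y_cols Character vectors of column names for the X and Y
#'   blocks.
#' @return A [paired_sample()].
#' @export
read_pairs <- function(path, x_cols, y_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  missing_cols <- setdiff(c(x_cols, y_cols), names(df))
  if (length(missing_cols)) {
    stop(sprintf("unknown column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  sub <- df[, c(x_cols, y_cols), drop = FALSE]
  bad <- !vapply(sub, is.numeric, TRUE)
  if (any(bad)) {
    stop(sprintf("non-numeric column(s): %s",
                 paste(names(sub)[bad], collapse = ", ")), call. = FALSE)
  }
  complete <- stats::complete.cases(sub)
  if (!all(complete)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!complete)))
    sub <- sub[complete, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 complete rows", call. = FALSE)
  paired_sample(as.matrix(sub[, x_cols, drop = FALSE]),
                as.matrix(sub[, y_cols, drop = FALSE]))
}

#' Write an analysis result to JSON or CSV
#'
#' Serializes a `clam_result`, `assoc_value`, cluster result or simulation
#' study to disk losslessly (full double precision). JSON embeds every
#' parameter of the run; the CSV format is available for the tabular parts
#' (study grids, cluster summaries).
#'
#' @param result A `clam_result`, `assoc_value`, `clam_clusters` or
#'   `sim_study` object (or any list of numeric fields).
#' @param path Output path; parent directory must exist.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir), call. = FALSE)
  if (format == "json") {
    jsonlite::write_json(serialize_result(result), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    tab <- if (inherits(result, "sim_study")) result$cells
           else if (inherits(result, "clam_result")) result$summaries
           else if (is.data.frame(result)) result
           else stop("no tabular representation for this object", call. = FALSE)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Re-read a JSON result written by [write_result()]
#'
#' @param path Path to the JSON file.
#' @return A named list mirroring the serialized fields.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

serialize_result <- function(x) {
  if (inherits(x, "clam_result")) {
    list(schema = "clam_result/1",
         overall = x$overall,
         clusters = x$summaries,
         measure = x$measure,
         clustering = list(algorithm = x$clustering$algorithm,
                           K = x$clustering$K,
                           params = drop_null(x$clustering$params)),
         n_used = x$n_used, n_noise = x$n_noise, n_warnings = x$n_warnings)
  } else if (inherits(x, "assoc_value")) {
    list(schema = "assoc_value/1", measure = x$measure,
         direction = x$direction, value = x$value, n = x$n,
         params = drop_null(x$params))
  } else if (inherits(x, "clam_clusters")) {
    list(schema = "clam_clusters/1", algorithm = x$algorithm, K = x$K,
         labels = x$labels, sizes = x$sizes, params = drop_null(x$params),
         eigenvalues = x$eigenvalues)
  } else if (inherits(x, "sim_study")) {
    list(schema = "sim_study/1", which = x$which, reps = x$reps,
         seed = x$seed, cells = x$cells, params = drop_null(x$params))
  } else {
    x
  }
}

drop_null <- function(l) l[!vapply(l, is.null, TRUE)]

#' Write a sample to CSV
#'
#' Writes `x1..xp, y1..yq` columns (plus `label` for labeled samples) with a
#' header, the format [read_pairs()] reads back.
#'
#' @param sample A [paired_sample()] or [labeled_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "paired_sample"))
  df <- as.data.frame(joint_points(sample))
  names(df) <- c(paste0("x", seq_len(ncol(sample$x))),
                 paste0("y", seq_len(ncol(sample$y))))
  if (!is.null(sample$true_labels)) df$label <- sample$true_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
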