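#' Construct a flow cytometry sample
#'
#' A `flow_sample` holds one subject's event-by-marker fluorescence matrix
#' together with the marker (channel) names. It is the input type of every
#' clustering function in the package.
#'
#' @param values numeric matrix, rows = cells (events), columns = markers.
#'   All entries must be finite; non-finite values are a hard error because
#'   silently dropping events would change every downstream statistic.
#' @param marker_names character vector of column labels; defaults to the
#'   matrix column names, or `"M1"..."Mm"` when absent.
#' @param sample_id identifier for the sample.
#' @param subject_id optional subject identifier (used in cohort analyses).
#'
#' @return An object of class `flow_sample` with fields `values`,
#'   `marker_names`, `sample_id` and `subject_id`.
#' @export
#' @examples
#' fs <- flow_sample(matrix(rnorm(20), 10, 2), c("CD3", "CD19"))
#' n_cells(fs)
flow_sample <- function(values, marker_names = NULL, sample_id = "sample",
                        subject_id = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x markers)")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must have at least one cell and one marker")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at cell %d, marker %d", bad[1L], bad[2L]))
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values)
    if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(values)))
  }
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values)) {
    stop("length of `marker_names` must equal the number of columns")
  }
  dimnames(values) <- list(NULL, marker_names)
  structure(
    list(values = values, marker_names = marker_names,
         sample_id = sample_id, subject_id = subject_id),
    class = "flow_sample"
  )
}

#' @rdname flow_sample
#' @param x a `flow_sample`.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname flow_sample
#' @export
n_markers <- function(x) ncol(x$values)

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("flow_sample '%s': %d cells x %d markers (%s)\n",
              x$sample_id, n_cells(x), n_markers(x),
              paste(x$marker_names, collapse = ", ")))
  invisible(x)
}

#' Read a numeric CSV matrix as a flow sample
#'
#' Reads a rectangular numeric CSV (rows = cells, columns = markers).
#' With `has_header = TRUE` the first row supplies the marker names;
#' headerless files get names `"M1"..."Mm"`.
#'
#' @param path path to the CSV file.
#' @param has_header logical; does the first row hold marker names?
#' @param sample_id sample identifier; defaults to the file name.
#' @param subject_id optional subject identifier.
#' @return A [flow_sample].
#' @export
read_csv_matrix <- function(path, has_header = TRUE,
                            sample_id = basename(path), subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- tryCatch(utils::count.fields(path, sep = ","),
                 warning = function(w) stop(sprintf("cannot parse CSV: %s", path)))
  if (length(nf) == 0L) stop(sprintf("empty CSV file: %s", path))
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]))
  }
  df <- utils::read.csv(path, header = has_header, colClasses = "character",
                        check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("CSV has a header but no data rows: %s", path))
  mat <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                   df[[j]][i], i + as.integer(has_header), j, path))
    }
    mat[, j] <- v
  }
  nm <- if (has_header) names(df) else NULL
  flow_sample(mat, marker_names = nm, sample_id = sample_id,
              subject_id = subject_id)
}

#' Write a flow sample to CSV
#'
#' @param sample a [flow_sample].
#' @param path output path; a header row of marker names is written.
#' @return `path`, invisibly.
#' @export
write_csv_matrix <- function(sample, path) {
  stopifnot(inherits(sample, "flow_sample"))
  utils::write.csv(as.data.frame(sample$values), path, row.names = FALSE)
  invisible(path)
}

#' Arcsinh-transform marker intensities
#'
#' Replaces every intensity v by `asinh(v / cofactor)`. No transform is
#' applied by default anywhere in the package; this is an opt-in
#' preprocessing step for users whose data need variance compression.
#'
#' @param sample a [flow_sample].
#' @param cofactor positive scaling constant (5 is customary for standard
#'   flow cytometry, 150 for older instruments).
#' @return A transformed [flow_sample] with unchanged marker names.
#' @export
transform_arcsinh <- function(sample, cofactor = 5) {
  stopifnot(inherits(sample, "flow_sample"))
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("`cofactor` must be a positive number")
  }
  flow_sample(asinh(sample$values / cofactor),
              marker_names = sample$marker_names,
              sample_id = sample$sample_id, subject_id = sample$subject_id)
}

#' Write per-cell population labels to CSV
#'
#' Writes a two-column CSV `cell_index,label` (1-based indices).
#'
#' @param labels integer vector of population labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(cell_index = seq_along(labels),
                              label = as.integer(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-cell population labels from CSV
#'
#' @param path CSV written by [write_labels_csv()] (or any CSV whose last
#'   column holds integer labels).
#' @return Integer label vector.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  as.integer(df[[ncol(df)]])
}
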