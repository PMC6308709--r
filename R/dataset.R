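#' Construct a clustering dataset
#'
#' A `pam_dataset` wraps an N x d matrix of real-valued attributes together
#' with per-record activity flags. Inactive records exist only to pad a
#' dataset to a length divisible by the number of processing elements: they
#' contribute nothing to any distance sum, are never medoid candidates, and
#' receive an `NA` cluster tag.
#'
#' @param data A data frame, tibble or numeric matrix; one row per point,
#'   one numeric column per attribute. Non-numeric columns are rejected.
#' @param active Logical vector of length `nrow(data)`; `FALSE` marks
#'   padding records. Defaults to all active.
#'
#' @return An object of class `pam_dataset`: a list with elements `points`
#'   (numeric matrix), `active` (logical), `n` (total records), `n_active`,
#'   and `d`.
#' @export
#' @examples
#' ds <- as_pam_dataset(data.frame(x = c(0, 1, 2), y = c(0, 0, 1)))
#' ds$n
as_pam_dataset <- function(data, active = NULL) {
  if (inherits(data, "pam_dataset")) return(data)
  if (is.data.frame(data)) {
    numeric_cols <- vapply(data, is.numeric, logical(1))
    if (!all(numeric_cols)) {
      abort(paste0("all columns must be numeric; offending: ",
                   paste(names(data)[!numeric_cols], collapse = ", ")))
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix or an all-numeric data frame")
  }
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 1L) abort("need at least one point and one attribute")
  if (!all(is.finite(data))) abort("all attribute values must be finite")
  if (is.null(active)) active <- rep(TRUE, nrow(data))
  stopifnot(is.logical(active), length(active) == nrow(data))
  if (!any(active)) abort("at least one record must be active")
  structure(
    list(points = data, active = active, n = nrow(data),
         n_active = sum(active), d = ncol(data)),
    class = "pam_dataset"
  )
}

#' @export
print.pam_dataset <- function(x, ...) {
  cat(sprintf("<pam_dataset> %d points (%d active) x %d attributes\n",
              x$n, x$n_active, x$d))
  invisible(x)
}

validate_medoids <- function(ds, medoids) {
  medoids <- as.integer(medoids)
  if (length(medoids) < 1L) abort("medoid set must not be empty")
  if (anyDuplicated(medoids)) abort("medoid indices must be distinct")
  if (any(medoids < 1L | medoids > ds$n)) abort("medoid index out of range")
  if (!all(ds$active[medoids])) abort("medoids must reference active records")
  if (length(medoids) > ds$n_active) abort("more medoids than active records")
  medoids
}

#' Read and write point sets as delimited text
#'
#' Point sets are exchanged as comma- or tab-delimited text, one row per
#' point, one column per attribute, with an optional header line. The
#' delimiter is taken from the file extension (`.tsv`/`.txt` tab, otherwise
#' comma) unless given, and a header is detected automatically when
#' `col_names = NULL`.
#'
#' @param path File path.
#' @param col_names `TRUE` (first line is a header), `FALSE`, or `NULL` to
#'   detect: a first line with any non-numeric field is treated as a header.
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @return `read_points()` returns a tibble of numeric columns.
#' @export
read_points <- function(path, col_names = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  if (is.null(col_names)) {
    first <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
    col_names <- anyNA(suppressWarnings(as.numeric(first)))
  }
  out <- readr::read_delim(path, delim = delim, col_names = col_names,
                           col_types = readr::cols(.default = readr::col_double()),
                           progress = FALSE)
  as_tibble(out)
}

#' @param points Data frame or matrix of points to write.
#' @rdname read_points
#' @export
write_points <- function(points, path, delim = NULL, col_names = TRUE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(as.data.frame(points), path, delim = delim,
                     col_names = isTRUE(col_names))
  invisible(path)
}

#' Read and write cluster tags
#'
#' Tags are written as a single-column text file aligned to the input row
#' order; padding records appear as `NA`.
#'
#' @param tags Integer vector of cluster tags.
#' @param path File path.
#' @export
write_tags <- function(tags, path) {
  writeLines(as.character(tags), path)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  as.integer(readLines(path))
}
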