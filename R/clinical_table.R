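#' Clinical table container
#'
#' A `clinical_table` holds an n x d numeric feature matrix, a logical
#' missingness mask of the same shape, feature names, and a binary outcome
#' vector (1 = presence of heart disease, 0 = absence). It is the common
#' currency of the preprocessing, feature-selection and evaluation steps.
#'
#' @param values numeric n x d matrix; cells flagged in `missing_mask` may
#'   be `NA`.
#' @param labels integer/numeric vector of length n with values in {0, 1}.
#' @param missing_mask logical n x d matrix; defaults to `is.na(values)`.
#' @param feature_names character vector of length d; defaults to the
#'   column names of `values`, or `V1..Vd`.
#'
#' @return An object of class `clinical_table` with elements `values`,
#'   `missing_mask`, `feature_names`, `labels`, `n`, `d`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' ct <- clinical_table(x, labels = c(0, 1, 0, 1, 1))
#' ct$n; ct$d
clinical_table <- function(values, labels, missing_mask = NULL,
                           feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(values), dim(missing_mask)))
    stop("`values` and `missing_mask` must have identical dimensions")
  if (length(labels) != nrow(values))
    stop("`labels` must have length nrow(values)")
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must be binary (0 = absence, 1 = presence)")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names))
      feature_names <- paste0("V", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values))
    stop("`feature_names` must have length ncol(values)")
  colnames(values) <- feature_names
  structure(
    list(values = values,
         missing_mask = missing_mask,
         feature_names = feature_names,
         labels = as.integer(labels),
         n = nrow(values), d = ncol(values)),
    class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("clinical_table: %d samples x %d features\n", x$n, x$d))
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  labels:   %d presence / %d absence\n",
              sum(x$labels == 1), sum(x$labels == 0)))
  cat(sprintf("  missing:  %d cells (%.2f%%)\n", sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

# canonical 13 UCI Cleveland predictor names
cleveland_feature_names <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
    "thalach", "exang", "oldpeak", "slope", "ca", "thal")
}

#' Read a Cleveland-dialect clinical CSV
#'
#' Reads a comma-separated file in the UCI Cleveland heart-disease dialect:
#' 14 columns (13 predictors plus an integer disease-stage column), with
#' `"?"` marking missing cells. The stage column is collapsed to a binary
#' label: 1 when the stage is greater than 0, else 0.
#'
#' @param path path to the CSV file (no header).
#' @param n_features expected number of predictor columns; 13 for the
#'   canonical dialect. `NULL` infers the width from the first row (used
#'   for synthetic tables of other widths).
#' @param feature_names names for the predictor columns; defaults to the
#'   canonical 13 names when they fit the width.
#' @return a [clinical_table()] with `d = n_features` and the missingness
#'   mask set exactly where `"?"` appeared.
#' @export
read_cleveland <- function(path, n_features = 13L, feature_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  widths <- utils::count.fields(path, sep = ",", quote = "")
  expect <- if (is.null(n_features)) widths[1] else n_features + 1L
  bad <- which(widths != expect)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad[1], expect, widths[bad[1]]))
  d <- expect - 1L
  if (is.null(feature_names))
    feature_names <- if (d == 13L) cleveland_feature_names()
                     else paste0("V", seq_len(d))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE, quote = "")
  raw <- as.matrix(raw)
  mask <- raw == "?"
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad_cell <- which(is.na(num) & !mask, arr.ind = TRUE)
  if (nrow(bad_cell))
    stop(sprintf("parse error at line %d, column %d: non-numeric value '%s'",
                 bad_cell[1, 1], bad_cell[1, 2],
                 raw[bad_cell[1, 1], bad_cell[1, 2]]))
  stage <- num[, d + 1L]
  if (any(mask[, d + 1L]))
    stop("missing values are not allowed in the stage column")
  clinical_table(num[, seq_len(d), drop = FALSE],
                 labels = as.integer(stage > 0),
                 missing_mask = mask[, seq_len(d), drop = FALSE],
                 feature_names = feature_names)
}

#' Write a clinical table in the Cleveland CSV dialect
#'
#' Masked cells are written as `"?"`; the binary label is appended as the
#' final (stage) column, so [read_cleveland()] round-trips the file.
#'
#' @param table a [clinical_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cleveland <- function(table, path) {
  stopifnot(inherits(table, "clinical_table"))
  chr <- matrix(format_cell(table$values), table$n, table$d)
  chr[table$missing_mask] <- "?"
  lines <- apply(cbind(chr, as.character(table$labels)), 1L,
                 paste, collapse = ",")
  writeLines(lines, path)
  invisible(path)
}

format_cell <- function(x) {
  out <- format(x, trim = TRUE, digits = 15, scientific = FALSE)
  out[is.na(x)] <- "?"
  out
}
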