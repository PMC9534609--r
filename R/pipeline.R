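#' Preprocess a Cleveland-dialect CSV file
#'
#' Reads, imputes, repairs noise, normalizes, and writes the processed
#' table as CSV together with a JSON sidecar of the preprocessing
#' parameters (imputation statistics, replaced-cell count, normalization
#' parameters).
#'
#' @param input path to a Cleveland-dialect CSV (any predictor width; the
#'   last column is the disease stage).
#' @param output path for the processed CSV (feature columns plus a final
#'   `label` column); the sidecar is written to `<output>.json`.
#' @param cfg a [preprocess_config()].
#' @return the processed [clinical_table()], invisibly.
#' @export
run_preprocess <- function(input, output, cfg = preprocess_config()) {
  raw <- read_cleveland(input, n_features = NULL)
  imputed <- impute_missing(raw, cfg)
  repaired <- remove_noise_studentized(imputed, cfg)
  processed <- normalize_table(repaired, cfg)
  out <- data.frame(processed$values, label = processed$labels)
  names(out) <- c(processed$feature_names, "label")
  utils::write.csv(out, output, row.names = FALSE, quote = FALSE)
  params <- attr(processed, "norm_params")
  sidecar <- list(
    missing_strategy = cfg$missing_strategy,
    studentized_threshold = cfg$studentized_threshold,
    n_noise_cells_replaced = attr(repaired, "n_replaced"),
    normalization = params)
  jsonlite::write_json(sidecar, paste0(output, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(processed)
}

#' Write a selected-feature result as JSON
#'
#' @param result list returned by [select_features()].
#' @param path output JSON path; the cost trace is written alongside as
#'   `<path basename>_trace.csv` with columns `iteration`, `best_cost`.
#' @return `path`, invisibly.
#' @export
write_subset_json <- function(result, path) {
  trace_path <- paste0(sub("\\.json$", "", path), "_trace.csv")
  utils::write.csv(
    data.frame(iteration = seq_along(result$trace) - 1L,
               best_cost = result$trace),
    trace_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(indices = result$subset$indices,
         mask = as.integer(result$subset$mask),
         size = result$subset$size,
         cost = result$cost,
         trace = trace_path),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a processed-table CSV written by [run_preprocess()]
#' @param path CSV with feature columns and a final `label` column.
#' @return a [clinical_table()].
#' @export
read_processed_csv <- function(path) {
  df <- utils::read.csv(path)
  clinical_table(as.matrix(df[, -ncol(df), drop = FALSE]),
                 labels = df[[ncol(df)]])
}
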