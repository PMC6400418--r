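# CSV round-tripping for datasets and fit results. Dialect: UTF-8, comma
# separated, header row, '.' decimal; angles in degrees-on-the-circle with 4
# decimals at the I/O boundary.

.DATASET_COLS <- c("participant", "experiment", "condition", "set_size",
                   "block", "item_angles", "target_index", "landmark_deg",
                   "shift_deg", "response_deg")

#' Read and write trial datasets as CSV
#'
#' One row per trial with columns `participant`, `experiment`, `condition`,
#' `set_size`, `block`, `item_angles` (semicolon-joined item angles in
#' degrees), `target_index` (0-based), `landmark_deg` (empty when no
#' landmark), `shift_deg`, `response_deg`. `read_dataset()` re-derives the
#' `target_deg` column from `item_angles[target_index + 1]` and restores trial
#' numbering, so a write/read round trip reproduces the dataset.
#'
#' @param data dataset data frame (design plus responses).
#' @param path file path.
#' @return `read_dataset()`: the dataset data frame; `write_dataset()`: the
#'   path, invisibly.
#' @export
write_dataset <- function(data, path) {
  missing <- setdiff(.DATASET_COLS, names(data))
  if (length(missing))
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "))
  out <- data[, .DATASET_COLS]
  for (col in c("landmark_deg", "shift_deg", "response_deg"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.4f", round(out[[col]], 4)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing <- setdiff(.DATASET_COLS, header)
  if (length(missing))
    stop("malformed dataset CSV, missing column(s): ",
         paste(missing, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(item_angles = "character",
                                        landmark_deg = "character"),
                         fileEncoding = "UTF-8")
  items <- strsplit(raw$item_angles, ";", fixed = TRUE)
  n_items <- lengths(items)
  bad <- which(n_items != raw$set_size | raw$target_index < 0 |
                 raw$target_index >= n_items)
  if (length(bad))
    stop("unparseable dataset rows (item list / target index mismatch): ",
         paste(utils::head(bad, 10), collapse = ", "))
  raw$landmark_deg <- suppressWarnings(
    as.numeric(ifelse(raw$landmark_deg == "", NA, raw$landmark_deg)))
  raw$target_deg <- vapply(seq_along(items), function(i)
    as.numeric(items[[i]][raw$target_index[i] + 1L]), numeric(1))
  raw$trial <- seq_len(nrow(raw))
  raw[, c("participant", "experiment", "condition", "set_size", "block",
          "trial", "item_angles", "target_index", "target_deg",
          "landmark_deg", "shift_deg", "response_deg")]
}

#' Write fit results to CSV
#'
#' One row per participant and variant, with slot names and values
#' semicolon-joined alongside the fit summary (log-likelihood, k, n, AICc).
#'
#' @param fits a named list of variants, each a list of `observer_fit` (as
#'   returned by [fit_cohort()]), or a single such list (variant `"model"`).
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  if (length(fits) && inherits(fits[[1]], "observer_fit"))
    fits <- list(model = fits)
  rows <- list()
  for (variant in names(fits)) {
    for (f in fits[[variant]]) {
      stopifnot(inherits(f, "observer_fit"))
      rows[[length(rows) + 1]] <- data.frame(
        participant = f$participant, variant = variant,
        slot_names = paste(names(f$values), collapse = ";"),
        slot_values = paste(sprintf("%.6g", f$values), collapse = ";"),
        loglik = f$loglik, k = f$k, n = f$n, aicc = f$aicc,
        n_starts = f$n_starts, converged = f$converged,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a binned summary to CSV
#'
#' @param summary a [binned_summary()] data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
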