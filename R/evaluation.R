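# Tolerance-banded position accuracy, classification efficiency, and
# the reproducible run pipeline.

#' Tolerance-banded position-prediction accuracy
#'
#' Shares of predictions whose absolute position error equals each band
#' b = 0, 1, ..., `max_band`, as percentages of n, plus the cumulative
#' shares within 3 and within 6 positions.
#'
#' @param predicted,actual Equal-length integer position vectors.
#' @param max_band Largest individual band reported.
#' @return An object of class `banded_accuracy`: `bands` (named
#'   percentages), `cum_0_3`, `cum_0_6`, `n`.
#' @export
banded_accuracy <- function(predicted, actual, max_band = 6L) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  n <- length(actual)
  if (n < 1) stop("need at least one pair", call. = FALSE)
  err <- abs(predicted - actual)
  bands <- vapply(0:max_band, function(b) 100 * sum(err == b) / n, numeric(1))
  names(bands) <- as.character(0:max_band)
  structure(list(bands = bands,
                 cum_0_3 = 100 * sum(err <= 3) / n,
                 cum_0_6 = 100 * sum(err <= 6) / n,
                 n = n), class = "banded_accuracy")
}

#' @export
print.banded_accuracy <- function(x, ...) {
  cat("<banded_accuracy> n=", x$n, "\n", sep = "")
  for (b in names(x$bands)) {
    cat("  error ", b, ": ", format_percent(x$bands[[b]]), "%\n", sep = "")
  }
  cat("  within 3: ", format_percent(x$cum_0_3), "%  within 6: ",
      format_percent(x$cum_0_6), "%\n", sep = "")
  invisible(x)
}

# Half-up rounding to 2 decimals for report display.
format_percent <- function(x) {
  sprintf("%.2f", floor(x * 100 + 0.5) / 100)
}

#' Classification accuracy index
#'
#' Correct classifications divided by all classifications.
#'
#' @param correct Count of correct classifications.
#' @param total Count of all classifications (>= 1).
#' @return Real in [0, 1].
#' @export
accuracy_index <- function(correct, total) {
  if (total < 1) stop("total must be >= 1", call. = FALSE)
  if (correct < 0 || correct > total) {
    stop("need 0 <= correct <= total", call. = FALSE)
  }
  correct / total
}

#' Efficiency of the "strong" group for podium finishers
#'
#' Among records whose actual finishing position is 1-3, the fraction
#' classified into the "strong" group.
#'
#' @param predicted_groups Factor/character of predicted groups.
#' @param actual_positions Integer actual positions, aligned.
#' @return Real in [0, 1].
#' @export
strong_group_efficiency <- function(predicted_groups, actual_positions) {
  if (length(predicted_groups) != length(actual_positions)) {
    stop("aligned sequences required", call. = FALSE)
  }
  top <- actual_positions <= 3
  if (!any(top)) stop("no records with actual position <= 3", call. = FALSE)
  mean(as.character(predicted_groups)[top] == "strong")
}

#' Confusion-based classification report
#'
#' @param predicted_groups,actual_groups Aligned factors/characters
#'   with values strong/medium/weak.
#' @return List: `confusion` (3x3 counts, predicted x actual),
#'   `efficiency` (trace/total), `n`.
#' @export
classification_report <- function(predicted_groups, actual_groups) {
  p <- factor(as.character(predicted_groups), levels = GROUP_LEVELS)
  a <- factor(as.character(actual_groups), levels = GROUP_LEVELS)
  cm <- table(predicted = p, actual = a)
  list(confusion = cm,
       efficiency = accuracy_index(sum(diag(cm)), sum(cm)),
       n = sum(cm))
}

pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$path)) {
    read_dataset(cfg$path)
  } else if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    if (!is.null(args$line_probs)) args$line_probs <- unlist(args$line_probs)
    if (!is.null(args$line_effects)) args$line_effects <- unlist(args$line_effects)
    if (!is.null(args$age_curve)) args$age_curve <- unlist(args$age_curve)
    if (!is.null(args$years)) args$years <- args$years[1]:args$years[length(args$years)]
    simulate_dataset(do.call(synthetic_config, args))$dataset
  } else {
    stop("config error: dataset.path or dataset.synthetic required", call. = FALSE)
  }
}

#' Run the full evaluation pipeline from a config file
#'
#' The YAML config names a dataset (a CSV path, or parameters for the
#' synthetic generator), a task (`position` or `group`), the
#' hidden-layer topologies to compare, training settings and the
#' cross-validation scheme. For every topology the pipeline encodes
#' features, builds targets, trains and evaluates under repeated
#' k-fold CV, and writes `report.csv` and `report.json` into
#' `out_dir`. Fully reproducible from config + seed.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Optional master-seed override.
#' @return Tibble with one row per topology and the mean CV metrics,
#'   invisibly returned alongside the per-topology reports in
#'   attribute `"reports"`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("dataset", "task", "topologies")) {
    if (is.null(cfg[[field]])) {
      stop("config error: missing field '", field, "'", call. = FALSE)
    }
  }
  task <- match.arg(cfg$task, c("position", "group"))
  dataset <- pipeline_dataset(cfg$dataset)
  tr_args <- cfg$training %||% list()
  if (!is.null(seed)) tr_args$seed <- as.integer(seed)
  tcfg <- do.call(training_config, tr_args)
  n_folds <- cfg$cv$n_folds %||% 3L
  n_repeats <- cfg$cv$n_repeats %||% 1L
  spec <- if (is.null(cfg$features)) feature_spec() else
    feature_spec(unlist(cfg$features))
  topologies <- lapply(cfg$topologies, function(h) as.integer(unlist(h)))
  reports <- vector("list", length(topologies))
  rows <- vector("list", length(topologies))
  for (i in seq_along(topologies)) {
    h <- topologies[[i]]
    message("pipeline: task=", task, " hidden=", paste(h, collapse = "&"))
    rep_i <- crossval(dataset, spec, hidden = h, task = task, config = tcfg,
                      n_folds = n_folds, n_repeats = n_repeats)
    reports[[i]] <- rep_i
    rows[[i]] <- tibble::as_tibble(c(
      list(task = task, hidden = paste(h, collapse = "&")),
      as.list(rep_i$mean)))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir, "report.csv"), progress = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         dataframe = "rows", digits = NA)
  }
  attr(out, "reports") <- reports
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
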