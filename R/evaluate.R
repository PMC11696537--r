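# Performance metrics and agreement statistics.
#
# Balanced accuracy (mean per-class recall), expected calibration error
# (10 equal-width right-closed confidence bins), the stability delta
# (spread of per-level median accuracies), the one-tailed binomial
# above-chance threshold (0.411 at n = 90 trials, chance 1/3), Fleiss'
# kappa for fixed-rater-count nominal agreement, the rater-study trial
# roster, and the experiment-report aggregation around them.

#' Balanced accuracy
#'
#' Mean over classes of per-class recall, with predictions reduced by
#' argmax; classes absent from `true_labels` are excluded from the mean.
#' Robust to class imbalance: on a balanced test set it equals plain
#' accuracy.
#'
#' @param true_labels integer vector of true class indices (1..K).
#' @param predictions n x K matrix of class probabilities (or an integer
#'   vector of predicted classes).
#' @return scalar in `[0,1]`.
#' @export
balanced_accuracy <- function(true_labels, predictions) {
  if (length(true_labels) == 0) stop("empty input", call. = FALSE)
  pred <- if (is.matrix(predictions)) apply(predictions, 1, which.max)
          else as.integer(predictions)
  stopifnot(length(pred) == length(true_labels))
  mean(vapply(sort(unique(true_labels)), function(k)
    mean(pred[true_labels == k] == k), 1.0))
}

#' Expected calibration error
#'
#' Confidence is the maximum predicted probability per sample. `[0,1]` is
#' partitioned into `n_bins` equal-width right-closed bins;
#' `ECE = sum_b (|b|/N) * |acc_b - conf_b|`, with empty bins contributing
#' zero.
#'
#' @param predictions n x K matrix of class probabilities (rows on the
#'   simplex).
#' @param true_labels integer vector of true class indices.
#' @param n_bins number of confidence bins (default 10).
#' @return scalar in `[0,1]`.
#' @export
expected_calibration_error <- function(predictions, true_labels,
                                       n_bins = 10L) {
  if (length(true_labels) == 0) stop("empty input", call. = FALSE)
  conf <- apply(predictions, 1, max)
  pred <- apply(predictions, 1, which.max)
  correct <- pred == true_labels
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    ece <- ece + sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  ece
}

#' Stability delta
#'
#' The difference between the highest and lowest median balanced accuracy
#' across noise levels for one model; lower values indicate a more stable
#' model.
#'
#' @param medians numeric vector of per-level median accuracies.
#' @return scalar `max(medians) - min(medians)`.
#' @export
delta_stability <- function(medians) {
  if (length(medians) == 0) stop("empty input", call. = FALSE)
  max(medians) - min(medians)
}

#' Above-chance accuracy threshold
#'
#' Treating single classification trials as independent Bernoulli draws at
#' chance probability `chance_p`, returns `q / n_trials` where `q` is the
#' smallest integer `k` with `CDF_Binomial(n_trials, chance_p)(k) >= 1 -
#' alpha`, i.e. the one-tailed `(1 - alpha)` binomial quantile. Accuracies
#' above this value are significantly better than chance. At `n_trials =
#' 90`, `chance_p = 1/3`, `alpha = 0.05` the threshold is 37/90, about
#' 0.411.
#'
#' @param n_trials number of classification trials (>= 1).
#' @param chance_p chance success probability, in (0,1).
#' @param alpha one-tailed significance level, in (0,1).
#' @return scalar threshold in `[0,1]`.
#' @export
chance_threshold <- function(n_trials, chance_p = 1 / 3, alpha = 0.05) {
  if (n_trials < 1 || chance_p <= 0 || chance_p >= 1 || alpha <= 0 ||
      alpha >= 1)
    stop("invalid parameters", call. = FALSE)
  qbinom(1 - alpha, n_trials, chance_p) / n_trials
}

#' Fleiss' kappa for fixed-rater-count nominal agreement
#'
#' Standard formulation for `n` items each rated by the same number of
#' raters: `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar` is the mean
#' observed pairwise agreement per item and `Pe` the chance agreement from
#' the marginal category proportions. In the degenerate case where all mass
#' falls in one category (`Pe = 1`) kappa is defined as 1 when agreement is
#' perfect.
#'
#' @param counts items x categories matrix, `counts[i, c]` = number of
#'   raters assigning item `i` to category `c`; all row sums equal.
#' @return scalar kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be a non-negative integer matrix with >= 2 items",
         call. = FALSE)
  r <- sum(counts[1, ])
  if (r < 2) stop("at least 2 raters are required", call. = FALSE)
  if (any(rowSums(counts) != r))
    stop("unequal row sums: every item needs the same rater count",
         call. = FALSE)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(counts) / (nrow(counts) * r)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12) return(if (Pbar >= 1 - 1e-12) 1.0 else NaN)
  (Pbar - Pe) / (1 - Pe)
}

#' Build the rater-study trial roster
#'
#' Enumerates `n_raters * images_per_level * length(levels)` forced-choice
#' classification trials (e.g. 4 raters x 30 images x levels 0-6 = 840
#' trials) together with a blank response-sheet template.
#'
#' @param n_raters number of raters.
#' @param images_per_level images shown per noise level.
#' @param levels integer vector of noise levels (e.g. `0:6`).
#' @return list with `trials` (data frame `rater_id`, `item_id`, `level`)
#'   and `response_template` (the same rows plus an empty `response`
#'   column).
#' @export
build_rater_protocol <- function(n_raters, images_per_level, levels) {
  stopifnot(n_raters >= 1, images_per_level >= 1, length(levels) >= 1)
  grid <- expand.grid(image = seq_len(images_per_level), level = levels,
                      rater_id = seq_len(n_raters))
  trials <- data.frame(rater_id = grid$rater_id,
                       item_id = sprintf("L%d_img%02d", grid$level,
                                         grid$image),
                       level = grid$level, stringsAsFactors = FALSE)
  list(trials = trials,
       response_template = cbind(trials, response = NA_character_))
}

#' Aggregate per-run metric cells into a robustness report
#'
#' Computes, per (strategy, family, level), the median balanced accuracy
#' across runs (the exact middle order statistic for odd run counts); per
#' (strategy, family), the stability delta over levels; and flags each
#' aggregate cell whose median exceeds the above-chance threshold
#' `chance_threshold(n_test, 1/3, alpha)`.
#'
#' @param cells data frame with columns `strategy`, `run`, `family`,
#'   `level`, `balanced_accuracy`, `ece`.
#' @param n_test number of test trials behind each accuracy.
#' @param chance_p chance probability (default 1/3).
#' @param alpha one-tailed level for the threshold (default 0.05).
#' @return an object of class `robustness_report` with elements `cells`,
#'   `medians`, `deltas`, `threshold`, `n_test`.
#' @export
aggregate_report <- function(cells, n_test, chance_p = 1 / 3,
                             alpha = 0.05) {
  stopifnot(nrow(cells) >= 1)
  thr <- chance_threshold(n_test, chance_p, alpha)
  medians <- stats::aggregate(
    cbind(median_balanced_accuracy = balanced_accuracy,
          median_ece = ece) ~ strategy + family + level,
    data = cells, FUN = median)
  medians$above_chance <- medians$median_balanced_accuracy > thr
  deltas <- stats::aggregate(
    median_balanced_accuracy ~ strategy + family, data = medians,
    FUN = delta_stability)
  names(deltas)[3] <- "delta"
  structure(list(cells = cells, medians = medians, deltas = deltas,
                 threshold = thr, n_test = n_test),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d cells, above-chance threshold %.3f (n=%d)\n",
              nrow(x$cells), x$threshold, x$n_test))
  cat("stability deltas (max - min median accuracy over levels):\n")
  print(x$deltas, row.names = FALSE)
  invisible(x)
}

#' Write a robustness report to disk (CSV cells + JSON aggregates)
#'
#' @param report a `robustness_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(medians = report$medians, deltas = report$deltas,
         threshold = report$threshold, n_test = report$n_test),
    file.path(dir, "aggregates.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a robustness report written by [write_report()]
#'
#' @param dir directory holding `cells.csv` and `aggregates.json`.
#' @return a `robustness_report` recomputed from the cells.
#' @export
read_report <- function(dir) {
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  agg <- jsonlite::read_json(file.path(dir, "aggregates.json"),
                             simplifyVector = TRUE)
  aggregate_report(cells, n_test = agg$n_test)
}

#' Boxplot of balanced accuracy by noise level
#'
#' @param x a `robustness_report`.
#' @param family noise family to plot (default the first present).
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.robustness_report <- function(x, family = NULL, ...) {
  fam <- family %||% x$cells$family[1]
  sub <- x$cells[x$cells$family == fam, ]
  graphics::boxplot(balanced_accuracy ~ strategy + level, data = sub,
                    las = 2, main = paste("balanced accuracy,", fam),
                    ylab = "balanced accuracy", ...)
  graphics::abline(h = c(1 / 3, x$threshold), lty = c(3, 1))
  invisible(x)
}
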