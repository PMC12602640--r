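REPLICA <- "replica"
NON_REPLICA <- "non-replica"

check_truth <- function(truth) {
  stopifnot(is.data.frame(truth), all(c("id", "label") %in% names(truth)))
  bad <- setdiff(unique(truth$label), c(REPLICA, NON_REPLICA))
  if (length(bad)) {
    abort(sprintf("ground-truth labels must be '%s'/'%s'; got: %s", REPLICA,
                  NON_REPLICA, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(truth$id)) abort("duplicate ids in ground truth")
  if (length(unique(truth$label)) < 2L) {
    abort("ground truth contains a single class; calibration needs both",
          class = "replicheck_single_class")
  }
  invisible(truth)
}

check_values <- function(values) {
  stopifnot(is.data.frame(values), all(c("id", "value") %in% names(values)))
  if (any(!is.finite(values$value)) || any(values$value < 0)) {
    abort("decision values must be finite and non-negative")
  }
  invisible(values)
}

#' Binary replica decision for a decision value
#'
#' The decision rule is strict: a synthetic image is flagged as a replica
#' iff its decision value is strictly below the threshold `T`; a value
#' equal to `T` is a non-replica. The same rule applies whether the value
#' is a distance ratio (image/feature level) or an absolute converted
#' segmentation distance.
#'
#' @param value Non-negative numeric vector of decision values.
#' @param threshold Threshold `T`.
#' @param decision_variable `"ratio"` or `"absolute"` (informational; the
#'   rule is identical).
#' @return Character vector of `"replica"` / `"non-replica"`.
#' @examples
#' decide(c(0.10, 0.25, 0.39), threshold = 0.25)
#' @export
decide <- function(value, threshold, decision_variable = c("ratio",
                                                           "absolute")) {
  decision_variable <- match.arg(decision_variable)
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("decision values must be finite and non-negative")
  }
  ifelse(value < threshold, REPLICA, NON_REPLICA)
}

#' Balanced accuracy of replica predictions
#'
#' `(sensitivity + specificity) / 2` with replica as the positive class, so
#' sensitivity is the fraction of true replicas caught -- the
#' privacy-relevant direction.
#'
#' @param predictions Data frame `(id, label)` of predicted labels.
#' @param truth Data frame `(id, label)` of reference labels; must contain
#'   both classes and the same id set as `predictions`.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, truth) {
  check_truth(truth)
  stopifnot(is.data.frame(predictions),
            all(c("id", "label") %in% names(predictions)))
  if (!setequal(predictions$id, truth$id) ||
      nrow(predictions) != nrow(truth)) {
    abort("predictions and truth must cover the same id set",
          class = "replicheck_id_mismatch")
  }
  m <- dplyr::inner_join(predictions, truth, by = "id",
                         suffix = c("_pred", "_true"))
  pos <- m$label_true == REPLICA
  tpr <- sum(m$label_pred == REPLICA & pos) / sum(pos)
  tnr <- sum(m$label_pred == NON_REPLICA & !pos) / sum(!pos)
  (tpr + tnr) / 2
}

sens_spec_at <- function(value, is_replica, threshold) {
  pred_rep <- value < threshold
  c(sensitivity = sum(pred_rep & is_replica) / sum(is_replica),
    specificity = sum(!pred_rep & !is_replica) / sum(!is_replica))
}

#' Sweep replica thresholds against ground truth
#'
#' Evaluates the strict decision rule over a regular threshold grid and
#' reports sensitivity, specificity and balanced accuracy at each point,
#' plus the optimum (highest balanced accuracy; smallest threshold on
#' ties). For ratio-type decision variables (and converted distances) the
#' grid spans `[0, 1]` in `step` increments; for unconverted absolute
#' values it spans `[0, max(value)]` in `step * max(value)` increments, so
#' the grid is always relative to the value scale of the measure.
#'
#' @param values Data frame `(id, value)` of decision values.
#' @param truth Data frame `(id, label)`; both classes required.
#' @param step Grid increment, default 0.01.
#' @param decision_variable `"ratio"` or `"absolute"` (chooses the grid
#'   construction).
#' @param measure Optional measure name recorded in the result.
#' @return A `replica_sweep` object; see [tidy.replica_sweep()],
#'   [glance.replica_sweep()], [autoplot.replica_sweep()].
#' @export
sweep_thresholds <- function(values, truth, step = 0.01,
                             decision_variable = c("ratio", "absolute"),
                             measure = NULL) {
  decision_variable <- match.arg(decision_variable)
  check_values(values)
  check_truth(truth)
  if (!is.numeric(step) || step <= 0) abort("step must be > 0")
  m <- dplyr::inner_join(values, truth, by = "id")
  if (nrow(m) != nrow(values) || nrow(m) != nrow(truth)) {
    abort("values and truth must cover the same id set",
          class = "replicheck_id_mismatch")
  }
  is_rep <- m$label == REPLICA
  grid_max <- if (decision_variable == "ratio") 1 else max(m$value)
  thresholds <- if (grid_max == 0) 0 else seq(0, grid_max, by = step *
    (if (decision_variable == "ratio") 1 else grid_max))
  stats <- t(vapply(thresholds, function(th) sens_spec_at(m$value, is_rep, th),
                    numeric(2)))
  grid <- tibble::tibble(
    threshold = thresholds,
    sensitivity = stats[, "sensitivity"],
    specificity = stats[, "specificity"],
    balanced_accuracy = (stats[, "sensitivity"] + stats[, "specificity"]) / 2
  )
  best <- which.max(grid$balanced_accuracy)  # first max = smallest threshold
  structure(
    list(grid = grid,
         optimal_threshold = grid$threshold[best],
         optimal_balanced_accuracy = grid$balanced_accuracy[best],
         measure = measure,
         decision_variable = decision_variable,
         step = step,
         grid_note = paste0("grid: [0, ",
                            format(grid_max), "] in ",
                            format(step),
                            if (decision_variable == "absolute")
                              " x max(value)" else "",
                            " increments")),
    class = "replica_sweep")
}

#' @export
print.replica_sweep <- function(x, ...) {
  cat(sprintf(
    "<replica_sweep%s (%s)> %d thresholds; optimum T = %g (balanced accuracy %.4g)\n",
    if (is.null(x$measure)) "" else paste0(" ", x$measure),
    x$decision_variable, nrow(x$grid), x$optimal_threshold,
    x$optimal_balanced_accuracy))
  invisible(x)
}

#' Tidy a threshold sweep into its grid
#'
#' @param x A `replica_sweep`.
#' @param ... Unused.
#' @return The grid tibble `(threshold, sensitivity, specificity,
#'   balanced_accuracy)`.
#' @export
tidy.replica_sweep <- function(x, ...) x$grid

#' One-row summary of a threshold sweep
#'
#' @param x A `replica_sweep`.
#' @param ... Unused.
#' @return One-row tibble `(measure, decision_variable, optimal_threshold,
#'   optimal_balanced_accuracy, n_thresholds)`.
#' @export
glance.replica_sweep <- function(x, ...) {
  tibble::tibble(
    measure = x$measure %||% NA_character_,
    decision_variable = x$decision_variable,
    optimal_threshold = x$optimal_threshold,
    optimal_balanced_accuracy = x$optimal_balanced_accuracy,
    n_thresholds = nrow(x$grid))
}

#' Plot a threshold sweep
#'
#' Balanced accuracy (with sensitivity and specificity) as a function of
#' threshold, the selected optimum marked.
#'
#' @param object A `replica_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replica_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid, -"threshold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal_threshold,
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("threshold (%s)", object$decision_variable),
      y = NULL,
      title = sprintf("Threshold sweep%s: optimum T = %g (BA = %.3f)",
                      if (is.null(object$measure)) "" else
                        paste0(" [", object$measure, "]"),
                      object$optimal_threshold,
                      object$optimal_balanced_accuracy)) +
    ggplot2::theme_minimal()
}

#' Margin-maximizing automation threshold
#'
#' For automating replica detection on future samples, the threshold is
#' placed in the middle of the margin between the classes: the mean of the
#' highest decision value among true replicas and the lowest among true
#' non-replicas. A `separable` attribute records whether that margin is
#' positive (max replica value strictly below min non-replica value).
#'
#' @inheritParams sweep_thresholds
#' @return Scalar threshold with attribute `separable` (logical).
#' @examples
#' vals <- tibble::tibble(id = c("a", "b"), value = c(0.11, 0.39))
#' truth <- tibble::tibble(id = c("a", "b"),
#'                         label = c("replica", "non-replica"))
#' margin_threshold(vals, truth)  # 0.25
#' @export
margin_threshold <- function(values, truth) {
  check_values(values)
  check_truth(truth)
  m <- dplyr::inner_join(values, truth, by = "id")
  if (nrow(m) != nrow(values) || nrow(m) != nrow(truth)) {
    abort("values and truth must cover the same id set",
          class = "replicheck_id_mismatch")
  }
  hi_rep <- max(m$value[m$label == REPLICA])
  lo_non <- min(m$value[m$label == NON_REPLICA])
  structure((hi_rep + lo_non) / 2, separable = hi_rep < lo_non)
}

#' Apply a fixed threshold to a set of decision values
#'
#' The automation step: [decide()] mapped over all ids under one fixed
#' threshold, with summary counts.
#'
#' @param values Data frame `(id, value)`.
#' @param threshold Threshold `T >= 0`.
#' @param decision_variable Passed to [decide()].
#' @return Tibble `(id, value, decision)` with attributes `n_flagged` and
#'   `n_total`.
#' @export
apply_automation <- function(values, threshold,
                             decision_variable = c("ratio", "absolute")) {
  decision_variable <- match.arg(decision_variable)
  if (threshold < 0) abort("threshold must be >= 0")
  if (nrow(values) == 0L) {
    return(structure(tibble::tibble(id = character(), value = numeric(),
                                    decision = character()),
                     n_flagged = 0L, n_total = 0L))
  }
  check_values(values)
  dec <- decide(values$value, threshold, decision_variable)
  structure(tibble::tibble(id = values$id, value = values$value,
                           decision = dec),
            n_flagged = sum(dec == REPLICA), n_total = nrow(values))
}

#' Read replica ground truth from CSV
#'
#' Two layouts are accepted. (1) Adjudicated: columns `synthetic_id`,
#' `label` with labels `replica` / `non-replica`. (2) Rater scores: columns
#' `synthetic_id`, `rater1_score`, `rater2_score` on the 4-point scale,
#' where scores of 3 or 4 classify an image as a replica. With rater
#' scores, disagreements between the raters must be resolved by an explicit
#' `adjudicated` column (the final label); the reader refuses to apply a
#' silent majority rule.
#'
#' @param path CSV path.
#' @return Tibble `(id, label)` with attribute `provenance` describing how
#'   labels were derived.
#' @export
read_ground_truth <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"synthetic_id" %in% names(df)) {
    abort(sprintf("ground truth '%s' needs a synthetic_id column", path))
  }
  if ("label" %in% names(df)) {
    out <- tibble::tibble(id = as.character(df$synthetic_id),
                          label = df$label)
    attr(out, "provenance") <- "adjudicated labels read directly"
    return(out)
  }
  if (!all(c("rater1_score", "rater2_score") %in% names(df))) {
    abort(sprintf(
      "ground truth '%s' needs either a label column or rater1_score/rater2_score",
      path))
  }
  score_ok <- function(s) all(s %in% 1:4)
  if (!score_ok(df$rater1_score) || !score_ok(df$rater2_score)) {
    abort("rater scores must be integers on the 4-point scale (1-4)")
  }
  r1 <- ifelse(df$rater1_score >= 3, REPLICA, NON_REPLICA)
  r2 <- ifelse(df$rater2_score >= 3, REPLICA, NON_REPLICA)
  disagree <- r1 != r2
  if (any(disagree)) {
    if (!"adjudicated" %in% names(df)) {
      abort(paste0(
        "raters disagree on: ",
        paste(df$synthetic_id[disagree], collapse = ", "),
        "; add an explicit 'adjudicated' column (no silent majority rule)"),
        class = "replicheck_unadjudicated")
    }
    lab <- ifelse(disagree, df$adjudicated, r1)
  } else {
    lab <- r1
  }
  bad <- setdiff(unique(lab), c(REPLICA, NON_REPLICA))
  if (length(bad)) {
    abort(sprintf("adjudicated labels must be replica/non-replica; got %s",
                  paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(id = as.character(df$synthetic_id), label = lab)
  attr(out, "provenance") <-
    "scores 3-4 -> replica per rater; disagreements from adjudicated column"
  out
}
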