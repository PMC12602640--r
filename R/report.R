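resolve_index <- function(x, role) {
  if (inherits(x, "replica_index")) return(x)
  if (is.character(x) && length(x) == 1L) return(build_index(x, role = role))
  abort(sprintf("expected a replica_index or manifest path for the %s set",
                role))
}

resolve_truth <- function(x) {
  if (is.character(x) && length(x) == 1L) return(read_ground_truth(x))
  if (is.data.frame(x)) {
    df <- tibble::as_tibble(x)
    if ("synthetic_id" %in% names(df) && !"id" %in% names(df)) {
      df <- dplyr::rename(df, id = "synthetic_id")
    }
    return(df[c("id", "label")])
  }
  abort("expected a ground-truth path or data frame")
}

#' Decision values for one measure over a synthetic set
#'
#' Produces the per-synthetic-image decision variable the thresholding step
#' consumes: the distance ratio for image- and feature-level measures, and
#' the absolute converted distance to the closest training image for
#' segmentation-level measures (the segmentation step already isolates the
#' region of interest, so the raw closeness is used rather than the ratio).
#'
#' @inheritParams compute_ratios
#' @return Tibble `(synthetic_id, measure, decision_variable, value,
#'   closest_id, n, degenerate)`.
#' @export
compute_decision_values <- function(synthetic, training, measure, n = 50L,
                                    extractor = "pooled", cache = NULL) {
  spec <- as_measure_spec(measure)
  if (spec$level == "segmentation") {
    dist_tbl <- pairwise_distances(synthetic, training, spec,
                                   extractor = extractor, cache = cache)
    purrr::map_dfr(synthetic$id, function(sid) {
      ranked <- ranked_from_distances(dist_tbl, sid)
      tibble::tibble(synthetic_id = sid, measure = spec$name,
                     decision_variable = "absolute",
                     value = ranked$distance[1],
                     closest_id = ranked$training_id[1],
                     n = 1L, degenerate = FALSE)
    })
  } else {
    ratios <- compute_ratios(synthetic, training, spec, n = n,
                             extractor = extractor, cache = cache)
    tibble::tibble(synthetic_id = ratios$synthetic_id,
                   measure = ratios$measure,
                   decision_variable = "ratio",
                   value = ratios$ratio,
                   closest_id = ratios$closest_id,
                   n = ratios$n,
                   degenerate = ratios$degenerate)
  }
}

#' Run the replica-detection pipeline
#'
#' The end-to-end detection workflow for a synthetic set against a training
#' set: for every requested measure, rank training images per synthetic
#' image, compute the decision values ([compute_decision_values()]),
#' produce the RMSE review pairs for visual scoring, and -- when thresholds
#' are supplied -- binary replica decisions. All tables are returned and,
#' with `out_dir` set, written as CSV plus a JSON run summary.
#'
#' @param training,synthetic `replica_index` objects or manifest paths.
#' @param measures Character vector of measure names, or list of
#'   [measure_spec()] objects. Default `"rmse"`.
#' @param n Neighbourhood size for the distance ratio, default 50.
#' @param thresholds Optional named numeric vector `c(measure = T)`; only
#'   measures named here get a decisions table.
#' @param out_dir Optional output directory for `ratios.csv`,
#'   `review_pairs.csv`, `decisions.csv`, `summary.json`.
#' @param extractor Feature extractor name, default `"pooled"`.
#' @param cache Optional distance-cache CSV path.
#' @param quiet Suppress progress messages.
#' @return List with `values`, `review_pairs`, `decisions` (or `NULL`),
#'   `summary`.
#' @export
run_detect <- function(training, synthetic, measures = "rmse", n = 50L,
                       thresholds = NULL, out_dir = NULL,
                       extractor = "pooled", cache = NULL, quiet = FALSE) {
  training <- resolve_index(training, "training")
  synthetic <- resolve_index(synthetic, "synthetic")
  specs <- lapply(measures, as_measure_spec)
  if (length(specs) == 0L) abort("at least one measure is required")
  say <- function(...) if (!quiet) inform(sprintf(...))
  say("detect: %d training / %d synthetic volumes, measures: %s",
      nrow(training), nrow(synthetic),
      paste(vapply(specs, `[[`, character(1), "name"), collapse = ", "))

  values <- purrr::map_dfr(specs, function(spec) {
    t0 <- proc.time()[["elapsed"]]
    out <- compute_decision_values(synthetic, training, spec, n = n,
                                   extractor = extractor, cache = cache)
    say("measure %s: %.2f s", spec$name, proc.time()[["elapsed"]] - t0)
    if (any(out$degenerate)) {
      warn(sprintf("measure %s: degenerate (all-zero) neighbourhood for: %s",
                   spec$name,
                   paste(out$synthetic_id[out$degenerate], collapse = ", ")))
    }
    out
  })
  review_pairs <- preselect_pairs(synthetic, training)

  decisions <- NULL
  if (!is.null(thresholds)) {
    stopifnot(!is.null(names(thresholds)))
    decisions <- purrr::map_dfr(names(thresholds), function(mname) {
      sub <- values[values$measure == mname, ]
      if (nrow(sub) == 0L) {
        abort(sprintf("threshold given for measure '%s' that was not run",
                      mname))
      }
      dec <- apply_automation(
        tibble::tibble(id = sub$synthetic_id, value = sub$value),
        threshold = thresholds[[mname]],
        decision_variable = sub$decision_variable[1])
      tibble::tibble(synthetic_id = dec$id, measure = mname,
                     value = dec$value, threshold = thresholds[[mname]],
                     decision = dec$decision)
    })
  }

  summary <- list(
    n_training = nrow(training),
    n_synthetic = nrow(synthetic),
    measures = vapply(specs, `[[`, character(1), "name"),
    n = as.integer(n),
    thresholds = as.list(thresholds %||% stats::setNames(list(), character())),
    extractor = extractor,
    package_version = as.character(utils::packageVersion("replicheck")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(values, file.path(out_dir, "ratios.csv"))
    readr::write_csv(review_pairs, file.path(out_dir, "review_pairs.csv"))
    if (!is.null(decisions)) {
      readr::write_csv(decisions, file.path(out_dir, "decisions.csv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(values = values, review_pairs = review_pairs, decisions = decisions,
       summary = summary)
}

#' Calibrate replica thresholds against ground truth
#'
#' The validation workflow: with visual-scoring ground truth available,
#' sweep thresholds in 0.01 increments for every measure
#' ([sweep_thresholds()]), compute the margin-maximizing automation
#' threshold ([margin_threshold()]), and emit a per-measure recommendation.
#'
#' @inheritParams run_detect
#' @param ground_truth Ground-truth CSV path or data frame
#'   (`id`/`synthetic_id`, `label`); both classes must be present.
#' @param step Sweep increment, default 0.01.
#' @return List with `values`, `sweeps` (named list of `replica_sweep`),
#'   `recommendation` tibble.
#' @export
run_calibrate <- function(training, synthetic, ground_truth,
                          measures = "rmse", n = 50L, step = 0.01,
                          out_dir = NULL, extractor = "pooled",
                          cache = NULL, quiet = FALSE) {
  truth <- resolve_truth(ground_truth)
  check_truth(truth)
  det <- run_detect(training, synthetic, measures = measures, n = n,
                    out_dir = NULL, extractor = extractor, cache = cache,
                    quiet = quiet)
  values <- det$values
  specs <- lapply(measures, as_measure_spec)
  sweeps <- list()
  rec <- purrr::map_dfr(specs, function(spec) {
    sub <- values[values$measure == spec$name, ]
    vals <- tibble::tibble(id = sub$synthetic_id, value = sub$value)
    sw <- sweep_thresholds(vals, truth, step = step,
                           decision_variable = sub$decision_variable[1],
                           measure = spec$name)
    sweeps[[spec$name]] <<- sw
    mt <- margin_threshold(vals, truth)
    tibble::tibble(measure = spec$name,
                   decision_variable = sub$decision_variable[1],
                   optimal_threshold = sw$optimal_threshold,
                   optimal_balanced_accuracy = sw$optimal_balanced_accuracy,
                   margin_threshold = as.numeric(mt),
                   separable = attr(mt, "separable"))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(values, file.path(out_dir, "ratios.csv"))
    for (mname in names(sweeps)) {
      readr::write_csv(sweeps[[mname]]$grid,
                       file.path(out_dir, paste0("sweep_", mname, ".csv")))
    }
    jsonlite::write_json(
      lapply(seq_len(nrow(rec)), function(i) as.list(rec[i, ])),
      file.path(out_dir, "recommendation.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(values = values, sweeps = sweeps, recommendation = rec)
}

#' Histogram of distance ratios
#'
#' The review figure of the automation workflow: the distribution of
#' decision values over the synthetic set, with the selected threshold
#' marked.
#'
#' @param values Tibble with columns `synthetic_id`/`id`, `value` (or
#'   `ratio`), for one measure.
#' @param threshold Optional threshold to mark.
#' @param binwidth Histogram bin width, default 0.02.
#' @return A ggplot.
#' @export
plot_ratio_histogram <- function(values, threshold = NULL,
                                 binwidth = 0.02) {
  if ("ratio" %in% names(values) && !"value" %in% names(values)) {
    values$value <- values$ratio
  }
  p <- ggplot2::ggplot(values, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35") +
    ggplot2::labs(x = "decision value (distance ratio)",
                  y = "synthetic images") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "orange")
  }
  p
}

#' Build the human review report for a ratio table
#'
#' Ranks the synthetic set ascending by decision value (most replica-like
#' first), truncates to the top-`k` candidates for visual inspection, and
#' plots the decision-value histogram with the threshold marked. With
#' `out_dir` set, writes `ranked.csv`, `top_pairs.csv` and
#' `ratio_histogram.png`.
#'
#' @param values Ratio/values table from [run_detect()] (or its
#'   `ratios.csv`), restricted to or containing a single measure.
#' @param threshold Decision threshold to mark and count against.
#' @param top_k Number of top candidates listed for review, default 10.
#' @param out_dir Optional output directory.
#' @return List with `ranked` (full ascending table), `top_pairs`,
#'   `histogram` (ggplot), `summary` (n, n_flagged, fraction_flagged,
#'   note).
#' @export
run_report <- function(values, threshold, top_k = 10L, out_dir = NULL) {
  if (is.character(values) && length(values) == 1L) {
    values <- readr::read_csv(values, show_col_types = FALSE,
                              progress = FALSE)
  }
  if (nrow(values) == 0L) abort("empty ratio table")
  if (length(unique(values$measure)) > 1L) {
    abort("report expects a single measure; filter the table first",
          class = "replicheck_mixed_measures")
  }
  ranked <- values[order(values$value, values$synthetic_id,
                         method = "radix"), ]
  top_pairs <- utils::head(
    ranked[c("synthetic_id", "closest_id", "value")], top_k)
  n_flagged <- sum(ranked$value < threshold)
  note <- if (n_flagged == nrow(ranked)) {
    "100% of synthetic images flagged as replicas at this threshold"
  } else {
    sprintf("%d of %d synthetic images flagged (%.1f%%)", n_flagged,
            nrow(ranked), 100 * n_flagged / nrow(ranked))
  }
  hist <- plot_ratio_histogram(ranked, threshold = threshold)
  summary <- list(measure = values$measure[1], threshold = threshold,
                  n = nrow(ranked), n_flagged = n_flagged,
                  fraction_flagged = n_flagged / nrow(ranked), note = note)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(ranked, file.path(out_dir, "ranked.csv"))
    readr::write_csv(top_pairs, file.path(out_dir, "top_pairs.csv"))
    ggplot2::ggsave(file.path(out_dir, "ratio_histogram.png"), hist,
                    width = 6, height = 4, dpi = 150)
    jsonlite::write_json(summary, file.path(out_dir, "report_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(ranked = ranked, top_pairs = top_pairs, histogram = hist,
       summary = summary)
}
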