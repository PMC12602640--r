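#' Pairwise synthetic-vs-training distances for one measure
#'
#' Computes the full distance table between every synthetic and every
#' training entry under one measure, on the common distance scale
#' (similarities converted via [to_distance()]). With `cache` set, the
#' long-format table is persisted to CSV and reused on subsequent calls:
#' image-level analysis over large training sets is the expensive part of a
#' replica audit, and cached rows are never recomputed.
#'
#' @param synthetic,training `replica_index` tibbles on a shared grid.
#' @param measure A `measure_spec` or measure name.
#' @param extractor Extractor name used when feature-level measures find no
#'   stored feature vectors.
#' @param cache Optional CSV path for the distance-matrix cache.
#' @return Tibble with columns `synthetic_id`, `training_id`, `measure`,
#'   `raw_value`, `distance`, `flag`.
#' @export
pairwise_distances <- function(synthetic, training, measure,
                               extractor = "pooled", cache = NULL) {
  spec <- as_measure_spec(measure)
  if (nrow(training) == 0L) {
    abort("empty training set", class = "replicheck_empty_index")
  }
  check_same_grid(synthetic$volume[[1]], training$volume[[1]],
                  spacing = TRUE)

  cached <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    cached <- read_cache(cache)
    cached <- dplyr::filter(cached, .data$measure == spec$name)
  }

  syn_feats <- train_feats <- NULL
  if (spec$level == "feature") {
    syn_feats <- lapply(seq_len(nrow(synthetic)),
                        function(i) entry_features(synthetic, i, extractor))
    train_feats <- lapply(seq_len(nrow(training)),
                          function(i) entry_features(training, i, extractor))
  }
  if (spec$level == "segmentation") {
    if (any(vapply(synthetic$mask, is.null, logical(1))) ||
        any(vapply(training$mask, is.null, logical(1)))) {
      abort("segmentation-level analysis requested but masks are missing",
            class = "replicheck_missing_mask")
    }
  }

  rows <- vector("list", nrow(synthetic) * nrow(training))
  r <- 1L
  for (i in seq_len(nrow(synthetic))) {
    for (j in seq_len(nrow(training))) {
      sid <- synthetic$id[i]; tid <- training$id[j]
      hit <- if (!is.null(cached)) {
        dplyr::filter(cached, .data$synthetic_id == sid,
                      .data$training_id == tid)
      } else NULL
      if (!is.null(hit) && nrow(hit) == 1L) {
        rows[[r]] <- tibble::tibble(
          synthetic_id = sid, training_id = tid, measure = spec$name,
          raw_value = hit$raw_value, distance = hit$distance,
          flag = as.character(hit$flag))
      } else {
        raw <- compute_raw_measure(
          spec,
          syn = synthetic$volume[[i]], train = training$volume[[j]],
          syn_mask = synthetic$mask[[i]], train_mask = training$mask[[j]],
          syn_feat = syn_feats[[i]], train_feat = train_feats[[j]])
        flag <- attr(raw, "flag") %||% NA_character_
        raw <- as.numeric(raw)
        rows[[r]] <- tibble::tibble(
          synthetic_id = sid, training_id = tid, measure = spec$name,
          raw_value = raw, distance = to_distance(raw, spec), flag = flag)
      }
      r <- r + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(cache)) {
    keep <- NULL
    if (file.exists(cache)) {
      keep <- read_cache(cache)
      keep <- dplyr::anti_join(keep, out,
                               by = c("synthetic_id", "training_id",
                                      "measure"))
    }
    readr::write_csv(dplyr::bind_rows(keep, out), cache)
  }
  out
}

read_cache <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    synthetic_id = readr::col_character(),
                    training_id = readr::col_character(),
                    measure = readr::col_character(),
                    raw_value = readr::col_double(),
                    distance = readr::col_double(),
                    flag = readr::col_character()))
}

#' Rank training images by distance to one synthetic image
#'
#' Produces the full ascending ranking of the training set for one
#' synthetic image under one measure; ties are broken lexicographically by
#' training id so the ranking is deterministic. Distances are on the common
#' distance scale ([to_distance()]).
#'
#' @param synthetic A `replica_volume`, numeric feature vector, or
#'   `replica_segmask` matching the measure's level; or a one-row
#'   `replica_index`.
#' @param training A `replica_index` with role `"training"`.
#' @param measure A `measure_spec` or measure name.
#' @param extractor Extractor for feature-level measures when `synthetic`
#'   is a volume or index entry without stored features.
#' @return Tibble `(training_id, distance)` sorted ascending, with
#'   attributes `synthetic_id` and `measure`.
#' @export
rank_training <- function(synthetic, training, measure,
                          extractor = "pooled") {
  spec <- as_measure_spec(measure)
  if (nrow(training) == 0L) {
    abort("empty training set", class = "replicheck_empty_index")
  }
  syn_id <- "synthetic"
  syn_vol <- NULL; syn_mask <- NULL; syn_feat <- NULL
  if (inherits(synthetic, "replica_index")) {
    stopifnot(nrow(synthetic) == 1L)
    syn_id <- synthetic$id[1]
    syn_vol <- synthetic$volume[[1]]
    syn_mask <- synthetic$mask[[1]]
    if (spec$level == "feature") {
      syn_feat <- entry_features(synthetic, 1L, extractor)
    }
  } else if (inherits(synthetic, "replica_volume")) {
    syn_id <- synthetic$id
    syn_vol <- synthetic
    if (spec$level == "feature") {
      syn_feat <- as.numeric(extract_features(synthetic, extractor))
    }
  } else if (inherits(synthetic, "replica_segmask")) {
    syn_id <- synthetic$id
    syn_mask <- synthetic
  } else if (is.numeric(synthetic)) {
    syn_feat <- as.numeric(synthetic)
  } else {
    abort("unsupported synthetic input for rank_training")
  }
  if (spec$level == "image" && is.null(syn_vol)) {
    abort(sprintf("image-level measure '%s' needs a volume input", spec$name))
  }
  if (spec$level == "segmentation" && is.null(syn_mask)) {
    abort(sprintf("segmentation-level measure '%s' needs a mask input",
                  spec$name),
          class = "replicheck_missing_mask")
  }

  train_feats <- NULL
  if (spec$level == "feature") {
    train_feats <- lapply(seq_len(nrow(training)),
                          function(i) entry_features(training, i, extractor))
  }
  dists <- vapply(seq_len(nrow(training)), function(j) {
    raw <- compute_raw_measure(
      spec, syn = syn_vol, train = training$volume[[j]],
      syn_mask = syn_mask, train_mask = training$mask[[j]],
      syn_feat = syn_feat, train_feat = train_feats[[j]])
    to_distance(as.numeric(raw), spec)
  }, numeric(1))

  out <- tibble::tibble(training_id = training$id, distance = dists)
  out <- out[order(out$distance, out$training_id, method = "radix"), ]
  structure(out, synthetic_id = syn_id, measure = spec$name,
            class = class(tibble::tibble()))
}

ranked_from_distances <- function(dist_tbl, sid) {
  sub <- dist_tbl[dist_tbl$synthetic_id == sid, ]
  out <- tibble::tibble(training_id = sub$training_id,
                        distance = sub$distance)
  out <- out[order(out$distance, out$training_id, method = "radix"), ]
  structure(out, synthetic_id = sid, measure = dist_tbl$measure[1])
}

#' Distance ratio of one ranked neighbourhood
#'
#' The decision statistic: the distance to the closest training image
#' divided by the mean distance to the `n` closest training images (the
#' rank-1 image included in the neighbourhood). Values near 0 mean the
#' synthetic image is abnormally close to one training image relative to
#' its local neighbourhood -- the signature of a memorized replica. The
#' ratio always lies in `[0, 1]`.
#'
#' If the whole neighbourhood is at distance 0 (exact duplicates) the ratio
#' is defined as 0 with `degenerate = TRUE`. When `n` exceeds the training
#' set size it is capped with a warning.
#'
#' @param ranked Output of [rank_training()].
#' @param n Neighbourhood size; default 50.
#' @return One-row tibble `(synthetic_id, measure, ratio, closest_id, n,
#'   degenerate)`.
#' @export
distance_ratio <- function(ranked, n = 50L) {
  n <- as.integer(n)
  if (n < 1L) abort("n must be a positive integer")
  if (nrow(ranked) == 0L) abort("empty ranking")
  if (n > nrow(ranked)) {
    warn(sprintf("n=%d exceeds training-set size %d; capping", n,
                 nrow(ranked)))
    n <- nrow(ranked)
  }
  d <- ranked$distance
  d1 <- d[1]
  m <- mean(d[seq_len(n)])
  degenerate <- m == 0
  ratio <- if (degenerate) 0 else d1 / m
  tibble::tibble(
    synthetic_id = attr(ranked, "synthetic_id") %||% NA_character_,
    measure = attr(ranked, "measure") %||% NA_character_,
    ratio = ratio,
    closest_id = ranked$training_id[1],
    n = n,
    degenerate = degenerate
  )
}

#' Distance ratios for a whole synthetic set
#'
#' Runs [rank_training()] + [distance_ratio()] for every synthetic entry
#' under one measure, via a single pairwise distance table (optionally
#' cached).
#'
#' @inheritParams pairwise_distances
#' @param n Neighbourhood size, default 50 (capped at the training-set size
#'   with a warning).
#' @return Tibble with one row per synthetic entry, columns as
#'   [distance_ratio()].
#' @export
compute_ratios <- function(synthetic, training, measure, n = 50L,
                           extractor = "pooled", cache = NULL) {
  spec <- as_measure_spec(measure)
  dist_tbl <- pairwise_distances(synthetic, training, spec,
                                 extractor = extractor, cache = cache)
  purrr::map_dfr(synthetic$id, function(sid) {
    distance_ratio(ranked_from_distances(dist_tbl, sid), n = n)
  })
}

#' Pair each synthetic image with its RMSE-closest training image
#'
#' The preselection step that makes expert visual scoring feasible: rather
#' than inspecting every synthetic-training pair, raters review one pair
#' per synthetic image, chosen by voxel-wise RMSE.
#'
#' @param synthetic,training `replica_index` tibbles on a shared grid.
#' @return Tibble `(synthetic_id, training_id, rmse)`, one row per
#'   synthetic entry.
#' @export
preselect_pairs <- function(synthetic, training) {
  if (nrow(synthetic) == 0L || nrow(training) == 0L) {
    abort("both indices must be non-empty", class = "replicheck_empty_index")
  }
  purrr::map_dfr(seq_len(nrow(synthetic)), function(i) {
    ranked <- rank_training(synthetic[i, ], training, "rmse")
    tibble::tibble(synthetic_id = synthetic$id[i],
                   training_id = ranked$training_id[1],
                   rmse = ranked$distance[1])
  })
}

#' Rank synthetic images by distance ratio
#'
#' Orders a ratio table ascending by ratio (lowest = most replica-like
#' first), ties broken by synthetic id. This ranking drives the manual
#' review of likely replicas in the automation workflow.
#'
#' @param ratios Tibble as returned by [compute_ratios()]; all rows must
#'   share one measure.
#' @return The ratios tibble, reordered.
#' @export
rank_synthetic_by_ratio <- function(ratios) {
  if (nrow(ratios) == 0L) abort("empty ratio table")
  if (length(unique(ratios$measure)) != 1L) {
    abort("ratios mix measures; rank one measure at a time",
          class = "replicheck_mixed_measures")
  }
  ratios[order(ratios$ratio, ratios$synthetic_id, method = "radix"), ]
}
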