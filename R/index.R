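#' Build a dataset index from loaded objects
#'
#' A dataset index is the package's handle on one co-registered image set
#' (either the training set or the synthetic set under audit). It is a
#' tibble with one row per subject: `id`, a `volume` list-column, and
#' optional `mask` and `features` list-columns. Rows are sorted
#' lexicographically by id (C locale) so ordering is stable across runs, and
#' all volumes are checked to share one grid shape and spacing.
#'
#' @param volumes List of `replica_volume` objects.
#' @param masks Optional list of `replica_segmask` objects, parallel to
#'   `volumes` (use `NULL` elements for missing masks).
#' @param features Optional list of numeric feature vectors, parallel to
#'   `volumes`.
#' @param role `"training"` or `"synthetic"`.
#' @return A tibble of class `replica_index` with attribute `role`.
#' @export
dataset_index <- function(volumes, masks = NULL, features = NULL,
                          role = c("training", "synthetic")) {
  role <- match.arg(role)
  if (length(volumes) == 0L) {
    abort("dataset index must contain at least one volume",
          class = "replicheck_empty_index")
  }
  stopifnot(all(vapply(volumes, inherits, logical(1), "replica_volume")))
  ids <- vapply(volumes, function(v) v$id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate ids in %s index: %s", role,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "replicheck_duplicate_id")
  }
  if (is.null(masks)) masks <- vector("list", length(volumes))
  if (is.null(features)) features <- vector("list", length(volumes))
  stopifnot(length(masks) == length(volumes),
            length(features) == length(volumes))

  ord <- order(ids, method = "radix")
  idx <- tibble::tibble(
    id = ids[ord],
    volume = volumes[ord],
    mask = masks[ord],
    features = features[ord]
  )
  check_shared_grid(idx, role)
  structure(idx, role = role,
            class = c("replica_index", class(tibble::tibble())))
}

check_shared_grid <- function(idx, role) {
  ref <- idx$volume[[1]]
  for (i in seq_len(nrow(idx))) {
    v <- idx$volume[[i]]
    if (!identical(dim(v$data), dim(ref$data))) {
      abort(sprintf(
        "%s index: volume '%s' has grid %s but '%s' has %s; all volumes must share one grid",
        role, v$id, paste(dim(v$data), collapse = "x"),
        ref$id, paste(dim(ref$data), collapse = "x")),
        class = "replicheck_grid_mismatch")
    }
    if (max(abs(v$spacing - ref$spacing)) > 1e-6) {
      abort(sprintf("%s index: volume '%s' spacing differs from '%s'",
                    role, v$id, ref$id),
            class = "replicheck_grid_mismatch")
    }
    m <- idx$mask[[i]]
    if (!is.null(m) && !identical(dim(m$labels), dim(ref$data))) {
      abort(sprintf("%s index: mask '%s' grid differs from its volume",
                    role, m$id),
            class = "replicheck_grid_mismatch")
    }
  }
  invisible(idx)
}

#' Build a dataset index from a manifest CSV or a directory
#'
#' Accepts either a directory of NIfTI files (every `.nii`/`.nii.gz` becomes
#' a volume, id = file stem) or a manifest CSV with header columns `id`,
#' `volume` and optionally `mask` and `features`. Relative paths in a
#' manifest are resolved against the manifest's directory. The `features`
#' column names one feature CSV for the dataset (first column `id`,
#' remaining columns numeric); per-id rows are attached to matching entries.
#'
#' @param path Manifest CSV path or directory path.
#' @param role `"training"` or `"synthetic"`.
#' @param features Optional path to a feature CSV, overriding any manifest
#'   `features` column.
#' @return A `replica_index` tibble sorted lexicographically by id.
#' @export
build_index <- function(path, role = c("training", "synthetic"),
                        features = NULL) {
  role <- match.arg(role)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(files) == 0L) {
      abort(sprintf("no NIfTI files found in directory '%s'", path),
            class = "replicheck_empty_index")
    }
    vols <- lapply(files, read_volume)
    idx <- dataset_index(vols, role = role)
  } else {
    man <- readr::read_csv(path, show_col_types = FALSE,
                           progress = FALSE)
    if (!all(c("id", "volume") %in% names(man))) {
      abort(sprintf("manifest '%s' must have columns id, volume", path))
    }
    if (anyDuplicated(man$id)) {
      abort(sprintf("duplicate ids in manifest '%s': %s", path,
                    paste(unique(man$id[duplicated(man$id)]), collapse = ", ")),
            class = "replicheck_duplicate_id")
    }
    base <- dirname(path)
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                  file.path(base, p))
    vols <- purrr::map2(man$volume, man$id,
                        function(p, id) read_volume(resolve(p), id = id))
    masks <- NULL
    if ("mask" %in% names(man) && any(!is.na(man$mask))) {
      masks <- purrr::map2(man$mask, man$id, function(p, id) {
        if (is.na(p) || !nzchar(p)) NULL else read_seg_mask(resolve(p), id = id)
      })
    }
    if (is.null(features) && "features" %in% names(man)) {
      fpaths <- unique(stats::na.omit(man$features))
      if (length(fpaths) > 1L) {
        abort(sprintf("manifest '%s': expected one feature CSV, got %d",
                      path, length(fpaths)))
      }
      if (length(fpaths) == 1L) features <- resolve(fpaths)
    }
    idx <- dataset_index(vols, masks = masks, role = role)
  }
  if (!is.null(features)) idx <- attach_features(idx, features)
  idx
}

#' Attach precomputed feature vectors to an index
#'
#' @param index A `replica_index`.
#' @param path Feature CSV: first column `id`, remaining columns numeric.
#' @return The index with its `features` list-column filled.
#' @export
attach_features <- function(index, path) {
  ft <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(ft)[1] <- "id"
  missing <- setdiff(index$id, ft$id)
  if (length(missing)) {
    abort(sprintf("feature CSV '%s' is missing ids: %s", path,
                  paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(ft[-1])
  if (!is.numeric(mat) || !all(is.finite(mat))) {
    abort(sprintf("feature CSV '%s' must be entirely finite numeric", path))
  }
  rows <- match(index$id, ft$id)
  index$features <- lapply(rows, function(r) as.numeric(mat[r, ]))
  index
}

index_role <- function(index) attr(index, "role", exact = TRUE)

# keep class/attributes through dplyr verbs used internally
#' @export
`[.replica_index` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "volume") %in% names(out))) {
    attr(out, "role") <- attr(x, "role")
    class(out) <- class(x)
  }
  out
}
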