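# Extractor registry: feature-level analysis is extractor-agnostic. The
# built-in pooled descriptor needs no pretrained weights; adapters for
# external models plug in here, and precomputed embeddings can be attached
# to an index from CSV instead (attach_features()).
.extractors <- new.env(parent = emptyenv())

#' Register a feature extractor
#'
#' An extractor is a function `function(volume, ...)` returning a numeric
#' vector of fixed length for a fixed configuration. Registered extractors
#' are addressed by name in [extract_features()] and the pipeline
#' functions.
#'
#' @param name Extractor name.
#' @param fn Function taking a `replica_volume` plus configuration
#'   arguments and returning a numeric vector.
#' @return `name`, invisibly.
#' @export
register_extractor <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .extractors)
  invisible(name)
}

#' List registered feature extractors
#' @return Character vector of extractor names.
#' @export
list_extractors <- function() sort(ls(.extractors))

#' Extract a feature vector from a volume
#'
#' Deterministic for a fixed extractor configuration and input. The result
#' carries attributes `extractor_id` (name plus configuration) and
#' `source_id` (the volume id).
#'
#' @param v A `replica_volume`.
#' @param extractor Name of a registered extractor (default the built-in
#'   `"pooled"` descriptor).
#' @param ... Configuration passed to the extractor.
#' @return Numeric feature vector with attributes `extractor_id`,
#'   `source_id`.
#' @export
extract_features <- function(v, extractor = "pooled", ...) {
  stopifnot(inherits(v, "replica_volume"))
  if (!exists(extractor, envir = .extractors, inherits = FALSE)) {
    abort(sprintf("unknown extractor '%s'; registered: %s", extractor,
                  paste(list_extractors(), collapse = ", ")),
          class = "replicheck_unknown_extractor")
  }
  fn <- get(extractor, envir = .extractors)
  out <- tryCatch(fn(v, ...), error = function(e) {
    abort(sprintf("extractor '%s' failed on volume '%s': %s", extractor,
                  v$id, conditionMessage(e)))
  })
  out <- as.numeric(out)
  if (length(out) == 0L || !all(is.finite(out))) {
    abort(sprintf("extractor '%s' produced a non-finite or empty vector",
                  extractor))
  }
  cfg <- list(...)
  cfg_str <- if (length(cfg)) {
    paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                             character(1)),
          sep = "=", collapse = ";")
  } else ""
  structure(out,
            extractor_id = paste0(extractor, if (nzchar(cfg_str)) "(" else "",
                                  cfg_str, if (nzchar(cfg_str)) ")" else ""),
            source_id = v$id)
}

# block boundaries: n split into nb near-equal blocks, the last block
# absorbing the remainder
block_bounds <- function(n, nb) {
  base <- n %/% nb
  sizes <- rep(base, nb)
  sizes[nb] <- sizes[nb] + n - base * nb
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Built-in pooled pyramid descriptor
#'
#' A deterministic stand-in feature extractor requiring no pretrained
#' weights. The volume is first min-max scaled to `[0, 1]` (a constant
#' volume maps to all zeros), then for each pyramid level `l = 1..levels`
#' it is partitioned into `2^l` blocks per axis (boundary blocks absorb
#' remainders) and the per-block mean and population standard deviation are
#' recorded. The vector concatenates, level by level, all block means
#' followed by all block standard deviations, blocks in array (first axis
#' fastest) order. Level 1 alone yields 8 blocks x 2 statistics = 16
#' elements.
#'
#' @param v A `replica_volume`.
#' @param levels Number of pyramid levels; requires `2^levels <=` the
#'   shortest axis. Default 2.
#' @return Numeric vector of length `sum(2 * 8^l)` over levels.
#' @export
pooled_descriptor <- function(v, levels = 2L) {
  stopifnot(inherits(v, "replica_volume"))
  levels <- as.integer(levels)
  d <- dim(v$data)
  if (levels < 1L) abort("levels must be >= 1")
  if (2^levels > min(d)) {
    abort(sprintf("levels=%d needs 2^%d <= shortest axis (%d)", levels,
                  levels, min(d)))
  }
  x <- v$data
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else
    array(0, d)
  out <- numeric(0)
  for (l in seq_len(levels)) {
    nb <- 2L^l
    bx <- block_bounds(d[1], nb)
    by <- block_bounds(d[2], nb)
    bz <- block_bounds(d[3], nb)
    means <- numeric(nb^3)
    sds <- numeric(nb^3)
    i <- 1L
    for (k in seq_len(nb)) for (j in seq_len(nb)) for (ii in seq_len(nb)) {
      blk <- x[bx[ii, 1]:bx[ii, 2], by[j, 1]:by[j, 2], bz[k, 1]:bz[k, 2]]
      means[i] <- mean(blk)
      sds[i] <- sqrt(mean((blk - means[i])^2))
      i <- i + 1L
    }
    out <- c(out, means, sds)
  }
  out
}

register_extractor("pooled", pooled_descriptor)

# feature vector for one index entry: stored features win, else extract
entry_features <- function(index, i, extractor = "pooled", ...) {
  ft <- index$features[[i]]
  if (!is.null(ft)) return(as.numeric(ft))
  as.numeric(extract_features(index$volume[[i]], extractor = extractor, ...))
}

#' Write feature vectors for an index to CSV
#'
#' Exports one row per entry (first column `id`, remaining columns
#' numeric), the same format [attach_features()] ingests.
#'
#' @param index A `replica_index`.
#' @param path Output CSV path.
#' @param extractor Extractor used for entries without stored features.
#' @return `path`, invisibly.
#' @export
write_features <- function(index, path, extractor = "pooled") {
  feats <- lapply(seq_len(nrow(index)),
                  function(i) entry_features(index, i, extractor))
  len <- unique(lengths(feats))
  if (length(len) != 1L) abort("feature vectors have inconsistent lengths")
  mat <- do.call(rbind, feats)
  df <- tibble::as_tibble(as.data.frame(mat, optional = TRUE),
                          .name_repair = "minimal")
  names(df) <- paste0("f", seq_len(ncol(df)))
  readr::write_csv(dplyr::bind_cols(tibble::tibble(id = index$id), df), path)
  invisible(path)
}
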