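#' Specify a similarity/distance measure
#'
#' The framework compares images at three levels, each with a fixed set of
#' measures: image level (`mae`, `rmse`, `ssim`), feature level
#' (`feat_rmse`, `feat_cosine`) and segmentation level (`dice`, `asd`). The
#' name determines the level; `params` carries measure-specific settings.
#'
#' @param name One of `"mae"`, `"rmse"`, `"ssim"`, `"feat_rmse"`,
#'   `"feat_cosine"`, `"dice"`, `"asd"`.
#' @param params Named list of settings. For `ssim`: `window` (odd voxel
#'   count, default 7), `k1` (default 0.01), `k2` (default 0.03). For `dice`
#'   / `asd`: `label` (single positive label, default 1) or `labels` (label
#'   set for macro-averaged multiclass comparison).
#' @return A `measure_spec` object with fields `name`, `level`, `params`.
#' @examples
#' measure_spec("ssim", params = list(window = 5))
#' @export
measure_spec <- function(name, params = list()) {
  levels <- c(mae = "image", rmse = "image", ssim = "image",
              feat_rmse = "feature", feat_cosine = "feature",
              dice = "segmentation", asd = "segmentation")
  name <- match.arg(name, names(levels))
  defaults <- switch(name,
    ssim = list(window = 7L, k1 = 0.01, k2 = 0.03),
    dice = list(label = 1L),
    asd  = list(label = 1L),
    list())
  params <- utils::modifyList(defaults, params)
  structure(list(name = name, level = unname(levels[name]), params = params),
            class = "measure_spec")
}

as_measure_spec <- function(x) {
  if (inherits(x, "measure_spec")) x else measure_spec(x)
}

#' @export
print.measure_spec <- function(x, ...) {
  cat(sprintf("<measure_spec %s (%s-level)>\n", x$name, x$level))
  invisible(x)
}

measure_data <- function(x) {
  if (inherits(x, "replica_volume")) x$data
  else if (inherits(x, "replica_segmask")) x$labels
  else if (is.array(x) && length(dim(x)) == 3L) x
  else abort("expected a volume, mask or 3D array")
}

check_same_grid <- function(a, b, spacing = FALSE) {
  da <- measure_data(a); db <- measure_data(b)
  if (!identical(dim(da), dim(db))) {
    abort(sprintf("shape mismatch: %s vs %s",
                  paste(dim(da), collapse = "x"),
                  paste(dim(db), collapse = "x")),
          class = "replicheck_grid_mismatch")
  }
  if (spacing && inherits(a, c("replica_volume", "replica_segmask")) &&
      inherits(b, c("replica_volume", "replica_segmask"))) {
    sa <- a$spacing; sb <- b$spacing
    if (max(abs(sa - sb)) > 1e-6) {
      abort("spacing mismatch between compared images",
            class = "replicheck_grid_mismatch")
    }
  }
  invisible(NULL)
}

#' Voxel-wise image measures
#'
#' `mae()` is the mean absolute voxel difference, `rmse()` the root mean
#' squared voxel difference. Both are symmetric, zero iff the volumes are
#' identical, and require a shared grid.
#'
#' @param a,b `replica_volume` objects (or bare 3D arrays) on the same grid.
#' @return Non-negative scalar.
#' @export
mae <- function(a, b) {
  check_same_grid(a, b)
  mean(abs(measure_data(a) - measure_data(b)))
}

#' @rdname mae
#' @export
rmse <- function(a, b) {
  check_same_grid(a, b)
  sqrt(mean((measure_data(a) - measure_data(b))^2))
}

# column-wise cumulative sums, row-vectorized (fast for short columns)
col_cumsum <- function(m) {
  n <- nrow(m)
  if (n > 1L) for (i in 2:n) m[i, ] <- m[i - 1L, ] + m[i, ]
  m
}

# sliding-window sums over all fully-contained windows, separable per axis
box_sum_valid <- function(x, w) {
  for (ax in 1:3) {
    d <- dim(x)
    n <- d[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(x, perm), nrow = n)
    cs <- col_cumsum(m)
    top <- cs[w:n, , drop = FALSE]
    bot <- rbind(0, cs[seq_len(n - w), , drop = FALSE])
    out <- top - bot
    x <- aperm(array(out, c(n - w + 1L, d[perm[2]], d[perm[3]])),
               order(perm))
  }
  x
}

#' 3D structural similarity (SSIM)
#'
#' Mean of the local SSIM map computed with a uniform (boxcar) 3D sliding
#' window over all fully-contained window positions. Local means, variances
#' and covariance use population (divide-by-N) normalization. The data range
#' is the joint `max - min` over both volumes; the stabilizers are
#' `c1 = (k1 * L)^2`, `c2 = (k2 * L)^2`.
#'
#' @inheritParams mae
#' @param window Odd window side length in voxels; must fit within every
#'   axis. Default 7.
#' @param k1,k2 Stabilizer constants, defaults 0.01 and 0.03.
#' @return Scalar in `[-1, 1]`; 1 iff `a` and `b` are identical (and
#'   non-constant).
#' @export
ssim3d <- function(a, b, window = 7L, k1 = 0.01, k2 = 0.03) {
  check_same_grid(a, b)
  da <- measure_data(a); db <- measure_data(b)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("ssim window must be a positive odd integer")
  }
  if (any(dim(da) < window)) {
    abort(sprintf("ssim window %d exceeds an image axis (%s)", window,
                  paste(dim(da), collapse = "x")))
  }
  L <- max(max(da), max(db)) - min(min(da), min(db))
  if (L == 0) {
    if (identical(da, db)) return(1)
    abort("zero data range: both volumes constant but not identical",
          class = "replicheck_zero_range")
  }
  n <- window^3
  mu_a <- box_sum_valid(da, window) / n
  mu_b <- box_sum_valid(db, window) / n
  e_aa <- box_sum_valid(da * da, window) / n
  e_bb <- box_sum_valid(db * db, window) / n
  e_ab <- box_sum_valid(da * db, window) / n
  var_a <- e_aa - mu_a^2
  var_b <- e_bb - mu_b^2
  cov_ab <- e_ab - mu_a * mu_b
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  if (any(den == 0)) {
    abort("degenerate SSIM denominator; use nonzero k1/k2 for constant windows",
          class = "replicheck_zero_range")
  }
  mean(num / den)
}

#' Feature-vector measures
#'
#' Compares two fixed-length feature embeddings. `kind = "feat_rmse"` is the
#' root mean squared element difference; `kind = "feat_cosine"` returns the
#' raw cosine similarity in `[-1, 1]` (convert to a distance with
#' [to_distance()]).
#'
#' @param u,v Numeric vectors of equal length >= 1.
#' @param kind `"feat_rmse"` or `"feat_cosine"`.
#' @return Scalar: non-negative for `feat_rmse`, in `[-1, 1]` for
#'   `feat_cosine`.
#' @export
feature_distance <- function(u, v, kind = c("feat_rmse", "feat_cosine")) {
  kind <- match.arg(kind)
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v) || length(u) < 1L) {
    abort(sprintf("feature length mismatch: %d vs %d", length(u), length(v)))
  }
  if (kind == "feat_rmse") {
    sqrt(mean((u - v)^2))
  } else {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) {
      abort("cosine similarity undefined for an all-zero vector",
            class = "replicheck_zero_vector")
    }
    sum(u * v) / (nu * nv)
  }
}

#' Dice overlap coefficient for one label
#'
#' `2|A n B| / (|A| + |B|)` over voxels equal to `label`. When the label is
#' absent from both masks the masks agree on absence and the Dice is defined
#' as 1.
#'
#' @param a,b `replica_segmask` objects (or integer 3D arrays) on the same
#'   grid.
#' @param label Positive integer label to compare.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b, label = 1L) {
  check_same_grid(a, b)
  fa <- measure_data(a) == label
  fb <- measure_data(b) == label
  na <- sum(fa); nb <- sum(fb)
  if (na + nb == 0L) return(1)
  2 * sum(fa & fb) / (na + nb)
}

# -- anisotropic Euclidean distance transform (separable lower envelope) ----

# 1D squared distance transform with sample spacing s; f holds squared
# distances (Inf = no source). Lower envelope of parabolas.
dt1d_sq <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n + 1L)
  z <- numeric(n + 2L)
  k <- 1L
  v[1] <- fin[1]
  z[1] <- -Inf
  z[2] <- Inf
  s2 <- s * s
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      sec <- ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (sec > z[k]) break
      k <- k - 1L
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- sec
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

# distance (mm) from every voxel to the nearest TRUE voxel
edt3d <- function(mask, spacing) {
  d2 <- array(Inf, dim(mask))
  d2[mask] <- 0
  for (ax in 1:3) {
    dm <- dim(d2)
    n <- dm[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(d2, perm), nrow = n)
    for (col in seq_len(ncol(m))) m[, col] <- dt1d_sq(m[, col], spacing[ax])
    d2 <- aperm(array(m, c(n, dm[perm[2]], dm[perm[3]])), order(perm))
  }
  sqrt(d2)
}

shift_logical <- function(x, ax, delta) {
  out <- array(FALSE, dim(x))
  n <- dim(x)[ax]
  src <- seq_len(n)
  dst <- src + delta
  keep <- dst >= 1L & dst <= n
  ix_src <- list(quote(expr =), quote(expr =), quote(expr =))
  ix_dst <- ix_src
  ix_src[[ax]] <- src[keep]
  ix_dst[[ax]] <- dst[keep]
  out <- do.call(`[<-`, c(list(out), ix_dst,
                          list(do.call(`[`, c(list(x), ix_src)))))
  out
}

# foreground voxels with at least one 6-connected background neighbour;
# the volume boundary counts as background
surface_voxels <- function(fg) {
  interior <- array(TRUE, dim(fg))
  for (ax in 1:3) {
    for (delta in c(-1L, 1L)) {
      interior <- interior & shift_logical(fg, ax, delta)
    }
  }
  fg & !interior
}

#' Symmetric average surface distance (ASD)
#'
#' Mean of the two directed mean surface distances between the border voxels
#' of `label` in the two masks, in millimetres. Surface voxels are
#' foreground voxels with at least one 6-connected background neighbour
#' (the volume boundary counts as background); distances are Euclidean in
#' physical units (voxel offsets scaled by spacing).
#'
#' Degenerate cases are flagged rather than silently numeric: if the label
#' is empty in exactly one mask the result is the image's physical diagonal
#' (a penalty distance) with attribute `flag = "one-sided-empty"`; if empty
#' in both, 0 with `flag = "both-empty"`.
#'
#' @param a,b `replica_segmask` objects on the same grid and spacing.
#' @param label Positive integer label.
#' @return Non-negative scalar (mm), possibly carrying a `flag` attribute.
#' @export
average_surface_distance <- function(a, b, label = 1L) {
  check_same_grid(a, b, spacing = TRUE)
  spacing <- if (inherits(a, "replica_segmask")) a$spacing else c(1, 1, 1)
  fa <- measure_data(a) == label
  fb <- measure_data(b) == label
  ea <- !any(fa); eb <- !any(fb)
  if (ea && eb) return(structure(0, flag = "both-empty"))
  if (ea || eb) {
    diag_mm <- sqrt(sum((dim(measure_data(a)) * spacing)^2))
    return(structure(diag_mm, flag = "one-sided-empty"))
  }
  sa <- surface_voxels(fa)
  sb <- surface_voxels(fb)
  dist_to_b <- edt3d(sb, spacing)
  dist_to_a <- edt3d(sa, spacing)
  d_ab <- mean(dist_to_b[sa])
  d_ba <- mean(dist_to_a[sb])
  (d_ab + d_ba) / 2
}

#' Macro-averaged multiclass segmentation measure
#'
#' Averages the per-label Dice or ASD over the labels present in at least
#' one of the two masks; labels absent from both are skipped. A label empty
#' in exactly one mask contributes its penalty value (Dice 0; ASD physical
#' diagonal).
#'
#' @param a,b `replica_segmask` objects on the same grid.
#' @param labels Non-empty set of positive integer labels.
#' @param base `"dice"` or `"asd"`.
#' @return Scalar macro-average. Per-label values are attached as attribute
#'   `per_label` (named numeric) so users can re-aggregate.
#' @export
multiclass_aggregate <- function(a, b, labels, base = c("dice", "asd")) {
  base <- match.arg(base)
  labels <- unique(as.integer(labels))
  if (length(labels) == 0L) abort("empty label set")
  check_same_grid(a, b)
  la <- measure_data(a); lb <- measure_data(b)
  vals <- c()
  for (lab in labels) {
    present_a <- any(la == lab); present_b <- any(lb == lab)
    if (!present_a && !present_b) next
    v <- if (base == "dice") {
      if (xor(present_a, present_b)) 0 else dice(a, b, label = lab)
    } else {
      as.numeric(average_surface_distance(a, b, label = lab))
    }
    vals <- c(vals, setNames(as.numeric(v), as.character(lab)))
  }
  if (length(vals) == 0L) {
    abort("none of the requested labels is present in either mask")
  }
  structure(mean(vals), per_label = vals)
}

#' Convert a measure value onto the common distance scale
#'
#' Thresholding needs all measures on a consistent distance footing.
#' Similarity measures are min-max mapped from their theoretical range onto
#' `[0, 1]` and subtracted from 1: Dice `v -> 1 - v`; SSIM and cosine
#' similarity `v -> 1 - (v + 1) / 2` (theoretical range `[-1, 1]`). Distance
#' measures (`mae`, `rmse`, `feat_rmse`, `asd`) pass through unchanged. For
#' example a Dice coefficient of 0.7 becomes a distance of 0.3.
#'
#' Values outside the theoretical range by at most 1e-9 (floating-point
#' slop) are clamped; larger violations are an error.
#'
#' @param value Numeric scalar or vector of raw measure values.
#' @param measure A `measure_spec` or measure name.
#' @return Distance value(s): in `[0, 1]` for converted similarities,
#'   unchanged for distances.
#' @export
to_distance <- function(value, measure) {
  spec <- as_measure_spec(measure)
  rng <- switch(spec$name,
    ssim = , feat_cosine = c(-1, 1),
    dice = c(0, 1),
    c(0, Inf))
  tol <- 1e-9
  if (any(value < rng[1] - tol | value > rng[2] + tol)) {
    abort(sprintf("%s value outside theoretical range [%g, %g]",
                  spec$name, rng[1], rng[2]),
          class = "replicheck_out_of_range")
  }
  value <- pmin(pmax(value, rng[1]), rng[2])
  switch(spec$name,
    dice = 1 - value,
    ssim = , feat_cosine = 1 - (value + 1) / 2,
    value)
}

# raw measure value for one pair, dispatched on the spec
compute_raw_measure <- function(spec, syn, train, syn_mask = NULL,
                                train_mask = NULL, syn_feat = NULL,
                                train_feat = NULL) {
  switch(spec$level,
    image = switch(spec$name,
      mae = mae(syn, train),
      rmse = rmse(syn, train),
      ssim = ssim3d(syn, train, window = spec$params$window,
                    k1 = spec$params$k1, k2 = spec$params$k2)),
    feature = feature_distance(syn_feat, train_feat, kind = spec$name),
    segmentation = {
      if (is.null(syn_mask) || is.null(train_mask)) {
        abort(sprintf("segmentation-level measure '%s' requires masks",
                      spec$name),
              class = "replicheck_missing_mask")
      }
      labs <- spec$params$labels
      if (!is.null(labs)) {
        as.numeric(multiclass_aggregate(syn_mask, train_mask, labs,
                                        base = spec$name))
      } else if (spec$name == "dice") {
        dice(syn_mask, train_mask, label = spec$params$label)
      } else {
        as.numeric(average_surface_distance(syn_mask, train_mask,
                                            label = spec$params$label))
      }
    })
}
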