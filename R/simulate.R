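# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed_local <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# hierarchical seed derivation (study -> subject -> stage); exact in double
# arithmetic, result < 2^31
derive_seed <- function(parent, i, stage = 0) {
  ((parent %% 1000000007) * 69069 + i * 30011 + stage * 7919) %% 2147483629
}

# boxcar blur with clamped (edge-shrinking) windows, same-size output
axis_box_blur <- function(x, r, ax) {
  if (r < 1L) return(x)
  d <- dim(x)
  n <- d[ax]
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(x, perm), nrow = n)
  cs <- rbind(0, col_cumsum(m))
  hi <- pmin(n, seq_len(n) + r)
  lo <- pmax(1L, seq_len(n) - r)
  cnt <- hi - lo + 1L
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / cnt
  aperm(array(out, c(n, d[perm[2]], d[perm[3]])), order(perm))
}

box_blur3d <- function(x, r, passes = 2L) {
  for (p in seq_len(passes)) for (ax in 1:3) x <- axis_box_blur(x, r, ax)
  x
}

#' Phantom generator parameters
#'
#' Settings for the anatomy-like phantom volumes used to validate the
#' pipeline without patient data: a smooth random background field (standing
#' in for brain parenchyma) plus bright ellipsoidal lesion-like blobs with
#' matching mask labels.
#'
#' @param grid Voxel grid shape, default `c(32, 32, 16)`.
#' @param spacing Millimetres per voxel, default isotropic 1 mm.
#' @param smoothness Boxcar blur radius (voxels) applied twice per axis to
#'   the background noise field; larger = smoother anatomy. Default 2.
#' @param lesion_count Integer range `c(lo, hi)` of lesions per phantom,
#'   default 1..3.
#' @param lesion_radius Range of per-axis lesion semi-axes in voxels,
#'   default 2..4; must fit inside the grid.
#' @param bg_intensity Intensity range the background field is scaled to,
#'   default `c(0, 0.5)`.
#' @param lesion_intensity Range of additive lesion intensity, default
#'   `c(0.3, 0.6)` so lesions are brighter than background on average.
#' @param binary_mask If `TRUE` all lesions share label 1; otherwise lesion
#'   `k` gets label `k`. Default `FALSE`.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid = c(32L, 32L, 16L), spacing = c(1, 1, 1),
                           smoothness = 2L, lesion_count = c(1L, 3L),
                           lesion_radius = c(2, 4),
                           bg_intensity = c(0, 0.5),
                           lesion_intensity = c(0.3, 0.6),
                           binary_mask = FALSE) {
  check_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) {
      abort(sprintf("%s must be c(lo, hi) with lo <= hi", nm))
    }
  }
  check_range(lesion_count, "lesion_count")
  check_range(lesion_radius, "lesion_radius")
  check_range(bg_intensity, "bg_intensity")
  check_range(lesion_intensity, "lesion_intensity")
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L))
  if (2 * lesion_radius[2] + 1 > min(grid)) {
    abort("largest lesion radius does not fit inside the grid")
  }
  structure(list(grid = grid, spacing = validate_spacing(spacing, "phantom"),
                 smoothness = as.integer(smoothness),
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius,
                 bg_intensity = bg_intensity,
                 lesion_intensity = lesion_intensity,
                 binary_mask = isTRUE(binary_mask)),
            class = "phantom_params")
}

#' Generate one phantom volume with its lesion mask
#'
#' Fully reproducible from `(params, seed)`: the background is a smoothed
#' seeded Gaussian random field min-max scaled to the background intensity
#' range; lesions are additive ellipsoids placed without overlap (bounded
#' retries), each labelled in the mask.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed.
#' @param id Identifier for the volume/mask pair.
#' @return List with elements `volume` (`replica_volume`) and `mask`
#'   (`replica_segmask`).
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1L,
                             id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  with_seed_local(seed, {
    d <- params$grid
    field <- array(stats::rnorm(prod(d)), d)
    field <- box_blur3d(field, params$smoothness)
    rng <- range(field)
    bg <- params$bg_intensity
    field <- if (rng[2] > rng[1]) {
      bg[1] + (field - rng[1]) / (rng[2] - rng[1]) * (bg[2] - bg[1])
    } else array(mean(bg), d)

    labels <- array(0L, d)
    k <- if (params$lesion_count[1] == params$lesion_count[2]) {
      params$lesion_count[1]
    } else {
      sample(seq(params$lesion_count[1], params$lesion_count[2]), 1L)
    }
    coords <- lapply(d, seq_len)
    for (les in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(50L)) {
        radii <- stats::runif(3, params$lesion_radius[1],
                              params$lesion_radius[2])
        lo <- ceiling(radii) + 1
        hi <- d - ceiling(radii)
        if (any(hi < lo)) next
        centre <- vapply(1:3, function(ax) {
          if (hi[ax] == lo[ax]) lo[ax] else sample(seq(lo[ax], hi[ax]), 1L)
        }, numeric(1))
        u1 <- (coords[[1]] - centre[1]) / radii[1]
        u2 <- (coords[[2]] - centre[2]) / radii[2]
        u3 <- (coords[[3]] - centre[3]) / radii[3]
        inside <- outer(outer(u1^2, u2^2, `+`), u3^2, `+`) <= 1
        if (any(labels[inside] != 0L)) next
        amp <- stats::runif(1, params$lesion_intensity[1],
                            params$lesion_intensity[2])
        field[inside] <- field[inside] + amp
        labels[inside] <- if (params$binary_mask) 1L else les
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("infeasible lesion placement after bounded retries",
              class = "replicheck_placement")
      }
    }
    list(volume = volume(field, spacing = params$spacing, id = id),
         mask = seg_mask(labels, spacing = params$spacing, id = id))
  })
}

apply_perturbation <- function(vol, mask, kind, magnitude, seed) {
  d <- dim(vol$data)
  switch(kind,
    none = list(volume = vol, mask = mask),
    gaussian_noise = with_seed_local(seed, {
      noisy <- vol$data + array(stats::rnorm(prod(d), sd = magnitude), d)
      list(volume = volume(noisy, vol$spacing, vol$id), mask = mask)
    }),
    intensity_shift = list(
      volume = volume(vol$data + magnitude, vol$spacing, vol$id),
      mask = mask),
    translation = with_seed_local(seed, {
      if (magnitude != round(magnitude)) {
        abort("translation magnitude must be an integral voxel count")
      }
      ax <- sample(1:3, 1L)
      sgn <- sample(c(-1L, 1L), 1L)
      delta <- as.integer(sgn * magnitude)
      fill <- min(vol$data)
      vdat <- array(fill, d)
      mdat <- array(0L, dim(mask$labels))
      n <- d[ax]
      src <- seq_len(n); dst <- src + delta
      keep <- dst >= 1L & dst <= n
      ix <- function(a, idx) {
        args <- list(quote(expr =), quote(expr =), quote(expr =))
        args[[ax]] <- idx
        do.call(`[`, c(list(a), args))
      }
      assign_ix <- function(a, idx, value) {
        args <- list(quote(expr =), quote(expr =), quote(expr =))
        args[[ax]] <- idx
        do.call(`[<-`, c(list(a), args, list(value)))
      }
      vdat <- assign_ix(vdat, dst[keep], ix(vol$data, src[keep]))
      mdat <- assign_ix(mdat, dst[keep], ix(mask$labels, src[keep]))
      list(volume = volume(vdat, vol$spacing, vol$id),
           mask = seg_mask(mdat, mask$spacing, mask$id))
    }),
    abort(sprintf("unknown perturbation kind '%s'", kind)))
}

#' Generate a planted-replica phantom study
#'
#' Builds a complete desk-scale study: `n_train` training phantoms (volumes
#' plus masks), and `n_synth` "synthetic" volumes of which
#' `round(replica_fraction * n_synth)` are copies of randomly chosen
#' training entries -- perturbed in sequence by `perturbations`
#' (`kind = "none"` means an exact copy) -- and the rest are novel phantoms
#' from fresh seeds. Ground-truth labels (planted copy = replica) and full
#' provenance (source id, perturbation kind and magnitude) are recorded, so
#' every stage of the detection pipeline can be validated against known
#' truth.
#'
#' Masks are perturbed consistently with their volumes: translated along
#' with the volume, unchanged under intensity perturbations.
#'
#' A single study seed drives a hierarchical derivation (study -> subject ->
#' perturbation), so each subject is individually reproducible.
#'
#' @param n_train Number of training phantoms (>= 1).
#' @param n_synth Number of synthetic entries.
#' @param replica_fraction Fraction of synthetic entries planted as
#'   replicas, in `[0, 1]`.
#' @param perturbations List of `list(kind =, magnitude =)` applied in
#'   order to every planted replica; kinds: `"none"`, `"gaussian_noise"`
#'   (magnitude = noise sd), `"intensity_shift"` (additive constant),
#'   `"translation"` (integral voxels; shifted-out voxels cropped, vacated
#'   voxels filled with the volume minimum).
#' @param seed Study seed.
#' @param params [phantom_params()] controlling the phantoms.
#' @return A `replica_study`: list with `training` and `synthetic`
#'   (`replica_index`), `truth` (tibble `id`, `label`), `provenance`
#'   (tibble `synthetic_id`, `source_id`, `kind`, `magnitude`), plus
#'   `params` and `seed`.
#' @export
generate_study <- function(n_train, n_synth, replica_fraction = 0.9,
                           perturbations = list(list(kind = "none",
                                                     magnitude = 0)),
                           seed = 1L, params = phantom_params()) {
  stopifnot(n_train >= 1L, n_synth >= 0L,
            replica_fraction >= 0, replica_fraction <= 1)
  n_rep <- round(replica_fraction * n_synth)
  if (n_rep > 0L && n_train < 1L) {
    abort("replicas requested but training set is empty")
  }
  train_ids <- sprintf("train_%03d", seq_len(n_train))
  train <- lapply(seq_len(n_train), function(i) {
    generate_phantom(params, seed = derive_seed(seed, i, stage = 1),
                     id = train_ids[i])
  })
  training <- dataset_index(lapply(train, `[[`, "volume"),
                            masks = lapply(train, `[[`, "mask"),
                            role = "training")

  syn_ids <- sprintf("synth_%03d", seq_len(n_synth))
  assignment <- with_seed_local(derive_seed(seed, 0, stage = 2), {
    pos <- sample(seq_len(n_synth))
    sources <- if (n_rep > 0) sample(seq_len(n_train), n_rep,
                                     replace = TRUE) else integer(0)
    list(replica_pos = sort(pos[seq_len(n_rep)]), sources = sources)
  })

  vols <- vector("list", n_synth)
  masks <- vector("list", n_synth)
  prov <- vector("list", n_synth)
  rep_slot <- 0L
  for (i in seq_len(n_synth)) {
    if (i %in% assignment$replica_pos) {
      rep_slot <- rep_slot + 1L
      src <- assignment$sources[rep_slot]
      src_row <- match(train_ids[src], training$id)
      v <- training$volume[[src_row]]
      m <- training$mask[[src_row]]
      v <- volume(v$data, v$spacing, id = syn_ids[i])
      m <- seg_mask(m$labels, m$spacing, id = syn_ids[i])
      for (p in seq_along(perturbations)) {
        pert <- perturbations[[p]]
        out <- apply_perturbation(v, m, pert$kind, pert$magnitude,
                                  seed = derive_seed(seed, i,
                                                     stage = 10 + p))
        v <- out$volume; m <- out$mask
      }
      vols[[i]] <- v; masks[[i]] <- m
      prov[[i]] <- tibble::tibble(
        synthetic_id = syn_ids[i], source_id = train_ids[src],
        kind = paste(vapply(perturbations, `[[`, character(1), "kind"),
                     collapse = "+"),
        magnitude = sum(vapply(perturbations, function(p)
          as.numeric(p$magnitude), numeric(1))))
    } else {
      ph <- generate_phantom(params, seed = derive_seed(seed, i, stage = 3),
                             id = syn_ids[i])
      vols[[i]] <- ph$volume; masks[[i]] <- ph$mask
      prov[[i]] <- tibble::tibble(synthetic_id = syn_ids[i],
                                  source_id = "novel", kind = "none",
                                  magnitude = 0)
    }
  }
  provenance <- dplyr::bind_rows(prov)
  truth <- tibble::tibble(
    id = syn_ids,
    label = ifelse(provenance$source_id == "novel", NON_REPLICA, REPLICA))
  synthetic <- if (n_synth > 0) {
    dataset_index(vols, masks = masks, role = "synthetic")
  } else NULL
  structure(list(training = training, synthetic = synthetic, truth = truth,
                 provenance = provenance, params = params, seed = seed),
            class = "replica_study")
}

#' @export
print.replica_study <- function(x, ...) {
  cat(sprintf(
    "<replica_study> %d training / %d synthetic (%d planted replicas), grid %s, seed %s\n",
    nrow(x$training), nrow(x$truth), sum(x$truth$label == REPLICA),
    paste(x$params$grid, collapse = "x"), format(x$seed)))
  invisible(x)
}

#' Write a study to disk in the layout the indexing module consumes
#'
#' Writes NIfTI volumes and masks under `training/` and `synthetic/`
#' subdirectories, manifest CSVs for both sets, the ground-truth CSV
#' (`synthetic_id`, `label`) and the provenance CSV.
#'
#' @param study A `replica_study`.
#' @param out_dir Output directory (created if missing).
#' @return Named list of the manifest, truth and provenance paths.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "replica_study"))
  dir.create(file.path(out_dir, "training"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "synthetic"), recursive = TRUE,
             showWarnings = FALSE)
  write_set <- function(index, sub) {
    rows <- purrr::map_dfr(seq_len(nrow(index)), function(i) {
      vp <- file.path(sub, paste0(index$id[i], ".nii.gz"))
      mp <- file.path(sub, paste0(index$id[i], "_mask.nii.gz"))
      write_volume(index$volume[[i]], file.path(out_dir, vp))
      has_mask <- !is.null(index$mask[[i]])
      if (has_mask) write_volume(index$mask[[i]], file.path(out_dir, mp))
      tibble::tibble(id = index$id[i], volume = vp,
                     mask = if (has_mask) mp else NA_character_)
    })
    man <- file.path(out_dir, paste0(sub, "_manifest.csv"))
    readr::write_csv(rows, man)
    man
  }
  train_man <- write_set(study$training, "training")
  synth_man <- if (!is.null(study$synthetic)) {
    write_set(study$synthetic, "synthetic")
  } else NA_character_
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(dplyr::rename(study$truth, synthetic_id = "id"),
                   truth_path)
  prov_path <- file.path(out_dir, "provenance.csv")
  readr::write_csv(study$provenance, prov_path)
  list(training_manifest = train_man, synthetic_manifest = synth_man,
       truth = truth_path, provenance = prov_path)
}
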