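# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, direct formulas) and share no code
# with the package implementations they check.

rand_volume <- function(seed, dim = c(8, 8, 4), spacing = c(1, 1, 1),
                        id = paste0("v", seed)) {
  set.seed(seed)
  volume(array(runif(prod(dim)), dim), spacing = spacing, id = id)
}

rand_mask <- function(seed, dim = c(8, 8, 4), p = 0.2, labels = 1L,
                      spacing = c(1, 1, 1), id = paste0("m", seed)) {
  set.seed(seed)
  lab <- array(0L, dim)
  pick <- runif(prod(dim)) < p
  lab[pick] <- sample(labels, sum(pick), replace = TRUE)
  seg_mask(lab, spacing = spacing, id = id)
}

# blob-like mask: a filled box at a seeded position, guaranteed non-empty
blob_mask <- function(seed, dim = c(8, 8, 4), spacing = c(1, 1, 1),
                      id = paste0("b", seed)) {
  set.seed(seed)
  lab <- array(0L, dim)
  lo <- sapply(dim, function(n) sample(seq_len(max(1, n - 3)), 1))
  hi <- pmin(dim, lo + sample(1:3, 3, replace = TRUE))
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  seg_mask(lab, spacing = spacing, id = id)
}

oracle_mae <- function(a, b) {
  da <- a$data; db <- b$data
  tot <- 0
  for (i in seq_len(dim(da)[1])) for (j in seq_len(dim(da)[2]))
    for (k in seq_len(dim(da)[3])) tot <- tot + abs(da[i, j, k] - db[i, j, k])
  tot / prod(dim(da))
}

oracle_rmse <- function(a, b) {
  da <- a$data; db <- b$data
  tot <- 0
  for (i in seq_len(dim(da)[1])) for (j in seq_len(dim(da)[2]))
    for (k in seq_len(dim(da)[3])) tot <- tot + (da[i, j, k] - db[i, j, k])^2
  sqrt(tot / prod(dim(da)))
}

# direct-formula SSIM: loop over every fully-contained window, local stats
# by explicit mean/var with population normalization
oracle_ssim <- function(a, b, w, k1 = 0.01, k2 = 0.03) {
  da <- a$data; db <- b$data
  d <- dim(da)
  L <- max(max(da), max(db)) - min(min(da), min(db))
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(d[1] - w + 1)) for (j in seq_len(d[2] - w + 1))
    for (k in seq_len(d[3] - w + 1)) {
      wa <- as.vector(da[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)])
      wb <- as.vector(db[i:(i + w - 1), j:(j + w - 1), k:(k + w - 1)])
      ma <- mean(wa); mb <- mean(wb)
      va <- mean((wa - ma)^2); vb <- mean((wb - mb)^2)
      cab <- mean((wa - ma) * (wb - mb))
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                  ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  mean(vals)
}

oracle_dice <- function(a, b, label = 1L) {
  fa <- a$labels == label; fb <- b$labels == label
  if (sum(fa) + sum(fb) == 0) return(1)
  2 * sum(fa & fb) / (sum(fa) + sum(fb))
}

# surface voxels by explicit neighbour inspection, distances by all-pairs
oracle_surface <- function(fg) {
  d <- dim(fg)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!fg[i, j, k]) next
    nb_bg <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !fg[p[1], p[2], p[3]]) {
        nb_bg <- TRUE
        break
      }
    }
    if (nb_bg) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_asd <- function(a, b, label = 1L) {
  sa <- oracle_surface(a$labels == label)
  sb <- oracle_surface(b$labels == label)
  sp <- a$spacing
  directed <- function(from, to) {
    mean(apply(from, 1, function(p) {
      min(apply(to, 1, function(q) sqrt(sum(((p - q) * sp)^2))))
    }))
  }
  (directed(sa, sb) + directed(sb, sa)) / 2
}

# best balanced accuracy over all midpoints between sorted unique values
# (plus the extremes), under the strict `< T` rule
oracle_best_ba <- function(values, is_replica) {
  u <- sort(unique(values))
  cuts <- c(u[1] - 1, (head(u, -1) + u[-1]) / 2, u[length(u)] + 1, u)
  best <- 0
  for (th in cuts) {
    pred <- values < th
    ba <- (sum(pred & is_replica) / sum(is_replica) +
             sum(!pred & !is_replica) / sum(!is_replica)) / 2
    best <- max(best, ba)
  }
  best
}

small_params <- function(grid = c(16L, 16L, 8L)) {
  phantom_params(grid = grid, lesion_radius = c(1.5, 3))
}

truth_tbl <- function(ids, labels) tibble::tibble(id = ids, label = labels)
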