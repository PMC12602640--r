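test_that("mae and rmse: identity, analytic constants, shape guard", {
  a <- rand_volume(1)
  expect_equal(mae(a, a), 0)
  expect_equal(rmse(a, a), 0)
  zero <- volume(array(0, c(8, 8, 4)), id = "zero")
  one <- volume(array(1, c(8, 8, 4)), id = "one")
  two <- volume(array(2, c(8, 8, 4)), id = "two")
  expect_equal(mae(zero, one), 1)
  expect_equal(rmse(zero, two), 2)
  b5 <- rand_volume(2, dim = c(8, 8, 5))
  expect_error(mae(a, b5), class = "replicheck_grid_mismatch")
})

test_that("mae/rmse match the per-voxel loop oracle; rmse >= mae", {
  for (seed in 1:10) {
    a <- rand_volume(seed * 2)
    b <- rand_volume(seed * 2 + 1)
    expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
    expect_equal(rmse(a, b), oracle_rmse(a, b), tolerance = 1e-12)
    expect_gte(rmse(a, b), mae(a, b))
  }
})

test_that("ssim3d: self-similarity 1, inverted volume < 1, window guard", {
  a <- rand_volume(3)
  expect_equal(ssim3d(a, a, window = 3), 1)
  inv <- volume(1 - a$data, id = "inv")
  expect_lt(ssim3d(a, inv, window = 3), 1)
  expect_error(ssim3d(a, a, window = 5), regexp = "axis")
  expect_error(ssim3d(a, a, window = 4), regexp = "odd")
  c1 <- volume(array(1, c(8, 8, 4)), id = "c1")
  c2 <- volume(array(2, c(8, 8, 4)), id = "c2")
  expect_equal(ssim3d(c1, c1, window = 3), 1)  # identical constants
  expect_error(ssim3d(c1, c2, window = 3, k1 = 0, k2 = 0))
})

test_that("ssim3d matches the direct local-statistics oracle", {
  for (seed in 1:6) {
    a <- rand_volume(seed * 10)
    b <- rand_volume(seed * 10 + 5)
    expect_equal(ssim3d(a, b, window = 3), oracle_ssim(a, b, 3),
                 tolerance = 1e-9)
  }
  # non-default window and constants
  a <- rand_volume(99, dim = c(9, 9, 5))
  b <- rand_volume(100, dim = c(9, 9, 5))
  expect_equal(ssim3d(a, b, window = 5, k1 = 0.02, k2 = 0.05),
               oracle_ssim(a, b, 5, k1 = 0.02, k2 = 0.05),
               tolerance = 1e-9)
})

test_that("feature_distance: identity, orthogonality, analytic cosine", {
  u <- c(1, 2, 3)
  expect_equal(feature_distance(u, u, "feat_cosine"), 1)
  expect_equal(feature_distance(u, u, "feat_rmse"), 0)
  expect_equal(feature_distance(c(1, 0), c(0, 1), "feat_cosine"), 0)
  expect_equal(feature_distance(c(1, 0), c(1, 1), "feat_cosine"),
               1 / sqrt(2))
  expect_error(feature_distance(c(1, 2), c(1, 2, 3)), regexp = "mismatch")
  expect_error(feature_distance(c(0, 0), c(1, 1), "feat_cosine"),
               class = "replicheck_zero_vector")
})

test_that("dice: identity, disjoint, analytic overlap, empty convention", {
  m <- blob_mask(1)
  expect_equal(dice(m, m), 1)
  a <- seg_mask(array(0L, c(8, 8, 4)), id = "a")
  b <- seg_mask(array(0L, c(8, 8, 4)), id = "b")
  a$labels[1:2, 1, 1] <- 1L
  b$labels[5:6, 1, 1] <- 1L
  expect_equal(dice(a, b), 0)
  # |A|=4, |B|=4, |A n B|=2
  a$labels[] <- 0L; b$labels[] <- 0L
  a$labels[1:4, 1, 1] <- 1L
  b$labels[3:6, 1, 1] <- 1L
  expect_equal(dice(a, b), 0.5)
  empty <- seg_mask(array(0L, c(8, 8, 4)), id = "e")
  expect_equal(dice(empty, empty), 1)
})

test_that("ASD: identity, analytic 3-voxel offset, anisotropic spacing", {
  m <- blob_mask(2)
  expect_equal(as.numeric(average_surface_distance(m, m)), 0)
  a <- seg_mask(array(0L, c(8, 8, 4)), id = "a")
  b <- seg_mask(array(0L, c(8, 8, 4)), id = "b")
  a$labels[3, 3, 2] <- 1L
  b$labels[6, 3, 2] <- 1L
  expect_equal(as.numeric(average_surface_distance(a, b)), 3)
  a2 <- seg_mask(a$labels, spacing = c(2, 1, 1), id = "a2")
  b2 <- seg_mask(b$labels, spacing = c(2, 1, 1), id = "b2")
  expect_equal(as.numeric(average_surface_distance(a2, b2)), 6)
})

test_that("ASD degenerate cases are flagged, never silently numeric", {
  m <- blob_mask(3)
  empty <- seg_mask(array(0L, c(8, 8, 4)), id = "e")
  one_sided <- average_surface_distance(m, empty)
  expect_equal(attr(one_sided, "flag"), "one-sided-empty")
  expect_equal(as.numeric(one_sided), sqrt(sum((c(8, 8, 4) * c(1, 1, 1))^2)))
  both <- average_surface_distance(empty, empty)
  expect_equal(as.numeric(both), 0)
  expect_equal(attr(both, "flag"), "both-empty")
})

test_that("ASD matches the all-pairs surface-voxel oracle", {
  for (seed in 1:8) {
    a <- blob_mask(seed * 3)
    b <- blob_mask(seed * 3 + 1)
    expect_equal(as.numeric(average_surface_distance(a, b)),
                 oracle_asd(a, b), tolerance = 1e-9)
  }
  # anisotropic spacing
  a <- blob_mask(50, spacing = c(1, 2, 0.5))
  b <- blob_mask(51, spacing = c(1, 2, 0.5))
  expect_equal(as.numeric(average_surface_distance(a, b)),
               oracle_asd(a, b), tolerance = 1e-9)
})

test_that("multiclass aggregate: identity, analytic mean, recomposition", {
  m <- rand_mask(4, labels = 1:3)
  expect_equal(as.numeric(multiclass_aggregate(m, m, 1:3, "dice")), 1)
  for (seed in 5:8) {
    a <- rand_mask(seed, labels = 1:3, p = 0.3)
    b <- rand_mask(seed + 100, labels = 1:3, p = 0.3)
    agg <- multiclass_aggregate(a, b, 1:3, "dice")
    per <- vapply(1:3, function(l) dice(a, b, label = l), numeric(1))
    expect_equal(as.numeric(agg), mean(per), tolerance = 1e-12)
    expect_equal(unname(attr(agg, "per_label")), per, tolerance = 1e-12)
  }
  # labels absent from both masks are skipped
  a <- blob_mask(9); b <- blob_mask(10)
  agg <- multiclass_aggregate(a, b, c(1L, 7L), "dice")
  expect_equal(as.numeric(agg), dice(a, b, 1L))
  expect_error(multiclass_aggregate(a, b, integer(0), "dice"),
               regexp = "empty")
})

test_that("to_distance: printed conversion, endpoints, pass-through, clamp", {
  expect_equal(to_distance(0.7, "dice"), 0.3)
  expect_equal(to_distance(1, "ssim"), 0)
  expect_equal(to_distance(-1, "feat_cosine"), 1)
  expect_equal(to_distance(2.5, "rmse"), 2.5)
  expect_equal(to_distance(1 + 1e-10, "dice"), 0)  # clamped
  expect_error(to_distance(1.1, "dice"), class = "replicheck_out_of_range")
  expect_error(to_distance(-0.5, "rmse"), class = "replicheck_out_of_range")
})

test_that("to_distance is monotone decreasing in similarity", {
  for (nm in c("dice", "ssim", "feat_cosine")) {
    lo <- if (nm == "dice") 0 else -1
    v <- seq(lo, 1, length.out = 21)
    d <- to_distance(v, nm)
    expect_true(all(diff(d) < 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  v <- seq(0, 5, length.out = 11)
  expect_equal(to_distance(v, "mae"), v)
})

test_that("image measures are symmetric under argument swap", {
  for (seed in 1:5) {
    a <- rand_volume(seed * 7)
    b <- rand_volume(seed * 7 + 3)
    expect_equal(mae(a, b), mae(b, a))
    expect_equal(rmse(a, b), rmse(b, a))
    expect_equal(ssim3d(a, b, window = 3), ssim3d(b, a, window = 3),
                 tolerance = 1e-12)
  }
  ma <- blob_mask(20); mb <- blob_mask(21)
  expect_equal(dice(ma, mb), dice(mb, ma))
  expect_equal(as.numeric(average_surface_distance(ma, mb)),
               as.numeric(average_surface_distance(mb, ma)))
})

test_that("measures degrade monotonically with added noise", {
  sigmas <- c(0.02, 0.05, 0.1, 0.2)
  mean_mae <- mean_rmse <- mean_ssim <- numeric(length(sigmas))
  for (s in seq_along(sigmas)) {
    maes <- rmses <- ssims <- numeric(10)
    for (r in 1:10) {
      a <- rand_volume(1000 + r, dim = c(12, 12, 6))
      set.seed(2000 + s * 100 + r)
      b <- volume(a$data + array(rnorm(prod(dim(a$data)), sd = sigmas[s]),
                                 dim(a$data)), id = "noisy")
      maes[r] <- mae(a, b)
      rmses[r] <- rmse(a, b)
      ssims[r] <- ssim3d(a, b, window = 3)
    }
    mean_mae[s] <- mean(maes)
    mean_rmse[s] <- mean(rmses)
    mean_ssim[s] <- mean(ssims)
  }
  expect_identical(order(mean_mae), seq_along(sigmas))
  expect_identical(order(mean_rmse), seq_along(sigmas))
  expect_identical(order(-mean_ssim), seq_along(sigmas))
})
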