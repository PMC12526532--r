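test_that("trajectories satisfy the cumulative-sum identity", {
  tr <- generate_trajectory(blur_spec(0.75, n_steps = 200, seed = 3))
  # independent recomputation of the partial sums
  z <- cumsum(tr$steps * exp(1i * tr$angles))
  scale <- Mod(tr$positions[200]) / Mod(z[200])
  expect_lt(max(Mod(tr$positions - z * scale)), 1e-9)
  # stepwise identity z_j - z_{j-1} = s_j exp(i theta_j)
  expect_lt(max(Mod(diff(c(0, tr$positions)) -
                      tr$steps * exp(1i * tr$angles))), 1e-12)
  expect_true(all(tr$steps >= 0))
  expect_lte(max(Mod(tr$positions)),
             blur_spec(0.75)$max_extent + 1e-12)
})

test_that("trajectory generation is seeded and degenerate at intensity 0", {
  s <- blur_spec(0.6, n_steps = 150, seed = 7)
  expect_identical(generate_trajectory(s), generate_trajectory(s))
  tr0 <- generate_trajectory(blur_spec(0, n_steps = 50, seed = 9))
  headings <- Arg(diff(tr0$positions))
  expect_lt(max(abs(diff(headings))), 1e-9)
})

test_that("invalid blur specifications are rejected", {
  expect_error(blur_spec(-0.1), "intensity")
  expect_error(blur_spec(NaN), "intensity")
  expect_error(blur_spec(0.5, n_steps = 0), "n_steps")
  expect_error(blur_spec(0.5, kernel_size = 10), "kernel_size")
  expect_error(blur_spec(0.5, smoothing_sigma = -1), "smoothing_sigma")
  expect_error(blur_spec(0.5, max_extent = 0), "max_extent")
})

test_that("step length and turning angle grow with intensity", {
  intensities <- c(0, 0.25, 0.5, 0.75, 1)
  stats <- sapply(intensities, function(i) {
    per_seed <- sapply(1:50, function(s) {
      tr <- generate_trajectory(blur_spec(i, n_steps = 300, seed = s))
      c(mean(tr$steps), mean(abs(diff(tr$angles))))
    })
    rowMeans(per_seed)
  })
  expect_true(all(diff(stats[1, ]) >= 0))
  expect_true(all(diff(stats[2, ]) >= 0))
})

test_that("PSF rasterization conserves mass and handles the delta case", {
  point <- structure(list(positions = 0 + 0i, steps = 0, angles = 0,
                          intensity = 0), class = "motion_trajectory")
  d <- trajectory_to_psf(point, 7, smoothing_sigma = 0)
  expect_equal(d[4, 4], 1)
  expect_equal(sum(d), 1)
  for (i in c(0.2, 0.5, 0.9)) {
    tr <- generate_trajectory(blur_spec(i, n_steps = 400, seed = 11))
    k <- trajectory_to_psf(tr, 31, 1.0)
    expect_true(all(k >= 0))
    expect_lt(abs(sum(k) - 1), 1e-9)
  }
})

test_that("a straight horizontal trajectory rasterizes onto one row", {
  n <- 60
  pos <- complex(real = seq(0.1, 6, length.out = n), imaginary = 0)
  tr <- structure(list(positions = pos,
                       steps = Mod(diff(c(0, pos))),
                       angles = rep(0, n), intensity = 0),
                  class = "motion_trajectory")
  k <- trajectory_to_psf(tr, 11, smoothing_sigma = 0)
  centre <- 6L
  expect_gte(sum(k[centre, ]), 0.95)
  # independent check: y-offsets of all samples sit on the centre row
  expect_true(all(abs(Im(pos - mean(pos))) < 0.5))
})

test_that("oversized trajectories produce an extent error naming a size", {
  pos <- complex(real = c(-20, 20), imaginary = c(0, 0))
  tr <- structure(list(positions = pos, steps = c(20, 40),
                       angles = c(pi, 0), intensity = 1),
                  class = "motion_trajectory")
  expect_error(trajectory_to_psf(tr, 9, 0), "kernel_size of at least")
})

test_that("motion blur has delta/constant fixed points and matches dense
           convolution", {
  sc <- make_scene(1, 32)
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  expect_lt(max(abs(apply_motion_blur(sc, delta) - sc)), 1e-12)
  const <- array(0.42, c(24, 24, 3))
  psf <- trajectory_to_psf(
    generate_trajectory(blur_spec(0.5, n_steps = 300, kernel_size = 9,
                                  seed = 2)), 9, 1)
  expect_lt(max(abs(apply_motion_blur(const, psf) - 0.42)), 1e-12)
  blurred <- apply_motion_blur(sc, psf)
  for (c in 1:3)
    expect_lt(max(abs(blurred[, , c] -
                        naive_conv2_reflect(sc[, , c], psf))), 1e-6)
})

test_that("box blur preserves the per-channel mean of textured images", {
  sc <- make_scene(5, 64)
  box <- matrix(1 / 81, 9, 9)
  blurred <- apply_motion_blur(sc, box)
  for (c in 1:3)
    expect_lt(abs(mean(blurred[, , c]) - mean(sc[, , c])), 1e-3)
})

test_that("blur rejects invalid kernels and oversized PSFs", {
  sc <- make_scene(1, 32)
  expect_error(apply_motion_blur(sc, matrix(1, 41, 41) / 41^2),
               "larger than the image")
  expect_error(apply_motion_blur(sc, matrix(1, 3, 3)), "unit mass")
  expect_error(apply_motion_blur(sc + 9, matrix(1 / 9, 3, 3)), "\\[0, 1\\]")
})

test_that("augmentation yields mirror, rotation and brightness variants", {
  img <- array(runif(2 * 2 * 3), c(2, 2, 3))
  v <- augment_sharp(img, seed = 1)
  expect_length(v, 3L)
  expect_identical(v$flip, img[, 2:1, , drop = FALSE])
  v1 <- augment_sharp(img, seed = 1, brightness_factor = 1)
  expect_equal(v1$brightness, img)
  sc <- make_scene(2, 48)
  vr <- augment_sharp(sc, seed = 3)
  expect_equal(dim(vr$rotate), dim(sc))
  expect_false(identical(vr$rotate, sc))
  expect_true(all(vr$rotate >= 0 & vr$rotate <= 1))
})

test_that("dataset splits follow the 8:1:1 arithmetic and partition ids", {
  sizes <- table(aggdeblur:::assign_splits(4000, c(0.8, 0.1, 0.1), 1))
  expect_equal(unname(sizes[c("train", "val", "test")]),
               c(3200L, 400L, 400L), ignore_attr = TRUE)
  imgs <- lapply(1:10, function(s) make_scene(s, 32))
  ds <- build_paired_dataset(imgs, seed = 4,
                             blur_args = list(kernel_size = 9,
                                              n_steps = 200))
  tab <- table(ds$manifest$split)
  expect_equal(unname(tab[c("train", "val", "test")]), c(8L, 1L, 1L),
               ignore_attr = TRUE)
  expect_false(any(duplicated(ds$manifest$id)))
  expect_setequal(ds$manifest$id, names(ds$pairs))
  ds2 <- build_paired_dataset(imgs, seed = 4,
                              blur_args = list(kernel_size = 9,
                                               n_steps = 200))
  expect_identical(ds$manifest, ds2$manifest)
  for (p in ds$pairs) {
    expect_identical(dim(p$sharp), dim(p$blurred))
    expect_true(all(p$blurred >= 0 & p$blurred <= 1))
  }
  expect_error(build_paired_dataset(list()), "empty")
  expect_error(build_paired_dataset(imgs, ratios = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("synthetic scenes are deterministic, bounded and sharp", {
  expect_identical(make_scene(0), make_scene(0))
  sc <- generate_synthetic_scene(128, 128, seed = 1)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(generate_synthetic_scene(31, 64), "at least 32")
  lv <- sapply(1:10, function(s) {
    sc <- make_scene(s, 48)
    b <- synthesize_blur(sc, blur_spec(0.5, n_steps = 300, kernel_size = 11,
                                       seed = 50 + s))$blurred
    laplacian_variance(sc) > laplacian_variance(b)
  })
  expect_true(all(lv))
})
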