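test_that("native metrics have exact perfect-reference fixed points", {
  sc <- make_scene(3, 64)
  expect_equal(ms_ssim(sc, sc), 1, tolerance = 1e-6)
  expect_equal(fsim(sc, sc), 1, tolerance = 1e-6)
  expect_equal(vsi(sc, sc), 1, tolerance = 1e-6)
  expect_lt(gmsd(sc, sc), 1e-6)
  expect_lt(nlpd(sc, sc), 1e-6)
})

test_that("MS-SSIM equals a literal SSIM product over the 5-level weights", {
  sc <- make_scene(7, 64)
  b <- synthesize_blur(sc, blur_spec(0.4, n_steps = 300, kernel_size = 11,
                                     seed = 1))$blurred
  # independent oracle: dense-convolution SSIM maps composed literally
  lum <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] +
    0.114 * img[, , 3]
  gwin <- function(size, sigma) {
    r <- (size - 1) / 2
    g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- outer(g, g); k / sum(k)
  }
  pool2 <- function(m) {
    h <- nrow(m) - nrow(m) %% 2; w <- ncol(m) - ncol(m) %% 2
    m <- m[1:h, 1:w]
    0.25 * (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
              m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)])
  }
  x <- lum(sc); y <- lum(b)
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  vals <- numeric(5)
  for (j in 1:5) {
    size <- min(11, 2 * ((min(dim(x)) - 1) %/% 2) + 1)
    win <- gwin(size, 1.5 * size / 11)
    mx <- naive_conv2_reflect(x, win); my <- naive_conv2_reflect(y, win)
    sx <- naive_conv2_reflect(x * x, win) - mx^2
    sy <- naive_conv2_reflect(y * y, win) - my^2
    sxy <- naive_conv2_reflect(x * y, win) - mx * my
    l <- (2 * mx * my + 0.01^2) / (mx^2 + my^2 + 0.01^2)
    cs <- (2 * sxy + 0.03^2) / (sx + sy + 0.03^2)
    vals[j] <- if (j < 5) mean(cs) else mean(l * cs)
    if (j < 5) { x <- pool2(x); y <- pool2(y) }
  }
  oracle <- prod(pmax(vals, 0)^w5)
  expect_equal(ms_ssim(sc, b), oracle, tolerance = 1e-6)
})

test_that("metrics degrade monotonically with blur intensity", {
  cmp <- sapply(1:10, function(s) {
    sc <- make_scene(s, 64)
    b25 <- synthesize_blur(sc, blur_spec(0.25, n_steps = 300, seed = s))
    b75 <- synthesize_blur(sc, blur_spec(0.75, n_steps = 300, seed = s))
    c(ms25 = ms_ssim(sc, b25$blurred), ms75 = ms_ssim(sc, b75$blurred))
  })
  expect_lt(median(cmp["ms75", ]), median(cmp["ms25", ]))
  expect_gt(mean(cmp["ms75", ] < cmp["ms25", ]), 0.7)
})

test_that("composite score is non-increasing in blur intensity", {
  with_learned_mocks({
    med <- sapply(c(0, 0.25, 0.5, 0.75), function(i) {
      vals <- sapply(1:10, function(s) {
        sc <- make_scene(s, 64)
        b <- synthesize_blur(sc, blur_spec(i, seed = 100 + s))$blurred
        iqa_report(sc, b)$composite
      })
      median(vals)
    })
    expect_true(all(diff(med) <= 0))
  })
})

test_that("normalization maps similarities and distances to [0, 1]", {
  expect_equal(normalize_metric("MS-SSIM", 1.0), 1.0)
  expect_equal(normalize_metric("MS-SSIM", 1.7), 1.0)
  expect_equal(normalize_metric("GMSD", 0.0), 1.0)
  expect_equal(normalize_metric("GMSD", 0.35), 0.0)
  expect_equal(normalize_metric("NLPD", 1.0), 0.0)
  expect_equal(normalize_metric("LPIPS", 0.25), 0.75)
  expect_error(normalize_metric("XYZ", 0.5), "unknown")
  expect_error(normalize_metric("GMSD", NaN), "finite")
})

test_that("composite score reproduces the published row averages", {
  expect_equal(composite_score(c(0.911, 0.766, 0.971, 0.863, 0.914,
                                 0.860, 0.697)), 0.855)
  expect_equal(composite_score(c(0.723, 0.638, 0.868, 0.472, 0.679,
                                 0.783, 0.546)), 0.673)
  expect_equal(composite_score(rep(1, 7)), 1.0)
  expect_error(composite_score(rep(0.5, 6)), "seven")
  expect_error(composite_score(c(rep(0.5, 6), 1.2)), "\\[0, 1\\]")
})

test_that("severity bands partition [0, 1] with left-closed boundaries", {
  expect_identical(severity_band(0.595), "severe")
  expect_identical(severity_band(0.671), "moderate")
  expect_identical(severity_band(0.765), "mild")
  expect_identical(severity_band(0.848), "sharp")
  expect_identical(severity_band(0.600), "moderate")
  expect_identical(severity_band(0.700), "mild")
  expect_identical(severity_band(0.800), "sharp")
  expect_identical(severity_band(0), "severe")
  expect_identical(severity_band(1), "sharp")
  expect_error(severity_band(1.2), "\\[0, 1\\]")
  # no gaps, no overlaps
  grid <- seq(0, 1, by = 0.001)
  bands <- vapply(grid, severity_band, character(1))
  expect_true(all(bands %in% c("severe", "moderate", "mild", "sharp")))
  expect_identical(rle(bands)$values, c("severe", "moderate", "mild",
                                        "sharp"))
})

test_that("paired comparison matches hand-computed t statistics", {
  pc <- paired_comparison(c(1, 2, 3), c(0, 2, 2))
  expect_equal(pc$t_stat, 2)
  expect_identical(pc$df, 2L)
  expect_equal(pc$p_value, 0.1835034, tolerance = 1e-6)
  v <- c(-3, -1, 1, 3) * 0.02 / sd(c(-3, -1, 1, 3))
  pc2 <- paired_comparison(v + 1, rep(1, 4))
  expect_equal(pc2$ci95_a, qt(0.975, 3) * 0.02 / 2, tolerance = 1e-12)
  same <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))
  expect_equal(same$mean_a - same$mean_b, 0)
  expect_error(paired_comparison(1:3, 1:4), "equal length")
  expect_error(paired_comparison(1, 1), "at least two")
})

test_that("learned metrics demand a backend and accept mocks", {
  sc <- make_scene(2, 32)
  expect_false(iqa_backend_available("DISTS"))
  expect_error(compute_raw_metric("DISTS", sc, sc), "backend")
  expect_error(iqa_report(sc, sc), "backend")
  with_learned_mocks({
    expect_true(iqa_backend_available("LPIPS"))
    expect_equal(compute_raw_metric("LPIPS", sc, sc), 0)
    rep_ <- iqa_report(sc, sc)
    expect_equal(rep_$composite, 1.0)
    expect_identical(rep_$severity, "sharp")
    expect_equal(rep_$composite, mean(rep_$per_metric$normalized))
  })
  expect_false(iqa_backend_available("DISTS"))
})

test_that("metric preconditions are enforced", {
  sc <- make_scene(1, 64)
  expect_error(compute_raw_metric("MS-SSIM", sc, sc[1:32, , ]),
               "identical shape")
  tiny <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_error(ms_ssim(tiny, tiny), "pyramid")
  expect_error(compute_raw_metric("SSIM2", sc, sc), "unknown")
})
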