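test_that("content loss follows the 0.7/0.3 weighting", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  expect_equal(as.numeric(content_loss(x, x)), 0)
  shifted <- x * 0 + 0.5
  base <- x * 0 + 0.4
  # identity extractor, uniform +0.1 offset: 0.7*0.01 + 0.3*0.1
  expect_equal(as.numeric(content_loss(shifted, base)), 0.037)
  # component arithmetic: L_p = 1, L_1 = 1 -> 0.7 + 0.3
  expect_equal(as.numeric(content_loss(base + 1, base)), 1)
  expect_error(content_loss(x, array(0, c(4, 4, 3, 1))), "shape")
})

test_that("content loss components and gradient are exact", {
  set.seed(1)
  x <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  y <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  cl <- content_loss(x, y)
  expect_equal(attr(cl, "l_p"), mean((x - y)^2))
  expect_equal(attr(cl, "l_1"), mean(abs(x - y)))
  fe <- identity_extractor()
  g <- aggdeblur:::content_loss_grad(x, y, fe, loss_weights())
  eps <- 1e-6
  xp <- x; xp[3] <- xp[3] + eps
  xm <- x; xm[3] <- xm[3] - eps
  num <- (as.numeric(content_loss(xp, y)) -
            as.numeric(content_loss(xm, y))) / (2 * eps)
  expect_equal(g$grad[3], num, tolerance = 1e-5)
  # the random-projection extractor keeps the zero fixed point
  rp <- random_projection_extractor(8, seed = 2)
  expect_equal(as.numeric(content_loss(x, x, rp)), 0)
})

test_that("relativistic least-squares losses match their closed forms", {
  # equal scores: both squared terms are 1
  adv <- adversarial_losses(rep(0.3, 5), rep(0.3, 5))
  expect_equal(adv$d_loss, 1)
  expect_equal(adv$g_loss, 1)
  # the optimum of the discriminator objective
  fake <- c(-1, -1, -1)
  real <- rep(mean(fake) + 1, 3)
  expect_equal(adversarial_losses(real, fake)$d_loss, 0)
  # shift invariance of the relativistic differences
  r <- rnorm(6); f <- rnorm(6)
  a1 <- adversarial_losses(r, f)
  a2 <- adversarial_losses(r + 11.3, f + 11.3)
  expect_equal(a1$g_loss, a2$g_loss)
  expect_equal(a1$d_loss, a2$d_loss)
  # two critics: summed by default, averaged on request
  two <- adversarial_losses(list(r, r), list(f, f))
  expect_equal(two$d_loss, 2 * a1$d_loss)
  avg <- adversarial_losses(list(r, r), list(f, f), aggregate = "mean")
  expect_equal(avg$d_loss, a1$d_loss)
  expect_error(adversarial_losses(numeric(0), 1), "non-empty")
})

test_that("adversarial gradients agree with central differences", {
  set.seed(3)
  dr <- rnorm(5); df <- rnorm(4)
  gd <- aggdeblur:::ra_ls_d_grad(dr, df)
  gg <- aggdeblur:::ra_ls_g_grad_fake(dr, df)
  eps <- 1e-6
  for (i in seq_along(df)) {
    dp <- df; dp[i] <- dp[i] + eps
    dm <- df; dm[i] <- dm[i] - eps
    num_d <- (adversarial_losses(dr, dp)$d_loss -
                adversarial_losses(dr, dm)$d_loss) / (2 * eps)
    num_g <- (adversarial_losses(dr, dp)$g_loss -
                adversarial_losses(dr, dm)$g_loss) / (2 * eps)
    expect_equal(gd$ddf[i], num_d, tolerance = 1e-6)
    expect_equal(gg[i], num_g, tolerance = 1e-6)
  }
})

test_that("total generator loss applies the 0.005 adversarial weight", {
  expect_equal(total_generator_loss(0, 0), 0)
  expect_equal(total_generator_loss(1, 2), 1.01)
  expect_equal(total_generator_loss(0.037, 1), 0.042)
})

test_that("learning-rate schedule is linear after the knee", {
  cfg <- train_config()
  expect_equal(learning_rate(0, cfg), 1e-4)
  expect_equal(learning_rate(10, cfg), 1e-4)
  expect_equal(learning_rate(200, cfg), 1e-6)
  expect_equal(learning_rate(105, cfg), 1e-4 + (95 / 190) * (1e-6 - 1e-4))
  # continuity at the knee and monotone decay afterwards
  expect_equal(learning_rate(10 + 1e-9, cfg), 1e-4, tolerance = 1e-8)
  lrs <- learning_rate(10:200, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(learning_rate(-1, cfg), "range")
  expect_error(learning_rate(300, cfg), "range")
  expect_error(train_config(lr_init = 1e-6, lr_final = 1e-4), "below")
})

test_that("training is seeded-deterministic and honors update ratios", {
  imgs <- lapply(1:8, function(s) make_scene(s, 32))
  ds <- build_paired_dataset(imgs, ratios = c(1, 0, 0), seed = 2,
                             blur_args = list(kernel_size = 9,
                                              n_steps = 200))
  gen <- build_generator(generator_config_small(), seed = 1)
  disc <- build_double_scale_discriminator(8, seed = 1)
  cfg <- train_config(seed = 5, batch_size = 4)
  f1 <- fit_deblur_gan(gen, disc, ds, cfg, epochs = 2)
  f2 <- fit_deblur_gan(gen, disc, ds, cfg, epochs = 2)
  expect_identical(f1$history, f2$history)
  expect_true(all(is.finite(f1$history$loss_total)))
  expect_identical(f1$g_updates, f1$d_updates)
  cfg2 <- train_config(seed = 5, batch_size = 4, d_steps_per_g_step = 2)
  f3 <- fit_deblur_gan(gen, disc, ds, cfg2, epochs = 1)
  expect_identical(f3$d_updates, 2L * f3$g_updates)
  expect_error(fit_deblur_gan(gen, disc, list(), cfg), "empty")
})
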