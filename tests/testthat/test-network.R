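test_that("GHIN at its initialization is the identity on any shape", {
  set.seed(1)
  shapes <- list(c(4, 4, 2, 1), c(3, 5, 4, 2), c(8, 8, 7, 1),
                 c(2, 2, 16, 3))
  for (d in shapes) {
    x <- array(rnorm(prod(d)), d)
    st <- ghin_state(d[3L])
    expect_lt(max(abs(ghin_forward(x, st) - x)), 1e-12)
  }
})

test_that("GHIN matches the hand-evaluated gating equations", {
  # one normalized channel [[1,3],[1,3]]: mu = 2, sigma^2 = 1,
  # normalized [[-1,1],[-1,1]], gate S = normalized, Y = (1+S)*X
  x <- array(0, c(2, 2, 2, 1))
  x[, , 1L, 1L] <- matrix(c(1, 3, 1, 3), 2, 2, byrow = TRUE)
  x[, , 2L, 1L] <- matrix(c(5, 6, 7, 8), 2, 2)
  st <- ghin_state(2, epsilon = 1e-10)
  st$alpha <- 1; st$gamma <- 1; st$beta <- 0
  y <- ghin_forward(x, st)
  expect_equal(y[, , 1L, 1L], matrix(c(0, 6, 0, 6), 2, 2, byrow = TRUE),
               tolerance = 1e-4)
  expect_identical(y[, , 2L, 1L], x[, , 2L, 1L])  # preserved half
})

test_that("the preserved channel half passes through bit-identically", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  st <- ghin_state(4)
  st$gamma <- c(0.7, -0.3); st$beta <- c(0.1, 0.2); st$alpha <- c(2, 0.5)
  y <- ghin_forward(x, st)
  expect_identical(y[, , 3:4, ], x[, , 3:4, ])
  expect_false(identical(y[, , 1:2, ], x[, , 1:2, ]))
})

test_that("GHIN validates channel counts and state size", {
  expect_error(ghin_state(1), "at least 2")
  expect_error(ghin_state(4, epsilon = 0), "positive")
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6, 1))
  expect_error(ghin_forward(x, ghin_state(4)), "sized for")
})

test_that("unit SE excitation reduces Attention-Ghost to plain Ghost", {
  set.seed(3)
  cfg <- ghost_config(4, 6, primary_kernel = 3)
  wa <- init_attention_ghost(cfg)
  # saturate the excitation at 1: zero weights, huge bias
  wa$se$w1[] <- 0; wa$se$b1[] <- 0
  wa$se$w2[] <- 0; wa$se$b2[] <- 50
  wp <- aggdeblur:::init_ghost(cfg, act = TRUE, se = FALSE)
  wp$primary <- wa$primary
  wp$cheap <- wa$cheap
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  ya <- attention_ghost_forward(x, cfg, wa)
  yp <- aggdeblur:::ghost_fwd(x, wp)$y
  expect_lt(max(abs(ya - yp)), 1e-12)
})

test_that("Attention-Ghost respects the shape contract and errors", {
  cfg <- ghost_config(16, 16)
  x <- array(runif(8 * 8 * 16), c(8, 8, 16, 1))
  y <- attention_ghost_forward(x, cfg)
  expect_identical(dim(y), c(8L, 8L, 16L, 1L))
  bad <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  expect_error(attention_ghost_forward(bad, cfg), "channels")
})

test_that("parameter counting matches closed-form convolution counts", {
  expect_identical(count_parameters(list()), 0L)
  conv <- aggdeblur:::init_conv(3, 16, 3)
  expect_equal(count_parameters(list(conv = conv)), 3 * 16 * 9 + 16)
  # attention-ghost closed form vs direct enumeration of arrays
  cfg <- ghost_config(24, 32, primary_kernel = 3)
  ci <- 16
  closed <- 24 * ci * 9 + ci +      # primary conv + bias
    ci * 9 + ci +                   # depth-wise cheap op + bias
    2 * ci * (2 * ci %/% 4) * 2 + (2 * ci %/% 4) + 2 * ci  # SE block
  expect_equal(count_parameters(init_attention_ghost(cfg)), closed)
})

test_that("generator is shape-preserving, deterministic and residual", {
  gen <- build_generator(generator_config_small(), seed = 4)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y1 <- generator_forward(gen, x)
  y2 <- generator_forward(gen, x)
  expect_identical(dim(y1), dim(x))
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)) && all(y1 >= 0 & y1 <= 1))
  # zeroed output projection -> exact identity through the residual path
  gen$params$proj$primary$w[] <- 0
  gen$params$proj$primary$b[] <- 0
  gen$params$proj$cheap$w[] <- 0
  gen$params$proj$cheap$b[] <- 0
  expect_identical(generator_forward(gen, x), x)
})

test_that("generator pads non-multiple-of-16 inputs or errors per config", {
  gen <- build_generator(generator_config_small(), seed = 5)
  x <- array(runif(40 * 44 * 3), c(40, 44, 3, 1))
  y <- generator_forward(gen, x)
  expect_identical(dim(y), dim(x))
  cfg <- generator_config_small()
  cfg$pad_inputs <- FALSE
  gen2 <- build_generator(cfg, seed = 5)
  expect_error(generator_forward(gen2, x), "multiple of the total stride")
})

test_that("generator gradients agree with central differences", {
  gen <- build_generator(generator_config_small(), seed = 6)
  # keep pixels away from the output clamp so the loss is smooth locally
  x <- array(0.2 + 0.6 * runif(32 * 32 * 3), c(32, 32, 3, 1))
  fw <- generator_forward(gen, x, with_cache = TRUE)
  bw <- generator_backward(gen, fw$cache, array(1, dim(fw$y)))
  eps <- 1e-5
  for (probe in list(c("stem", "w"), c("fuse2", "ghin"),
                     c("head1", "g1"), c("post2", "ghost"))) {
    loss_at <- function(v, path) {
      g2 <- gen
      leaf <- paste0("g2$params$", path)
      eval(parse(text = paste0(leaf, "[1] <- v")))
      sum(generator_forward(g2, x))
    }
    path <- switch(probe[1L],
                   stem = "stem$w",
                   fuse2 = "fuse2$ghin$gamma",
                   head1 = "head1$g1$primary$w",
                   post2 = "post2$ghost$se$w2")
    v0 <- eval(parse(text = paste0("gen$params$", path, "[1]")))
    num <- (loss_at(v0 + eps, path) - loss_at(v0 - eps, path)) / (2 * eps)
    ana <- eval(parse(text = paste0("bw$grads$", path, "[1]")))
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("double-scale discriminator emits two finite score maps", {
  disc <- build_double_scale_discriminator(16, seed = 7)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  s1 <- discriminator_forward(disc, x)
  s2 <- discriminator_forward(disc, x)
  expect_true(all(is.finite(s1$global)), all(is.finite(s1$local)))
  expect_identical(s1$global, s2$global)
  expect_identical(s1$local, s2$local)
  # local critic sees full resolution -> spatially larger map
  expect_gt(prod(dim(s1$local)[1:2]), prod(dim(s1$global)[1:2]))
  expect_error(discriminator_forward(disc,
                                     array(runif(8 * 8 * 3),
                                           c(8, 8, 3, 1))),
               "receptive field")
})

test_that("local critic receptive field is smaller than the image", {
  disc <- build_double_scale_discriminator(8, seed = 8)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  s <- discriminator_forward(disc, x, with_cache = TRUE)
  d_local <- array(0, dim(s$local))
  mid <- dim(s$local)[1:2] %/% 2L
  d_local[mid[1L], mid[2L], 1L, 1L] <- 1
  bk <- discriminator_backward(disc, s$cache,
                               array(0, dim(s$global)), d_local)
  support <- which(apply(abs(bk$dx) > 1e-12, c(1, 2), any), arr.ind = TRUE)
  extent <- max(apply(support, 2, function(v) diff(range(v)))) + 1L
  expect_lt(extent, 64L)
  expect_lte(extent, 22L)  # three stacked 4x4 convs at strides 2/2/1
})
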