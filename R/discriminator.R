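# Double-scale adversarial critics: a global critic on a 2x-downsampled
# full image and a local patch critic on full-resolution input. Both are
# three-layer convolutional score-map networks (base width 64, leaky
# ReLU), the patch-critic convention of image-restoration GANs.

init_critic <- function(base_width = 64L) {
  list(c1 = init_conv(3L, base_width, 4L),
       c2 = init_conv(base_width, 2L * base_width, 4L),
       c3 = init_conv(2L * base_width, 1L, 4L))
}

critic_fwd <- function(x, par) {
  a <- conv_fwd(x, par$c1, stride = 2L, pad = 1L, pad_mode = PAD_ZERO)
  r1 <- lrelu_fwd(a$y)
  b <- conv_fwd(r1$y, par$c2, stride = 2L, pad = 1L, pad_mode = PAD_ZERO)
  r2 <- lrelu_fwd(b$y)
  cc <- conv_fwd(r2$y, par$c3, stride = 1L, pad = 1L, pad_mode = PAD_ZERO)
  list(y = cc$y,
       cache = list(a = a$cache, r1 = r1$cache, b = b$cache,
                    r2 = r2$cache, cc = cc$cache))
}

critic_bwd <- function(dy, par, cache) {
  c3 <- conv_bwd(dy, par$c3, cache$cc)
  d <- lrelu_bwd(c3$dx, cache$r2)
  c2 <- conv_bwd(d, par$c2, cache$b)
  d <- lrelu_bwd(c2$dx, cache$r1)
  c1 <- conv_bwd(d, par$c1, cache$a)
  list(dx = c1$dx,
       grads = list(c1 = c1$grads, c2 = c2$grads, c3 = c3$grads))
}

#' Build the double-scale discriminator
#'
#' @param base_width channel width of the first critic layer.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `agg_discriminator` with `global` and
#'   `local` critic parameter trees.
#' @export
build_double_scale_discriminator <- function(base_width = 64L, seed = 1L) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  structure(list(params = list(global = init_critic(base_width),
                               local = init_critic(base_width)),
                 base_width = as.integer(base_width)),
            class = "agg_discriminator")
}

#' Score an image batch with both critics
#'
#' The global critic scores a 2x average-pool downsampled copy of the full
#' image; the local critic scores the full-resolution input, producing a
#' spatially larger patch score map.
#'
#' @param disc an `agg_discriminator`.
#' @param x image batch, array (H, W, 3, N) with spatial dims >= 16.
#' @param with_cache keep activations for [discriminator_backward].
#' @return list with score arrays `global` and `local` (and `cache` when
#'   requested).
#' @export
discriminator_forward <- function(disc, x, with_cache = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  if (d[1L] < 16L || d[2L] < 16L)
    stop("input smaller than the critics' minimum receptive field",
         call. = FALSE)
  pool <- avgpool2_fwd(x)
  gl <- critic_fwd(pool$y, disc$params$global)
  lo <- critic_fwd(x, disc$params$local)
  out <- list(global = gl$y, local = lo$y)
  if (with_cache)
    out$cache <- list(gl = gl$cache, lo = lo$cache, pool = pool$cache)
  out
}

#' Backward pass through both critics
#'
#' @param disc an `agg_discriminator`.
#' @param cache cache from `discriminator_forward(..., with_cache = TRUE)`.
#' @param d_global,d_local gradients at the two score maps.
#' @return list with `dx` (gradient at the input image) and `grads`.
#' @export
discriminator_backward <- function(disc, cache, d_global, d_local) {
  gl <- critic_bwd(d_global, disc$params$global, cache$gl)
  lo <- critic_bwd(d_local, disc$params$local, cache$lo)
  dx <- lo$dx + avgpool2_bwd(gl$dx, cache$pool)
  list(dx = dx, grads = list(global = gl$grads, local = lo$grads))
}
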