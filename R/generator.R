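# Feature-pyramid Ghost generator with Attention-Ghost + GHIN fusion.
#
# Topology: 3x3 stem -> four encoding stages of two Ghost bottlenecks
# (stride 2 in the first block of each stage; widths 16/24/40/80/160) ->
# 1x1 lateral projections (64 at the stem level, 128 at the four deeper
# levels) -> top-down nearest-neighbour fusion refined by three AGG
# (Attention-Ghost + GHIN) modules -> per-level two-layer Ghost heads to
# 64 channels -> upsample to the finest pyramid level and concatenate to
# 256 channels -> two successive AGG modules with nearest-neighbour
# upsampling back to full resolution -> residual add of the 64-channel
# stem lateral -> Ghost projection to RGB -> residual add with the input,
# clamped to [0, 1].

#' Generator configuration
#'
#' Defaults reproduce the published lightweight configuration: stage
#' widths 16/24/40/80/160 with two Ghost bottlenecks per stage, 64/128
#' lateral widths, 128-wide two-layer Ghost heads reduced to 64 channels,
#' a 256-channel fused tensor and a 128/64 post-fusion AGG pair. The
#' expansion (bottleneck mid) widths follow the GhostNet stage pattern
#' scaled so that the total trainable-parameter count matches the
#' published 1.53 M budget.
#'
#' @param stage_widths five stage output widths (stem + four stages).
#' @param expansion_widths list of four length-2 integer vectors, the
#'   bottleneck expansion widths of each stage's two blocks.
#' @param lateral_shallow,lateral_deep 1x1 lateral projection widths.
#' @param head_mid,head_width widths of the two Ghost layers in each
#'   pyramid head; the fused tensor has `4 * head_width` channels.
#' @param post_widths output widths of the two post-fusion AGG modules;
#'   the second must equal `lateral_shallow` for the shallow residual add.
#' @param out_channels output image channels.
#' @param blocks_per_stage Ghost bottlenecks per encoding stage (fixed 2).
#' @param pad_inputs if `TRUE`, inputs whose spatial size is not a
#'   multiple of the total stride 16 are reflect-padded (and the output
#'   cropped back); if `FALSE` such inputs raise an error.
#' @return a `generator_config` object.
#' @export
generator_config <- function(stage_widths = c(16L, 24L, 40L, 80L, 160L),
                             expansion_widths = list(c(84L, 126L),
                                                     c(210L, 420L),
                                                     c(350L, 840L),
                                                     c(1176L, 1680L)),
                             lateral_shallow = 64L, lateral_deep = 128L,
                             head_mid = 128L, head_width = 64L,
                             post_widths = c(128L, 64L),
                             out_channels = 3L, blocks_per_stage = 2L,
                             pad_inputs = TRUE) {
  if (length(stage_widths) != 5L || any(stage_widths <= 0))
    stop("stage_widths must be five positive widths", call. = FALSE)
  if (length(expansion_widths) != 4L)
    stop("expansion_widths must list four stages", call. = FALSE)
  if (blocks_per_stage != 2L)
    stop("the topology uses two Ghost bottlenecks per stage", call. = FALSE)
  if (post_widths[2L] != lateral_shallow)
    stop("post_widths[2] must equal lateral_shallow for the residual add",
         call. = FALSE)
  structure(list(stage_widths = as.integer(stage_widths),
                 expansion_widths = lapply(expansion_widths, as.integer),
                 lateral_shallow = as.integer(lateral_shallow),
                 lateral_deep = as.integer(lateral_deep),
                 head_mid = as.integer(head_mid),
                 head_width = as.integer(head_width),
                 fused_width = 4L * as.integer(head_width),
                 post_widths = as.integer(post_widths),
                 out_channels = as.integer(out_channels),
                 blocks_per_stage = 2L,
                 pad_inputs = isTRUE(pad_inputs)),
            class = "generator_config")
}

#' Reduced-width generator configuration for small-scale experiments
#'
#' Same topology as [generator_config] at roughly 2 % of the parameter
#' count; used for desk-scale training runs.
#' @export
generator_config_small <- function() {
  generator_config(stage_widths = c(8L, 12L, 16L, 24L, 32L),
                   expansion_widths = list(c(12L, 18L), c(24L, 36L),
                                           c(36L, 48L), c(48L, 72L)),
                   lateral_shallow = 8L, lateral_deep = 16L,
                   head_mid = 16L, head_width = 8L,
                   post_widths = c(16L, 8L))
}

#' Build the deblurring generator
#'
#' @param cfg a [generator_config].
#' @param seed RNG seed for weight initialization.
#' @param proj_gain gain of the output-projection initialization; a small
#'   value starts the network close to the identity restoration, which
#'   stabilizes early adversarial training.
#' @return an object of class `agg_generator` holding `params` and `cfg`.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L,
                            proj_gain = 0.1) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  w <- cfg$stage_widths
  mids <- cfg$expansion_widths
  ld <- cfg$lateral_deep
  params <- list(stem = init_conv(3L, w[1L], 3L))
  for (s in 1:4) {
    params[[paste0("s", s, "b1")]] <-
      init_bottleneck(w[s], w[s + 1L], mids[[s]][1L], stride = 2L)
    params[[paste0("s", s, "b2")]] <-
      init_bottleneck(w[s + 1L], w[s + 1L], mids[[s]][2L], stride = 1L)
  }
  params$lat0 <- init_conv(w[1L], cfg$lateral_shallow, 1L)
  for (s in 1:4)
    params[[paste0("lat", s)]] <- init_conv(w[s + 1L], ld, 1L)
  params$fuse3 <- init_agg(ld, ld)
  params$fuse2 <- init_agg(ld, ld)
  params$fuse1 <- init_agg(ld, ld)
  for (s in 1:4)
    params[[paste0("head", s)]] <- list(
      g1 = init_ghost(ghost_config(ld, cfg$head_mid, primary_kernel = 3L),
                      act = TRUE),
      g2 = init_ghost(ghost_config(cfg$head_mid, cfg$head_width,
                                   primary_kernel = 3L), act = TRUE))
  params$post1 <- init_agg(cfg$fused_width, cfg$post_widths[1L])
  params$post2 <- init_agg(cfg$post_widths[1L], cfg$post_widths[2L])
  params$proj <- init_ghost(ghost_config(cfg$post_widths[2L],
                                         cfg$out_channels,
                                         primary_kernel = 3L),
                            act = FALSE, gain = proj_gain)
  structure(list(params = params, cfg = cfg), class = "agg_generator")
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

pad_reflect_hw <- function(x, ph, pw) {
  d <- dim(x)
  ih <- c(rev(seq_len(ph) + 1L), seq_len(d[1L]),
          d[1L] - seq_len(ph))
  iw <- c(rev(seq_len(pw) + 1L), seq_len(d[2L]),
          d[2L] - seq_len(pw))
  x[ih, iw, , , drop = FALSE]
}

head_fwd <- function(x, par) {
  g1 <- ghost_fwd(x, par$g1)
  g2 <- ghost_fwd(g1$y, par$g2)
  list(y = g2$y, cache = list(g1 = g1$cache, g2 = g2$cache))
}

head_bwd <- function(dy, par, cache) {
  g2 <- ghost_bwd(dy, par$g2, cache$g2)
  g1 <- ghost_bwd(g2$dx, par$g1, cache$g1)
  list(dx = g1$dx, grads = list(g1 = g1$grads, g2 = g2$grads))
}

upn_fwd <- function(x, times) {
  caches <- vector("list", times)
  for (i in seq_len(times)) {
    r <- upsample2_fwd(x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, cache = caches)
}

upn_bwd <- function(dy, caches) {
  for (i in rev(seq_along(caches))) dy <- upsample2_bwd(dy, caches[[i]])
  dy
}

#' Generator forward pass
#'
#' @param gen an `agg_generator`.
#' @param x input image batch, array (H, W, 3, N) with values in \[0, 1\]
#'   (3-d inputs are promoted to a single-image batch).
#' @param with_cache keep intermediate activations for a backward pass.
#' @return restored image batch (same shape), or `list(y, cache)` when
#'   `with_cache = TRUE`.
#' @export
generator_forward <- function(gen, x, with_cache = FALSE) {
  p <- gen$params
  x <- as_t4(x)
  d0 <- dim(x)
  if (d0[1L] < 32L || d0[2L] < 32L)
    stop("generator inputs must be at least 32 x 32 pixels",
         call. = FALSE)
  ph <- (16L - d0[1L] %% 16L) %% 16L
  pw <- (16L - d0[2L] %% 16L) %% 16L
  if (ph > 0L || pw > 0L) {
    if (!gen$cfg$pad_inputs)
      stop(sprintf(
        "input %dx%d is not a multiple of the total stride 16",
        d0[1L], d0[2L]), call. = FALSE)
    ih <- c(seq_len(d0[1L]), if (ph > 0L) d0[1L] - seq_len(ph))
    iw <- c(seq_len(d0[2L]), if (pw > 0L) d0[2L] - seq_len(pw))
    x <- x[ih, iw, , , drop = FALSE]
  }
  cv <- conv_fwd(x, p$stem)
  r0 <- relu_fwd(cv$y)
  f0 <- r0$y
  enc <- list()
  h <- f0
  for (s in 1:4) {
    b1 <- bottleneck_fwd(h, p[[paste0("s", s, "b1")]])
    b2 <- bottleneck_fwd(b1$y, p[[paste0("s", s, "b2")]])
    enc[[s]] <- list(b1 = b1$cache, b2 = b2$cache, y = b2$y)
    h <- b2$y
  }
  l0 <- conv_fwd(f0, p$lat0)
  lat <- lapply(1:4, function(s)
    conv_fwd(enc[[s]]$y, p[[paste0("lat", s)]]))
  t4 <- lat[[4L]]$y
  u4 <- upsample2_fwd(t4)
  f3 <- agg_fwd(u4$y + lat[[3L]]$y, p$fuse3)
  u3 <- upsample2_fwd(f3$y)
  f2 <- agg_fwd(u3$y + lat[[2L]]$y, p$fuse2)
  u2 <- upsample2_fwd(f2$y)
  f1 <- agg_fwd(u2$y + lat[[1L]]$y, p$fuse1)
  tops <- list(f1$y, f2$y, f3$y, t4)
  heads <- vector("list", 4L)
  ups <- vector("list", 4L)
  hcat <- NULL
  for (s in 1:4) {
    hd <- head_fwd(tops[[s]], p[[paste0("head", s)]])
    up <- upn_fwd(hd$y, s - 1L)
    heads[[s]] <- hd$cache
    ups[[s]] <- up$cache
    hcat <- if (is.null(hcat)) up$y else cat_ch(hcat, up$y)
  }
  po1 <- agg_fwd(hcat, p$post1)
  pu <- upsample2_fwd(po1$y)
  po2 <- agg_fwd(pu$y, p$post2)
  ssum <- po2$y + l0$y
  pr <- ghost_fwd(ssum, p$proj)
  pre <- x + pr$y
  y <- pmin(pmax(pre, 0), 1)
  if (ph > 0L || pw > 0L)
    y <- y[seq_len(d0[1L]), seq_len(d0[2L]), , , drop = FALSE]
  if (!with_cache) return(y)
  list(y = y, cache = list(
    cv = cv$cache, r0 = r0$cache, enc = enc, l0 = l0$cache,
    lat = lapply(lat, `[[`, "cache"),
    u4 = u4$cache, f3 = f3$cache, u3 = u3$cache, f2 = f2$cache,
    u2 = u2$cache, f1 = f1$cache,
    heads = heads, ups = ups, hw = gen$cfg$head_width,
    po1 = po1$cache, pu = pu$cache, po2 = po2$cache, proj = pr$cache,
    clamp_mask = (pre > 0) & (pre < 1), pad = c(ph, pw), dim0 = d0))
}

#' Generator backward pass
#'
#' Propagates `d loss / d output` through the generator and returns
#' per-parameter gradients mirroring `gen$params`.
#'
#' @param gen an `agg_generator`.
#' @param cache the cache from `generator_forward(..., with_cache = TRUE)`.
#' @param dy gradient at the (cropped) output.
#' @return list with `grads` (parameter-tree gradients).
#' @export
generator_backward <- function(gen, cache, dy) {
  p <- gen$params
  if (any(cache$pad > 0L)) {
    full <- array(0, dim(cache$clamp_mask))
    full[seq_len(cache$dim0[1L]), seq_len(cache$dim0[2L]), , ] <- dy
    dy <- full
  }
  dy <- dy * cache$clamp_mask
  g <- list()
  pr <- ghost_bwd(dy, p$proj, cache$proj)
  g$proj <- pr$grads
  po2 <- agg_bwd(pr$dx, p$post2, cache$po2)
  g$post2 <- po2$grads
  dl0 <- pr$dx
  dpu <- upsample2_bwd(po2$dx, cache$pu)
  po1 <- agg_bwd(dpu, p$post1, cache$po1)
  g$post1 <- po1$grads
  hw <- cache$hw
  dtops <- vector("list", 4L)
  for (s in 1:4) {
    dh <- po1$dx[, , (s - 1L) * hw + seq_len(hw), , drop = FALSE]
    dh <- upn_bwd(dh, cache$ups[[s]])
    hb <- head_bwd(dh, p[[paste0("head", s)]], cache$heads[[s]])
    g[[paste0("head", s)]] <- hb$grads
    dtops[[s]] <- hb$dx
  }
  f1 <- agg_bwd(dtops[[1L]], p$fuse1, cache$f1)
  g$fuse1 <- f1$grads
  dlat1 <- f1$dx
  d_f2 <- dtops[[2L]] + upsample2_bwd(f1$dx, cache$u2)
  f2 <- agg_bwd(d_f2, p$fuse2, cache$f2)
  g$fuse2 <- f2$grads
  dlat2 <- f2$dx
  d_f3 <- dtops[[3L]] + upsample2_bwd(f2$dx, cache$u3)
  f3 <- agg_bwd(d_f3, p$fuse3, cache$f3)
  g$fuse3 <- f3$grads
  dlat3 <- f3$dx
  dt4 <- dtops[[4L]] + upsample2_bwd(f3$dx, cache$u4)
  dlats <- list(dlat1, dlat2, dlat3, dt4)
  denc <- vector("list", 4L)
  for (s in 1:4) {
    lb <- conv_bwd(dlats[[s]], p[[paste0("lat", s)]], cache$lat[[s]])
    g[[paste0("lat", s)]] <- lb$grads
    denc[[s]] <- lb$dx
  }
  l0 <- conv_bwd(dl0, p$lat0, cache$l0)
  g$lat0 <- l0$grads
  dh <- NULL
  for (s in 4:1) {
    dtop <- denc[[s]]
    if (!is.null(dh)) dtop <- dtop + dh
    b2 <- bottleneck_bwd(dtop, p[[paste0("s", s, "b2")]], cache$enc[[s]]$b2)
    g[[paste0("s", s, "b2")]] <- b2$grads
    b1 <- bottleneck_bwd(b2$dx, p[[paste0("s", s, "b1")]],
                         cache$enc[[s]]$b1)
    g[[paste0("s", s, "b1")]] <- b1$grads
    dh <- b1$dx
  }
  df0 <- dh + l0$dx
  df0 <- relu_bwd(df0, cache$r0)
  st <- conv_bwd(df0, p$stem, cache$cv)
  g$stem <- st$grads
  list(grads = g[names(p)])
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable array in a model built by this
#' package ([build_generator], [build_double_scale_discriminator]) or in a
#' raw parameter tree. GHIN layers contribute their three gate vectors;
#' constants such as the normalization epsilon are not counted.
#'
#' @param model a model object, parameter tree, or empty list.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  if (is.list(model) && !is.null(model$params)) model <- model$params
  if (length(model) == 0L) return(0L)
  leaves <- tree_flatten(model)
  sum(vapply(leaves, function(l) length(l$value), numeric(1)))
}

#' Restore a blurred image with a generator
#'
#' Convenience wrapper around [generator_forward] for single images.
#'
#' @param gen an `agg_generator`.
#' @param image array (H, W, 3) in \[0, 1\].
#' @return restored image, same shape.
#' @export
deblur_image <- function(gen, image) {
  y <- generator_forward(gen, as_t4(image))
  array(y, dim(y)[1:3])
}
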