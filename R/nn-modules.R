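# Ghost-convolution building blocks, squeeze-and-excitation attention and
# gated half-instance normalization (GHIN).

## ---- GHIN --------------------------------------------------------------

#' Gated half-instance normalization state
#'
#' Creates the learnable state of a GHIN layer acting on a feature map with
#' `n_channels` channels: the first `floor(n_channels / 2)` channels are
#' instance-normalized and gated, the remainder pass through untouched.
#' Gate parameters follow the identity initialization `alpha = 1`,
#' `gamma = 0`, `beta = 0`, which makes a freshly built GHIN layer an exact
#' identity map.
#'
#' @param n_channels total channel count of the feature map (>= 2).
#' @param epsilon positive variance-stabilizing constant.
#' @return an object of class `ghin_state` with fields `alpha`, `gamma`,
#'   `beta` (length `floor(n_channels / 2)`), `epsilon` and
#'   `n_norm_channels`.
#' @export
ghin_state <- function(n_channels, epsilon = 1e-5) {
  if (n_channels < 2L) stop("GHIN needs at least 2 channels", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  ci <- n_channels %/% 2L
  structure(list(alpha = rep(1, ci), gamma = rep(0, ci), beta = rep(0, ci),
                 epsilon = epsilon, n_norm_channels = ci),
            class = "ghin_state")
}

#' Gated half-instance normalization forward pass
#'
#' Splits the input channels into a normalized half `X_i` and a preserved
#' half `X_r`. `X_i` is standardized per sample and channel over spatial
#' positions, the gate `S = gamma * alpha * X_i_norm + beta` is formed, and
#' the modulated output `Y_i = (1 + S) * X_i` is concatenated with the
#' untouched `X_r`.
#'
#' @param x feature map, array of dim (H, W, C, N) (3-d inputs are treated
#'   as a single-image batch).
#' @param state a [ghin_state] sized for `floor(C / 2)` channels.
#' @return array with the same shape as `x`.
#' @export
ghin_forward <- function(x, state) {
  ghin_fwd(as_t4(x), state)$y
}

ghin_fwd <- function(x, state) {
  d <- dim(x)
  if (d[3L] < 2L) stop("GHIN needs at least 2 channels", call. = FALSE)
  ci <- d[3L] %/% 2L
  if (length(state$alpha) != ci)
    stop(sprintf("GHIN state sized for %d channels, input needs %d",
                 length(state$alpha), ci), call. = FALSE)
  xi <- x[, , seq_len(ci), , drop = FALSE]
  m <- d[1L] * d[2L]
  xm <- matrix(xi, nrow = m)                       # columns: (ci*N)
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  s_inv <- 1 / sqrt(v + state$epsilon)
  xn <- (xm - rep(mu, each = m)) * rep(s_inv, each = m)
  g <- rep_len(state$gamma * state$alpha, ci)      # per normalized channel
  gcol <- rep(g, times = d[4L])
  bcol <- rep(state$beta, times = d[4L])
  s_gate <- xn * rep(gcol, each = m) + rep(bcol, each = m)
  yi <- (1 + s_gate) * xm
  y <- x
  y[, , seq_len(ci), ] <- array(yi, c(d[1L], d[2L], ci, d[4L]))
  list(y = y, cache = list(dim = d, ci = ci, xm = xm, xn = xn,
                           s_inv = s_inv, s_gate = s_gate, gcol = gcol))
}

ghin_bwd <- function(dy, state, cache) {
  d <- cache$dim
  ci <- cache$ci
  m <- d[1L] * d[2L]
  dyi <- matrix(dy[, , seq_len(ci), , drop = FALSE], nrow = m)
  dx <- dy                                          # preserved half passes
  # direct term: y = (1 + S) x
  dxm <- dyi * (1 + cache$s_gate)
  # gate gradients: S = g * xn + beta, y = x + (g xn + beta) x
  dS <- dyi * cache$xm
  dxn <- dS * rep(cache$gcol, each = m)
  # per-(channel, sample) instance-norm backward
  mean_dxn <- colMeans(dxn)
  mean_dxn_xn <- colMeans(dxn * cache$xn)
  dxm <- dxm + (dxn - rep(mean_dxn, each = m) -
                  cache$xn * rep(mean_dxn_xn, each = m)) *
    rep(cache$s_inv, each = m)
  dx[, , seq_len(ci), ] <- array(dxm, c(d[1L], d[2L], ci, d[4L]))
  dg_full <- colSums(dS * cache$xn)                 # (ci*N)
  db_full <- colSums(dS)
  dg <- rowSums(matrix(dg_full, ci, d[4L]))
  db <- rowSums(matrix(db_full, ci, d[4L]))
  list(dx = dx,
       grads = list(alpha = dg * state$gamma, gamma = dg * state$alpha,
                    beta = db))
}

## ---- Ghost module ------------------------------------------------------

#' Ghost block configuration
#'
#' @param in_channels,out_channels channel counts.
#' @param ratio intrinsic-to-total channel ratio of the Ghost split
#'   (default 2: half the output computed by the primary convolution, half
#'   by the cheap depth-wise operation).
#' @param primary_kernel kernel size of the primary convolution.
#' @param dw_kernel depth-wise kernel size of the cheap operation.
#' @param se_reduction squeeze-and-excitation bottleneck reduction.
#' @return a `ghost_config` list.
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 2L,
                         primary_kernel = 1L, dw_kernel = 3L,
                         se_reduction = 4L) {
  if (se_reduction < 1L) stop("se_reduction must be >= 1", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 dw_kernel = as.integer(dw_kernel),
                 se_reduction = as.integer(se_reduction)),
            class = "ghost_config")
}

init_ghost <- function(cfg, act = TRUE, se = FALSE, gain = 1) {
  ci <- ceiling(cfg$out_channels / cfg$ratio)
  par <- list(primary = init_conv(cfg$in_channels, ci, cfg$primary_kernel,
                                  gain = gain),
              cheap = init_dwconv(ci, cfg$dw_kernel, gain = gain))
  if (se) par$se <- init_se(2L * ci, cfg$se_reduction)
  attr(par, "cfg") <- cfg
  attr(par, "act") <- act
  attr(par, "has_se") <- se
  par
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  y
}

ghost_fwd <- function(x, par) {
  cfg <- attr(par, "cfg")
  act <- attr(par, "act")
  if (dim(x)[3L] != cfg$in_channels)
    stop(sprintf("ghost block expects %d channels, got %d",
                 cfg$in_channels, dim(x)[3L]), call. = FALSE)
  cv <- conv_fwd(x, par$primary)
  if (act) { r1 <- relu_fwd(cv$y); p <- r1$y } else { r1 <- NULL; p <- cv$y }
  dw <- dwconv_fwd(p, par$cheap)
  if (act) { r2 <- relu_fwd(dw$y); ch <- r2$y } else { r2 <- NULL; ch <- dw$y }
  cat <- cat_ch(p, ch)
  se_c <- NULL
  if (attr(par, "has_se")) {
    se_r <- se_fwd(cat, par$se)
    cat <- se_r$y
    se_c <- se_r$cache
  }
  y <- cat[, , seq_len(cfg$out_channels), , drop = FALSE]
  list(y = y, cache = list(cv = cv$cache, r1 = r1, dw = dw$cache, r2 = r2,
                           se = se_c, ci = ceiling(cfg$out_channels /
                                                     cfg$ratio),
                           dcat_dim = dim(cat)))
}

ghost_bwd <- function(dy, par, cache) {
  act <- attr(par, "act")
  dcat <- array(0, cache$dcat_dim)
  dcat[, , seq_len(dim(dy)[3L]), ] <- dy
  grads <- list()
  if (attr(par, "has_se")) {
    se_r <- se_bwd(dcat, par$se, cache$se)
    dcat <- se_r$dx
    grads$se <- se_r$grads
  }
  ci <- cache$ci
  dp <- dcat[, , seq_len(ci), , drop = FALSE]
  dch <- dcat[, , ci + seq_len(ci), , drop = FALSE]
  if (act) dch <- relu_bwd(dch, cache$r2$cache)
  dwr <- dwconv_bwd(dch, par$cheap, cache$dw)
  dp <- dp + dwr$dx
  if (act) dp <- relu_bwd(dp, cache$r1$cache)
  cvr <- conv_bwd(dp, par$primary, cache$cv)
  out_grads <- list(primary = cvr$grads, cheap = dwr$grads)
  if (!is.null(grads$se)) out_grads$se <- grads$se
  list(dx = cvr$dx, grads = out_grads)
}

#' Attention-Ghost forward pass
#'
#' Runs a Ghost block whose concatenated intrinsic and cheap features are
#' recalibrated by a squeeze-and-excitation block before channel cropping:
#' primary convolution, depth-wise cheap convolution, channel
#' concatenation, SE gating, crop to `out_channels`.
#'
#' @param x feature map of dim (H, W, C, N).
#' @param cfg a [ghost_config] with `in_channels` matching `x`.
#' @param weights parameters created by [init_attention_ghost]; if `NULL`,
#'   fresh weights are drawn.
#' @return feature map with `cfg$out_channels` channels.
#' @export
attention_ghost_forward <- function(x, cfg, weights = NULL) {
  if (is.null(weights)) weights <- init_attention_ghost(cfg)
  ghost_fwd(as_t4(x), weights)$y
}

#' Initialize Attention-Ghost weights
#'
#' @param cfg a [ghost_config].
#' @param act apply ReLU activations inside the block.
#' @return parameter list usable with [attention_ghost_forward].
#' @export
init_attention_ghost <- function(cfg, act = TRUE) {
  init_ghost(cfg, act = act, se = TRUE)
}

## ---- AGG fusion module: Attention-Ghost + GHIN ------------------------

init_agg <- function(cin, cout, primary_kernel = 3L, se_reduction = 4L) {
  cfg <- ghost_config(cin, cout, primary_kernel = primary_kernel,
                      se_reduction = se_reduction)
  list(ghost = init_ghost(cfg, act = TRUE, se = TRUE),
       ghin = ghin_state(cout))
}

agg_fwd <- function(x, par) {
  g <- ghost_fwd(x, par$ghost)
  n <- ghin_fwd(g$y, par$ghin)
  list(y = n$y, cache = list(g = g$cache, n = n$cache))
}

agg_bwd <- function(dy, par, cache) {
  n <- ghin_bwd(dy, par$ghin, cache$n)
  g <- ghost_bwd(n$dx, par$ghost, cache$g)
  list(dx = g$dx, grads = list(ghost = g$grads, ghin = n$grads))
}

## ---- encoder Ghost bottleneck -----------------------------------------

init_bottleneck <- function(cin, cout, mid, stride) {
  par <- list(gm1 = init_ghost(ghost_config(cin, mid), act = TRUE),
              gm2 = init_ghost(ghost_config(mid, cout), act = FALSE))
  if (stride == 2L) par$dw <- init_dwconv(mid, 3L)
  if (stride == 2L || cin != cout)
    par$shortcut <- list(dw = init_dwconv(cin, 3L),
                         pw = init_conv(cin, cout, 1L))
  attr(par, "stride") <- stride
  par
}

bottleneck_fwd <- function(x, par) {
  stride <- attr(par, "stride")
  g1 <- ghost_fwd(x, par$gm1)
  h <- g1$y
  dwc <- NULL
  if (!is.null(par$dw)) {
    dwc <- dwconv_fwd(h, par$dw, stride = 2L)
    h <- dwc$y
  }
  g2 <- ghost_fwd(h, par$gm2)
  y <- g2$y
  sc <- NULL
  if (!is.null(par$shortcut)) {
    s1 <- dwconv_fwd(x, par$shortcut$dw, stride = stride)
    s2 <- conv_fwd(s1$y, par$shortcut$pw)
    y <- y + s2$y
    sc <- list(s1 = s1$cache, s2 = s2$cache)
  } else {
    y <- y + x
  }
  list(y = y, cache = list(g1 = g1$cache, dwc = if (is.null(dwc)) NULL else
    dwc$cache, g2 = g2$cache, sc = sc))
}

bottleneck_bwd <- function(dy, par, cache) {
  g2 <- ghost_bwd(dy, par$gm2, cache$g2)
  dh <- g2$dx
  grads <- list(gm2 = g2$grads)
  if (!is.null(par$dw)) {
    dwr <- dwconv_bwd(dh, par$dw, cache$dwc)
    dh <- dwr$dx
    grads$dw <- dwr$grads
  }
  g1 <- ghost_bwd(dh, par$gm1, cache$g1)
  dx <- g1$dx
  grads$gm1 <- g1$grads
  if (!is.null(par$shortcut)) {
    s2 <- conv_bwd(dy, par$shortcut$pw, cache$sc$s2)
    s1 <- dwconv_bwd(s2$dx, par$shortcut$dw, cache$sc$s1)
    dx <- dx + s1$dx
    grads$shortcut <- list(dw = s1$grads, pw = s2$grads)
  } else {
    dx <- dx + dy
  }
  # reorder grads to match param order (gm1, gm2, dw?, shortcut?)
  ordered <- list(gm1 = grads$gm1, gm2 = grads$gm2)
  if (!is.null(par$dw)) ordered$dw <- grads$dw
  if (!is.null(par$shortcut)) ordered$shortcut <- grads$shortcut
  list(dx = dx, grads = ordered)
}
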