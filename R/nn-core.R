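# Minimal feed-forward/backward neural-network primitives.
#
# Feature maps are plain double arrays with dim (H, W, C, N) -- the
# column-major R equivalent of a batched channel-second tensor. Every
# primitive exposes a forward function returning list(y, cache) and a
# backward function returning list(dx, grads), so composite modules can
# chain exact gradients without an autodiff framework.

PAD_ZERO <- 0L
PAD_REFLECT <- 1L

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("expected a (H, W, C, N) array", call. = FALSE)
  x
}

conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

## ---- dense convolution (im2col + BLAS) --------------------------------

init_conv <- function(cin, cout, k, gain = 1, rng = NULL) {
  fan_in <- cin * k * k
  w <- array(stats::rnorm(k * k * cin * cout, sd = gain * sqrt(2 / fan_in)),
             dim = c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

conv_fwd <- function(x, par, stride = 1L, pad = NULL, pad_mode = PAD_REFLECT) {
  d <- dim(x)
  kd <- dim(par$w)
  if (kd[3L] != d[3L])
    stop(sprintf("conv expects %d input channels, got %d", kd[3L], d[3L]),
         call. = FALSE)
  if (is.null(pad)) pad <- (kd[1L] - 1L) %/% 2L
  one_by_one <- kd[1L] == 1L && kd[2L] == 1L && stride == 1L && pad == 0L
  if (one_by_one) {
    # (H*W, C, N) -> (H*W*N, C) without an im2col pass
    cols <- matrix(aperm(x, c(1L, 2L, 4L, 3L)),
                   ncol = d[3L])
  } else {
    cols <- im2col_cpp(x, d[1L], d[2L], d[3L], d[4L],
                       kd[1L], kd[2L], stride, stride, pad, pad, pad_mode)
  }
  wm <- matrix(par$w, nrow = kd[1L] * kd[2L] * kd[3L], ncol = kd[4L])
  y2 <- cols %*% wm                           # (OH*OW*N, Cout)
  y2 <- y2 + rep(par$b, each = nrow(y2))
  oh <- conv_out_len(d[1L], kd[1L], stride, pad)
  ow <- conv_out_len(d[2L], kd[2L], stride, pad)
  y <- aperm(array(y2, c(oh, ow, d[4L], kd[4L])), c(1L, 2L, 4L, 3L))
  list(y = y, cache = list(cols = cols, dim_in = d, stride = stride,
                           pad = pad, pad_mode = pad_mode,
                           one_by_one = one_by_one))
}

conv_bwd <- function(dy, par, cache) {
  kd <- dim(par$w)
  d <- cache$dim_in
  dy2 <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = kd[4L])
  wm <- matrix(par$w, nrow = kd[1L] * kd[2L] * kd[3L], ncol = kd[4L])
  dw <- array(crossprod(cache$cols, dy2), dim = kd)
  db <- colSums(dy2)
  dcols <- tcrossprod(dy2, wm)                # (M, K)
  if (cache$one_by_one) {
    dx <- aperm(array(dcols, c(d[1L], d[2L], d[4L], d[3L])),
                c(1L, 2L, 4L, 3L))
  } else {
    dx <- col2im_cpp(dcols, d[1L], d[2L], d[3L], d[4L],
                     kd[1L], kd[2L], cache$stride, cache$stride,
                     cache$pad, cache$pad, cache$pad_mode)
  }
  list(dx = dx, grads = list(w = dw, b = db))
}

## ---- depth-wise convolution -------------------------------------------

init_dwconv <- function(c, k, gain = 1) {
  w <- array(stats::rnorm(k * k * c, sd = gain * sqrt(2 / (k * k))),
             dim = c(k, k, c))
  list(w = w, b = numeric(c))
}

dwconv_fwd <- function(x, par, stride = 1L, pad = NULL,
                       pad_mode = PAD_REFLECT) {
  d <- dim(x)
  kd <- dim(par$w)
  if (kd[3L] != d[3L]) stop("depth-wise channel mismatch", call. = FALSE)
  if (is.null(pad)) pad <- (kd[1L] - 1L) %/% 2L
  y <- dwconv_fwd_cpp(x, par$w, par$b, d[1L], d[2L], d[3L], d[4L],
                      kd[1L], kd[2L], stride, stride, pad, pad, pad_mode)
  list(y = y, cache = list(x = x, stride = stride, pad = pad,
                           pad_mode = pad_mode))
}

dwconv_bwd <- function(dy, par, cache) {
  d <- dim(cache$x)
  kd <- dim(par$w)
  r <- dwconv_bwd_cpp(cache$x, par$w, dy, d[1L], d[2L], d[3L], d[4L],
                      kd[1L], kd[2L], cache$stride, cache$stride,
                      cache$pad, cache$pad, cache$pad_mode)
  list(dx = r$dx, grads = list(w = r$dw, b = r$db))
}

## ---- activations -------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

lrelu_fwd <- function(x, slope = 0.2) {
  m <- x > 0
  list(y = ifelse_arr(m, x, slope * x), cache = list(m = m, slope = slope))
}
lrelu_bwd <- function(dy, cache)
  ifelse_arr(cache$m, dy, cache$slope * dy)

ifelse_arr <- function(mask, a, b) {
  y <- b
  y[mask] <- a[mask]
  dim(y) <- dim(a)
  y
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- resampling --------------------------------------------------------

upsample2_fwd <- function(x) {
  d <- dim(x)
  idx_h <- rep(seq_len(d[1L]), each = 2L)
  idx_w <- rep(seq_len(d[2L]), each = 2L)
  list(y = x[idx_h, idx_w, , , drop = FALSE], cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache
  oh <- 2L * d[1L]; ow <- 2L * d[2L]
  dim(dy) <- c(2L, d[1L], 2L, d[2L], d[3L], d[4L])
  dx <- colSums(aperm(dy, c(1L, 3L, 2L, 4L, 5L, 6L)), dims = 2L)
  dim(dx) <- d
  dx
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop("avgpool2 needs even spatial dims", call. = FALSE)
  dim(x) <- c(2L, d[1L] %/% 2L, 2L, d[2L] %/% 2L, d[3L], d[4L])
  y <- colSums(aperm(x, c(1L, 3L, 2L, 4L, 5L, 6L)), dims = 2L) / 4
  dim(y) <- c(d[1L] %/% 2L, d[2L] %/% 2L, d[3L], d[4L])
  list(y = y, cache = d)
}

avgpool2_bwd <- function(dy, cache) {
  d <- cache
  idx_h <- rep(seq_len(d[1L] %/% 2L), each = 2L)
  idx_w <- rep(seq_len(d[2L] %/% 2L), each = 2L)
  dy[idx_h, idx_w, , , drop = FALSE] / 4
}

## ---- squeeze-and-excitation -------------------------------------------

init_se <- function(c, reduction = 4L) {
  h <- max(1L, c %/% reduction)
  list(w1 = matrix(stats::rnorm(c * h, sd = sqrt(2 / c)), h, c),
       b1 = numeric(h),
       w2 = matrix(stats::rnorm(h * c, sd = sqrt(2 / h)), c, h),
       b2 = numeric(c))
}

se_fwd <- function(x, par) {
  d <- dim(x)
  z <- colMeans(matrix(x, nrow = d[1L] * d[2L]))   # (C*N) pooled means
  z <- matrix(z, d[3L], d[4L])                      # (C, N)
  h_pre <- par$w1 %*% z + par$b1
  h <- pmax(h_pre, 0)
  a <- sigmoid(par$w2 %*% h + par$b2)               # (C, N)
  ab <- aperm(array(a, c(d[3L], d[4L], d[1L], d[2L])), c(3L, 4L, 1L, 2L))
  list(y = x * ab, cache = list(x = x, z = z, hmask = h_pre > 0, h = h,
                                a = a, ab = ab))
}

se_bwd <- function(dy, par, cache) {
  d <- dim(cache$x)
  dx_direct <- dy * cache$ab
  da <- matrix(colSums(matrix(dy * cache$x, nrow = d[1L] * d[2L])),
               d[3L], d[4L])
  dpre2 <- da * cache$a * (1 - cache$a)
  dw2 <- tcrossprod(dpre2, cache$h)
  db2 <- rowSums(dpre2)
  dh <- crossprod(par$w2, dpre2) * cache$hmask
  dw1 <- tcrossprod(dh, cache$z)
  db1 <- rowSums(dh)
  dz <- crossprod(par$w1, dh)                       # (C, N)
  dzb <- aperm(array(dz / (d[1L] * d[2L]), c(d[3L], d[4L], d[1L], d[2L])),
               c(3L, 4L, 1L, 2L))
  list(dx = dx_direct + dzb,
       grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

## ---- parameter-tree utilities -----------------------------------------

# GHIN states carry non-trainable constants (epsilon, channel count);
# only the three gate vectors participate in gradient/optimizer trees.
GHIN_TRAINABLE <- c("alpha", "gamma", "beta")

tree_map <- function(f, tree) {
  if (inherits(tree, "ghin_state")) {
    for (nm in GHIN_TRAINABLE) tree[[nm]] <- f(tree[[nm]])
    return(tree)
  }
  if (is.list(tree)) {
    out <- lapply(tree, function(t) tree_map(f, t))
    attributes(out) <- attributes(tree)
    out
  } else {
    f(tree)
  }
}

tree_map2 <- function(f, a, b) {
  if (inherits(a, "ghin_state") || inherits(b, "ghin_state")) {
    out <- a
    for (nm in GHIN_TRAINABLE) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    return(out)
  }
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) {
  if (inherits(tree, "ghin_state")) {
    out <- lapply(tree[GHIN_TRAINABLE], function(x) x * 0)
    return(out)
  }
  if (is.list(tree)) {
    out <- lapply(tree, tree_zeros_like)
    names(out) <- names(tree)
    return(out)
  }
  tree * 0
}

tree_flatten <- function(tree) {
  out <- list()
  walk <- function(t, prefix) {
    if (inherits(t, "ghin_state")) {
      for (nm in GHIN_TRAINABLE)
        out[[length(out) + 1L]] <<- list(name = paste0(prefix, ".", nm),
                                         value = t[[nm]])
    } else if (is.list(t)) {
      nm <- names(t)
      for (i in seq_along(t))
        walk(t[[i]], paste0(prefix, ".", if (is.null(nm)) i else nm[i]))
    } else {
      out[[length(out) + 1L]] <<- list(name = sub("^\\.", "", prefix),
                                       value = t)
    }
  }
  walk(tree, "")
  out
}

## ---- Adam optimizer ----------------------------------------------------

adam_state <- function(params)
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map(function(m) m / bc1, state$m)
  vh <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
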