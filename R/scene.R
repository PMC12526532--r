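# Synthetic orchard-like scene generator. Stands in for field imagery so
# every pipeline stage is testable without photographic data: a smooth
# textured background (foliage analogue), shaded discs (fruit), elongated
# dark strokes (branches), and a high-frequency binary glyph block
# (signage/text analogue).

#' Generate a synthetic orchard-like scene
#'
#' @param width,height image size in pixels (>= 32 each).
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param n_discs number of fruit-like disc regions (>= 3).
#' @return RGB array (height, width, 3) with values in \[0, 1\].
#' @export
generate_synthetic_scene <- function(width, height, seed = 1L,
                                     n_discs = 4L) {
  if (width < 32L || height < 32L)
    stop("scene dimensions must be at least 32 x 32", call. = FALSE)
  if (n_discs < 3L) stop("at least 3 disc regions required", call. = FALSE)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  h <- as.integer(height); w <- as.integer(width)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)

  # textured background: sum of random low-frequency waves, green-brown
  tex <- matrix(0, h, w)
  for (q in 1:6) {
    fy <- stats::runif(1, 0.02, 0.25)
    fx <- stats::runif(1, 0.02, 0.25)
    ph <- stats::runif(2, 0, 2 * pi)
    tex <- tex + stats::runif(1, 0.3, 1) *
      sin(fy * yy + ph[1L]) * cos(fx * xx + ph[2L])
  }
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  grain <- matrix(stats::runif(h * w, -0.05, 0.05), h, w)
  img <- array(0, c(h, w, 3L))
  img[, , 1L] <- 0.20 + 0.25 * tex + grain
  img[, , 2L] <- 0.35 + 0.30 * tex + grain
  img[, , 3L] <- 0.10 + 0.15 * tex + grain

  # fruit-like discs with radial shading
  r_base <- 0.10 * min(h, w)
  for (q in seq_len(n_discs)) {
    cy <- stats::runif(1, 0.15, 0.85) * h
    cx <- stats::runif(1, 0.15, 0.85) * w
    r <- r_base * stats::runif(1, 0.7, 1.4)
    d2 <- (yy - cy)^2 + (xx - cx)^2
    mask <- d2 <= r^2
    shade <- pmax(0, 1 - d2 / r^2)
    img[, , 1L][mask] <- (0.85 + 0.15 * shade[mask]) * 0.95
    img[, , 2L][mask] <- 0.45 + 0.25 * shade[mask]
    img[, , 3L][mask] <- 0.05 + 0.10 * shade[mask]
  }

  # branch-like elongated strokes: thin dark segments
  n_strokes <- 3L + stats::rpois(1L, 2)
  for (q in seq_len(n_strokes)) {
    p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.4, 0.9) * min(h, w)
    p1 <- p0 + len * c(sin(ang), cos(ang))
    v <- p1 - p0
    vv <- sum(v * v)
    t <- pmin(pmax(((yy - p0[1L]) * v[1L] + (xx - p0[2L]) * v[2L]) / vv,
                   0), 1)
    dist2 <- (yy - (p0[1L] + t * v[1L]))^2 + (xx - (p0[2L] + t * v[2L]))^2
    wdt <- stats::runif(1, 1.0, 2.0)
    mask <- dist2 <= wdt^2
    for (c in 1:3) img[, , c][mask] <- c(0.25, 0.16, 0.08)[c]
  }

  # high-frequency glyph block (text analogue) in a random corner
  bs <- max(8L, round(0.22 * min(h, w)))
  oy <- sample(c(2L, h - bs - 1L), 1L)
  ox <- sample(c(2L, w - bs - 1L), 1L)
  glyph <- matrix(stats::runif(bs * bs) < 0.5, bs, bs)
  block <- matrix(0.08, bs, bs)
  block[glyph] <- 0.95
  for (c in 1:3)
    img[oy + seq_len(bs), ox + seq_len(bs), c] <- block
  pmin(pmax(img, 0), 1)
}
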