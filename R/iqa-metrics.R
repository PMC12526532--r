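# Native full-reference image-quality metrics: MS-SSIM, FSIM, VSI, GMSD
# and NLPD, plus PSNR/SSIM utilities. DISTS and LPIPS require learned
# feature backbones and are served by pluggable backends (see
# iqa_register_backend); without a registered backend they raise an
# explicit unavailability error.
#
# All metrics take images in [0, 1]; metrics defined on luminance use
# BT.601 luma. Internally several metrics follow their published
# formulations on the 0-255 scale, so luma is rescaled where noted.

same_shape <- function(ref, test) {
  if (!identical(dim(ref), dim(test)))
    stop("reference and test images must have identical shape",
         call. = FALSE)
}

# separable 'same' convolution with reflective borders (odd kernels)
conv_same <- function(x, kernel) fft_convolve2(x, kernel)

gaussian2 <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

down2 <- function(x) {
  d <- dim(x)
  h <- d[1L] - d[1L] %% 2L
  w <- d[2L] - d[2L] %% 2L
  x <- x[seq_len(h), seq_len(w)]
  0.25 * (x[seq(1L, h, 2L), seq(1L, w, 2L)] +
            x[seq(2L, h, 2L), seq(1L, w, 2L)] +
            x[seq(1L, h, 2L), seq(2L, w, 2L)] +
            x[seq(2L, h, 2L), seq(2L, w, 2L)])
}

## ---- SSIM / MS-SSIM ----------------------------------------------------

ssim_components <- function(x, y, win, k1 = 0.01, k2 = 0.03, dr = 1) {
  c1 <- (k1 * dr)^2
  c2 <- (k2 * dr)^2
  mx <- conv_same(x, win)
  my <- conv_same(y, win)
  sx <- conv_same(x * x, win) - mx * mx
  sy <- conv_same(y * y, win) - my * my
  sxy <- conv_same(x * y, win) - mx * my
  l <- (2 * mx * my + c1) / (mx * mx + my * my + c1)
  cs <- (2 * sxy + c2) / (sx + sy + c2)
  list(l = l, cs = cs)
}

adapt_win <- function(h, w, size = 11L, sigma = 1.5) {
  size <- min(size, 2L * ((min(h, w) - 1L) %/% 2L) + 1L)
  gaussian2(size, sigma * size / 11)
}

#' Structural similarity (single scale)
#'
#' Mean SSIM over an 11 x 11 Gaussian window (sigma 1.5), computed on
#' BT.601 luma with reflective borders.
#'
#' @param ref,test images in \[0, 1\], identical shape, at least 3 x 3.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(ref, test) {
  same_shape(ref, test)
  x <- luma(ref); y <- luma(test)
  win <- adapt_win(nrow(x), ncol(x))
  comp <- ssim_components(x, y, win)
  mean(comp$l * comp$cs)
}

#' Peak signal-to-noise ratio
#'
#' @param ref,test images in \[0, 1\], identical shape.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, test) {
  same_shape(ref, test)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Multi-scale structural similarity
#'
#' Five-scale MS-SSIM with the standard scale weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333): contrast-structure terms at
#' every scale, the luminance term only at the coarsest, combined as a
#' weighted product. Scales are linked by 2 x 2 average-pool
#' downsampling; the Gaussian window shrinks when a coarse scale is
#' smaller than the 11-pixel support.
#'
#' @param ref,test images in \[0, 1\], identical shape.
#' @param weights per-scale exponents; their length sets the number of
#'   scales.
#' @return MS-SSIM value.
#' @export
ms_ssim <- function(ref, test,
                    weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  same_shape(ref, test)
  x <- luma(ref); y <- luma(test)
  m <- length(weights)
  if (min(dim(x)) < 2^(m - 1) * 2)
    stop(sprintf("image too small for a %d-scale pyramid", m),
         call. = FALSE)
  vals <- numeric(m)
  for (j in seq_len(m)) {
    win <- adapt_win(nrow(x), ncol(x))
    comp <- ssim_components(x, y, win)
    vals[j] <- if (j < m) mean(comp$cs) else mean(comp$l * comp$cs)
    if (j < m) { x <- down2(x); y <- down2(y) }
  }
  prod(pmax(vals, 0)^weights)
}

## ---- GMSD --------------------------------------------------------------

#' Gradient magnitude similarity deviation
#'
#' Published formulation: luma rescaled to 0-255, 2 x 2 average-pool
#' preprocessing, Prewitt gradients, gradient-magnitude similarity map
#' with stability constant 170, score = population standard deviation of
#' the map. 0 for identical images; larger means more distortion.
#'
#' @param ref,test images in \[0, 1\], identical shape, at least 8 x 8.
#' @return GMSD value (>= 0).
#' @export
gmsd <- function(ref, test) {
  same_shape(ref, test)
  x <- down2(luma(ref) * 255)
  y <- down2(luma(test) * 255)
  if (min(dim(x)) < 3L) stop("image too small for GMSD", call. = FALSE)
  ph <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3L, 3L)
  gx <- sqrt(conv_same(x, ph)^2 + conv_same(x, t(ph))^2)
  gy <- sqrt(conv_same(y, ph)^2 + conv_same(y, t(ph))^2)
  c0 <- 170
  gms <- (2 * gx * gy + c0) / (gx * gx + gy * gy + c0)
  sqrt(mean((gms - mean(gms))^2))
}

## ---- NLPD --------------------------------------------------------------

binom5 <- function() {
  g <- c(1, 4, 6, 4, 1) / 16
  outer(g, g)
}

up2_filter <- function(x, h, w) {
  idx_h <- rep(seq_len(nrow(x)), each = 2L)[seq_len(h)]
  idx_w <- rep(seq_len(ncol(x)), each = 2L)[seq_len(w)]
  conv_same(x[idx_h, idx_w], binom5())
}

laplacian_pyramid <- function(x, levels) {
  bands <- vector("list", levels)
  for (k in seq_len(levels - 1L)) {
    low <- down2(conv_same(x, binom5()))
    bands[[k]] <- x - up2_filter(low, nrow(x), ncol(x))
    x <- low
  }
  bands[[levels]] <- x
  bands
}

#' Normalized Laplacian pyramid distance
#'
#' Distance in a normalized multi-scale representation: each Laplacian
#' band is divided by a local amplitude estimate (a constant plus the
#' locally averaged absolute band value), and the score is the mean over
#' scales of the root-mean-square difference between the two normalized
#' pyramids. 0 for identical images. The divisive-normalization constant
#' and the number of scales are exposed because published variants
#' differ in these choices.
#'
#' @param ref,test images in \[0, 1\], identical shape.
#' @param levels pyramid depth (reduced automatically for small images).
#' @param c0 divisive-normalization constant.
#' @return NLPD value (>= 0).
#' @export
nlpd <- function(ref, test, levels = 6L, c0 = 0.17) {
  same_shape(ref, test)
  x <- luma(ref); y <- luma(test)
  levels <- min(levels, max(1L, floor(log2(min(dim(x)))) - 1L))
  px <- laplacian_pyramid(x, levels)
  py <- laplacian_pyramid(y, levels)
  amp <- binom5()
  d <- 0
  for (k in seq_len(levels)) {
    nx <- px[[k]] / (c0 + conv_same(abs(px[[k]]), amp))
    ny <- py[[k]] / (c0 + conv_same(abs(py[[k]]), amp))
    d <- d + sqrt(mean((nx - ny)^2))
  }
  d / levels
}

## ---- log-Gabor machinery (FSIM, VSI) ----------------------------------

freq_grids <- function(h, w) {
  fy <- ((seq_len(h) - 1 + h %/% 2) %% h - h %/% 2) / h
  fx <- ((seq_len(w) - 1 + w %/% 2) %% w - w %/% 2) / w
  radius <- sqrt(outer(fy^2, fx^2, `+`))
  radius[1L, 1L] <- 1  # avoid log(0) at DC
  theta <- atan2(outer(-fy, rep(1, w)), outer(rep(1, h), fx))
  list(radius = radius, theta = theta)
}

log_gabor_radial <- function(radius, wavelength, sigma_onf = 0.55) {
  f0 <- 1 / wavelength
  lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2))
  lg[1L, 1L] <- 0
  lg
}

# oriented phase congruency without noise-energy compensation: for each
# orientation, energy of the summed scale responses over the summed
# response amplitudes
phase_congruency <- function(x, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55, d_theta_sigma = 1.2) {
  d <- dim(x)
  fr <- freq_grids(d[1L], d[2L])
  xf <- stats::fft(x)
  pc_num <- matrix(0, d[1L], d[2L])
  pc_den <- matrix(0, d[1L], d[2L])
  theta_sd <- pi / norient / d_theta_sigma
  for (o in seq_len(norient)) {
    angle <- (o - 1) * pi / norient
    ds <- sin(fr$theta) * cos(angle) - cos(fr$theta) * sin(angle)
    dc <- cos(fr$theta) * cos(angle) + sin(fr$theta) * sin(angle)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sd^2))
    sum_e <- matrix(0, d[1L], d[2L])
    sum_o <- matrix(0, d[1L], d[2L])
    sum_a <- matrix(0, d[1L], d[2L])
    for (s in seq_len(nscale)) {
      filt <- log_gabor_radial(fr$radius, min_wavelength * mult^(s - 1),
                               sigma_onf) * spread
      resp <- stats::fft(xf * filt, inverse = TRUE) / length(x)
      e <- Re(resp); od <- Im(resp)
      sum_e <- sum_e + e
      sum_o <- sum_o + od
      sum_a <- sum_a + sqrt(e * e + od * od)
    }
    pc_num <- pc_num + sqrt(sum_e^2 + sum_o^2)
    pc_den <- pc_den + sum_a
  }
  pc_num / (pc_den + 1e-4)
}

scharr_gm <- function(x) {
  k <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3) / 16, 3L, 3L)
  sqrt(conv_same(x, k)^2 + conv_same(x, t(k))^2)
}

iqa_downsample <- function(x) {
  f <- max(1L, round(min(dim(x)[1:2]) / 256))
  while (f >= 2L) {
    x <- if (length(dim(x)) == 3L) {
      d <- dim(x)
      out <- NULL
      for (c in seq_len(d[3L])) {
        ch <- down2(x[, , c])
        if (is.null(out)) out <- array(0, c(dim(ch), d[3L]))
        out[, , c] <- ch
      }
      out
    } else {
      down2(x)
    }
    f <- f %/% 2L
  }
  x
}

#' Feature similarity index
#'
#' Luminance FSIM: phase congruency (log-Gabor, 4 scales, 4
#' orientations) and Scharr gradient magnitude are compared pointwise and
#' the similarity map is averaged with phase-congruency weighting, on
#' 0-255 luma after the standard resolution reduction towards a 256-pixel
#' working size.
#'
#' @param ref,test images in \[0, 1\], identical shape, at least 16 x 16.
#' @return FSIM value in \[0, 1\].
#' @export
fsim <- function(ref, test) {
  same_shape(ref, test)
  x <- iqa_downsample(luma(ref) * 255)
  y <- iqa_downsample(luma(test) * 255)
  if (min(dim(x)) < 16L) stop("image too small for FSIM", call. = FALSE)
  t1 <- 0.85; t2 <- 160
  pc1 <- phase_congruency(x)
  pc2 <- phase_congruency(y)
  g1 <- scharr_gm(x)
  g2 <- scharr_gm(y)
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * g1 * g2 + t2) / (g1^2 + g2^2 + t2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

## ---- VSI ---------------------------------------------------------------

rgb_to_lab <- function(img) {
  # sRGB (D65) -> CIELAB
  lin <- ifelse(img <= 0.04045, img / 12.92, ((img + 0.055) / 1.055)^2.4)
  r <- lin[, , 1L]; g <- lin[, , 2L]; b <- lin[, , 3L]
  xn <- 0.95047; yn <- 1; zn <- 1.08883
  x <- (0.4124564 * r + 0.3575761 * g + 0.1804375 * b) / xn
  y <- (0.2126729 * r + 0.7151522 * g + 0.0721750 * b) / yn
  z <- (0.0193339 * r + 0.1191920 * g + 0.9503041 * b) / zn
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(x); fy <- f(y); fz <- f(z)
  list(l = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# SDSP-style visual saliency: log-Gabor band-pass frequency prior on Lab
# channels, centre-location prior, warm-colour prior
sdsp_saliency <- function(img, omega0 = 0.021, sigma_f = 1.34,
                          sigma_d = 145, sigma_c = 0.25) {
  d <- dim(img)
  lab <- rgb_to_lab(img)
  fr <- freq_grids(d[1L], d[2L])
  lg <- exp(-(log(fr$radius / omega0))^2 / (2 * log(sigma_f)^2))
  lg[1L, 1L] <- 0
  bp <- function(ch) Mod(stats::fft(stats::fft(ch) * lg,
                                    inverse = TRUE)) / length(ch)
  sf <- sqrt(bp(lab$l)^2 + bp(lab$a)^2 + bp(lab$b)^2)
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
  yy <- matrix(seq_len(d[1L]), d[1L], d[2L])
  xx <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  sd_prior <- exp(-((yy - cy)^2 + (xx - cx)^2) / sigma_d^2)
  rng <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) v * 0 else (v - lo) / (hi - lo)
  }
  an <- rng(lab$a); bn <- rng(lab$b)
  sc <- 1 - exp(-((an - 0.5)^2 + (bn - 0.5)^2) / sigma_c^2)
  sf * sd_prior * sc
}

#' Visual saliency-induced index
#'
#' Similarity of two images weighted by visual saliency: SDSP-style
#' saliency maps and Scharr gradients on luminance `L` of the LMN
#' opponent colour space, plus chrominance similarity on the `M`/`N`
#' channels, pooled with max-saliency weighting (published constants
#' C1 = 1.27, C2 = 386, C3 = 130, exponents 0.4 / 0.02).
#'
#' @param ref,test RGB images in \[0, 1\], identical shape, >= 16 x 16.
#' @return VSI value in \[0, 1\].
#' @export
vsi <- function(ref, test) {
  same_shape(ref, test)
  if (length(dim(ref)) != 3L)
    stop("VSI requires RGB input", call. = FALSE)
  r1 <- iqa_downsample(ref)
  r2 <- iqa_downsample(test)
  if (min(dim(r1)[1:2]) < 16L)
    stop("image too small for VSI", call. = FALSE)
  vs1 <- sdsp_saliency(r1)
  vs2 <- sdsp_saliency(r2)
  lmn <- function(img) {
    r <- img[, , 1L] * 255; g <- img[, , 2L] * 255; b <- img[, , 3L] * 255
    list(l = 0.06 * r + 0.63 * g + 0.27 * b,
         m = 0.30 * r + 0.04 * g - 0.35 * b,
         n = 0.34 * r - 0.60 * g + 0.17 * b)
  }
  c1 <- lmn(r1); c2 <- lmn(r2)
  g1 <- scharr_gm(c1$l)
  g2 <- scharr_gm(c2$l)
  cc1 <- 1.27; cc2 <- 386; cc3 <- 130
  s_vs <- (2 * vs1 * vs2 + cc1) / (vs1^2 + vs2^2 + cc1)
  s_g <- (2 * g1 * g2 + cc2) / (g1^2 + g2^2 + cc2)
  s_m <- (2 * c1$m * c2$m + cc3) / (c1$m^2 + c2$m^2 + cc3)
  s_n <- (2 * c1$n * c2$n + cc3) / (c1$n^2 + c2$n^2 + cc3)
  s_c <- s_m * s_n
  vsm <- pmax(vs1, vs2)
  s <- s_vs * abs(s_g)^0.4 * abs(s_c)^0.02
  sum(s * vsm) / sum(vsm)
}

## ---- learned-metric backends ------------------------------------------

iqa_backend_env <- new.env(parent = emptyenv())

#' Register a learned-metric backend
#'
#' DISTS and LPIPS depend on pretrained deep-feature backbones that this
#' package does not ship. A backend is any
#' `function(ref, test) -> distance` registered under the metric name;
#' without one, requesting the metric raises an explicit error rather
#' than silently substituting a value.
#'
#' @param name `"DISTS"` or `"LPIPS"`.
#' @param fn backend function, or `NULL` to unregister.
#' @export
iqa_register_backend <- function(name, fn) {
  name <- toupper(name)
  stopifnot(name %in% c("DISTS", "LPIPS"))
  if (is.null(fn)) {
    if (exists(name, envir = iqa_backend_env)) rm(list = name,
                                                  envir = iqa_backend_env)
  } else {
    stopifnot(is.function(fn))
    assign(name, fn, envir = iqa_backend_env)
  }
  invisible(name)
}

#' Is a learned-metric backend registered?
#' @param name metric name.
#' @return logical.
#' @export
iqa_backend_available <- function(name) {
  exists(toupper(name), envir = iqa_backend_env)
}

#' The seven composite-score metrics
#' @return character vector of metric names.
#' @export
iqa_metric_names <- function() {
  c("DISTS", "LPIPS", "VSI", "MS-SSIM", "FSIM", "GMSD", "NLPD")
}

#' Compute a raw full-reference metric
#'
#' @param name one of [iqa_metric_names()].
#' @param ref,test images in \[0, 1\], identical shape.
#' @return raw metric value on its native scale (similarity for VSI,
#'   FSIM, MS-SSIM; distance for GMSD, NLPD, DISTS, LPIPS).
#' @export
compute_raw_metric <- function(name, ref, test) {
  name <- toupper(name)
  same_shape(ref, test)
  check_image(ref, "ref"); check_image(test, "test")
  switch(name,
         "MS-SSIM" = ms_ssim(ref, test),
         "FSIM" = fsim(ref, test),
         "VSI" = vsi(ref, test),
         "GMSD" = gmsd(ref, test),
         "NLPD" = nlpd(ref, test),
         "DISTS" = ,
         "LPIPS" = {
           if (!iqa_backend_available(name))
             stop(sprintf(paste0(
               "%s requires a learned-feature backend; none is ",
               "registered (see iqa_register_backend)"), name),
               call. = FALSE)
           get(name, envir = iqa_backend_env)(ref, test)
         },
         stop(sprintf("unknown metric '%s'", name), call. = FALSE))
}
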