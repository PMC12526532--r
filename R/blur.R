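# Motion-blur synthesis from simulated camera trajectories.
#
# A blur kernel is generated in three steps: (1) a random walk in the
# complex plane whose positions are the cumulative sums of step vectors
# s_k * exp(i * theta_k); (2) sub-pixel bilinear splatting of the
# trajectory samples onto a square kernel grid centred on the trajectory
# centroid, followed by Gaussian smoothing; (3) normalization to unit
# mass. The blurred image is the per-channel convolution of the sharp
# image with this point spread function under reflective boundaries.

#' Blur synthesis specification
#'
#' The blur intensity controls path complexity: at 0 the trajectory is a
#' straight line, at 1 it is a highly random walk with longer average
#' steps and wider turning angles. Step lengths are drawn from a Beta
#' distribution with shape parameters `a = 1 + 3 * intensity`,
#' `b = 3 - 2 * intensity`, scaled by a maximum step of
#' `max_extent / n_steps * (1 + 4 * intensity)`; turning-angle increments
#' are uniform on `(-pi * intensity, pi * intensity)` with a
#' `0.1 * intensity` chance of a sign flip (jitter).
#'
#' @param intensity blur intensity in \[0, 1\].
#' @param n_steps number of trajectory steps (N).
#' @param kernel_size odd kernel side length in pixels (>= 3).
#' @param smoothing_sigma Gaussian smoothing width in pixels (>= 0).
#' @param max_extent trajectory bounding radius in pixels.
#' @param seed RNG seed.
#' @return a `blur_spec` object.
#' @export
blur_spec <- function(intensity, n_steps = 2000L, kernel_size = 31L,
                      smoothing_sigma = 1.0,
                      max_extent = kernel_size / 2 - 2, seed = 1L) {
  num_ok <- function(v) length(v) == 1L && is.numeric(v) && is.finite(v)
  if (!num_ok(intensity) || intensity < 0 || intensity > 1)
    stop("intensity must be a finite value in [0, 1]", call. = FALSE)
  if (!num_ok(n_steps) || n_steps < 1)
    stop("n_steps must be a positive integer", call. = FALSE)
  if (!num_ok(kernel_size) || kernel_size < 3 || kernel_size %% 2 != 1)
    stop("kernel_size must be an odd integer >= 3", call. = FALSE)
  if (!num_ok(smoothing_sigma) || smoothing_sigma < 0)
    stop("smoothing_sigma must be non-negative", call. = FALSE)
  if (!num_ok(max_extent) || max_extent <= 0)
    stop("max_extent must be positive", call. = FALSE)
  if (!num_ok(seed))
    stop("seed must be a finite integer", call. = FALSE)
  structure(list(intensity = intensity, n_steps = as.integer(n_steps),
                 kernel_size = as.integer(kernel_size),
                 smoothing_sigma = smoothing_sigma,
                 max_extent = max_extent, seed = as.integer(seed)),
            class = "blur_spec")
}

#' Generate a random motion trajectory
#'
#' Positions are the cumulative sums `z_j = sum_{k<=j} s_k exp(i theta_k)`
#' (with `z_0 = 0`); the whole path is rescaled if it leaves the
#' `max_extent` bounding radius, preserving the cumulative-sum identity.
#'
#' @param spec a [blur_spec].
#' @return a `motion_trajectory` with fields `positions` (complex),
#'   `steps`, `angles` and `intensity`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "blur_spec"))
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_steps
  i <- spec$intensity
  theta0 <- stats::runif(1L, 0, 2 * pi)
  if (i > 0) {
    d_theta <- stats::runif(n, -pi * i, pi * i)
    flip <- ifelse(stats::runif(n) < 0.1 * i, -1, 1)
    d_theta <- d_theta * flip
  } else {
    d_theta <- numeric(n)
  }
  angles <- theta0 + cumsum(d_theta)
  s_max <- spec$max_extent / n * (1 + 4 * i)
  steps <- s_max * stats::rbeta(n, 1 + 3 * i, 3 - 2 * i)
  positions <- cumsum(steps * exp(1i * angles))
  # Rescale the path so its spatial extent is set by the intensity while
  # its shape (complexity) comes from the walk: without this, long jittery
  # walks fold onto themselves and high intensity would paradoxically
  # yield smaller kernels. The extent never exceeds max_extent.
  r_max <- max(Mod(positions))
  target <- spec$max_extent * (0.15 + 0.85 * i)
  if (r_max > 1e-12) {
    scale <- target / r_max
    positions <- positions * scale
    steps <- steps * scale
  }
  structure(list(positions = positions, steps = steps, angles = angles,
                 intensity = i),
            class = "motion_trajectory")
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_kernel <- function(k, sigma) {
  if (sigma <= 0) return(k)
  g <- gauss_kernel_1d(sigma)
  r <- (length(g) - 1L) %/% 2L
  n <- nrow(k)
  pad <- matrix(0, n + 2L * r, n + 2L * r)
  pad[r + seq_len(n), r + seq_len(n)] <- k
  # separable convolution, zero boundary (mass restored by renormalizing)
  tmp <- apply(pad, 2L, function(col) stats::filter(col, g, sides = 2L))
  out <- t(apply(tmp, 1L, function(row) stats::filter(row, g, sides = 2L)))
  out <- out[r + seq_len(n), r + seq_len(n)]
  out[is.na(out)] <- 0
  out
}

#' Rasterize a trajectory into a point spread function
#'
#' The trajectory is centred on its centroid, each sample is splatted
#' with bilinear sub-pixel weights onto the kernel grid, the raster is
#' smoothed with a Gaussian filter, and the result is normalized to unit
#' mass.
#'
#' @param traj a `motion_trajectory`.
#' @param kernel_size odd kernel side length.
#' @param smoothing_sigma Gaussian width in pixels (0 disables smoothing).
#' @return a `psf` object: a non-negative `kernel_size` x `kernel_size`
#'   matrix summing to 1.
#' @export
trajectory_to_psf <- function(traj, kernel_size = 31L,
                              smoothing_sigma = 1.0) {
  stopifnot(inherits(traj, "motion_trajectory"))
  if (kernel_size < 3L || kernel_size %% 2L != 1L)
    stop("kernel_size must be an odd integer >= 3", call. = FALSE)
  pts <- traj$positions - mean(traj$positions)
  half <- (kernel_size - 1L) / 2
  ext <- max(abs(c(Re(pts), Im(pts))))
  if (ext > half) {
    required <- 2L * ceiling(ext) + 3L
    stop(sprintf(paste0("trajectory extent %.2f px exceeds the kernel; ",
                        "a kernel_size of at least %d is required"),
                 ext, required), call. = FALSE)
  }
  centre <- half + 1
  cx <- Re(pts) + centre
  cy <- Im(pts) + centre
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  k_flat <- numeric(kernel_size * kernel_size)
  wts <- list((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (q in 1:4) {
    ry <- pmin(pmax(y0 + offs[[q]][1L], 1), kernel_size)
    rx <- pmin(pmax(x0 + offs[[q]][2L], 1), kernel_size)
    ind <- (rx - 1) * kernel_size + ry
    acc <- rowsum(wts[[q]], ind)
    k_flat[as.integer(rownames(acc))] <-
      k_flat[as.integer(rownames(acc))] + acc[, 1L]
  }
  k <- matrix(k_flat, kernel_size, kernel_size)
  k <- smooth_kernel(k, smoothing_sigma)
  k[k < 0] <- 0
  k <- k / sum(k)
  structure(k, class = c("psf", "matrix"))
}

fft_convolve2 <- function(channel, kernel) {
  kh <- nrow(kernel)
  r <- (kh - 1L) %/% 2L
  d <- dim(channel)
  ih <- c(rev(seq_len(r) + 1L), seq_len(d[1L]), d[1L] - seq_len(r))
  iw <- c(rev(seq_len(r) + 1L), seq_len(d[2L]), d[2L] - seq_len(r))
  padded <- channel[ih, iw]
  pd <- dim(padded)
  kp <- matrix(0, pd[1L], pd[2L])
  kp[seq_len(kh), seq_len(kh)] <- kernel
  # shift kernel centre to (1, 1) for circular convolution
  kp <- kp[c((r + 1):pd[1L], seq_len(r)), c((r + 1):pd[2L], seq_len(r))]
  out <- Re(stats::fft(stats::fft(padded) * stats::fft(kp),
                       inverse = TRUE)) / length(padded)
  out[r + seq_len(d[1L]), r + seq_len(d[2L])]
}

#' Apply a motion-blur kernel to an image
#'
#' Convolves each channel independently with the PSF under reflective
#' boundary handling, then clips to \[0, 1\]. Constant images are exact
#' fixed points because the PSF has unit mass.
#'
#' @param image array (H, W, 3) or (H, W) in \[0, 1\].
#' @param psf a [trajectory_to_psf] kernel (or any unit-mass non-negative
#'   odd-sized square matrix).
#' @return blurred image, same shape.
#' @export
apply_motion_blur <- function(image, psf) {
  check_image(image)
  if (!is.matrix(psf) || nrow(psf) != ncol(psf))
    stop("psf must be a square matrix", call. = FALSE)
  if (any(psf < 0) || abs(sum(psf) - 1) > 1e-6)
    stop("psf must be non-negative with unit mass", call. = FALSE)
  d <- dim(image)
  if (nrow(psf) > min(d[1L], d[2L]))
    stop(sprintf("psf (%d px) is larger than the image (%d x %d)",
                 nrow(psf), d[1L], d[2L]), call. = FALSE)
  blur1 <- function(ch) fft_convolve2(ch, psf)
  if (length(d) == 2L) {
    out <- blur1(image)
  } else {
    out <- array(0, d)
    for (c in seq_len(d[3L])) out[, , c] <- blur1(image[, , c])
  }
  pmin(pmax(out, 0), 1)
}

#' Synthesize a blurred counterpart of a sharp image
#'
#' @param image sharp RGB image in \[0, 1\].
#' @param spec a [blur_spec].
#' @return a `sharp_blur_pair`: list with `sharp`, `blurred` and `spec`.
#' @export
synthesize_blur <- function(image, spec) {
  traj <- generate_trajectory(spec)
  psf <- trajectory_to_psf(traj, spec$kernel_size, spec$smoothing_sigma)
  structure(list(sharp = image, blurred = apply_motion_blur(image, psf),
                 spec = spec),
            class = "sharp_blur_pair")
}

rotate_reflect <- function(image, angle_deg) {
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  refl <- function(p, n) {
    p <- abs(p - 1) %% (2 * (n - 1))
    pmin(p, 2 * (n - 1) - p) + 1
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- refl(y0, h); iy1 <- refl(y0 + 1, h)
  ix0 <- refl(x0, w); ix1 <- refl(x0 + 1, w)
  out <- array(0, d)
  for (c in seq_len(d[3L])) {
    ch <- image[, , c]
    out[, , c] <-
      ch[cbind(c(iy0), c(ix0))] * (1 - fy) * (1 - fx) +
      ch[cbind(c(iy1), c(ix0))] * fy * (1 - fx) +
      ch[cbind(c(iy0), c(ix1))] * (1 - fy) * fx +
      ch[cbind(c(iy1), c(ix1))] * fy * fx
  }
  out
}

#' Augment a sharp image
#'
#' Produces three variants of a sharp source: an exact horizontal mirror,
#' a random small rotation (uniform in +/-15 degrees, bilinear resampling
#' with reflective fill), and a brightness rescaling (factor uniform in
#' \[0.7, 1.3\], clipped). One source therefore yields three additional
#' sharp images.
#'
#' @param image RGB image in \[0, 1\].
#' @param seed RNG seed.
#' @param brightness_factor optional fixed brightness factor (overrides
#'   the random draw).
#' @param angle_deg optional fixed rotation angle in degrees.
#' @return list of three images named `flip`, `rotate`, `brightness`.
#' @export
augment_sharp <- function(image, seed = 1L, brightness_factor = NULL,
                          angle_deg = NULL) {
  check_image(image)
  image <- if (length(dim(image)) == 2L)
    array(image, c(dim(image), 1L)) else image
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (is.null(angle_deg)) angle_deg <- stats::runif(1L, -15, 15)
  if (is.null(brightness_factor))
    brightness_factor <- stats::runif(1L, 0.7, 1.3)
  list(flip = image[, rev(seq_len(dim(image)[2L])), , drop = FALSE],
       rotate = rotate_reflect(image, angle_deg),
       brightness = pmin(pmax(image * brightness_factor, 0), 1))
}

#' Build a paired sharp/blurred dataset with splits
#'
#' Every sharp image receives a blurred counterpart synthesized at one of
#' the supplied intensities (cycled deterministically), and pair
#' identifiers are partitioned into train/val/test splits.
#'
#' @param sharp_images named list of RGB images in \[0, 1\].
#' @param intensities blur intensities to cycle over.
#' @param ratios train/val/test split proportions (must sum to 1).
#' @param seed RNG seed controlling blur draws and split assignment.
#' @param blur_args extra arguments passed to [blur_spec] (e.g.
#'   `kernel_size`).
#' @return a `paired_dataset`: list with `manifest` (data.frame of
#'   `id`, `split`, `intensity`), `pairs` (list of `sharp_blur_pair`) and
#'   `split_ratio`.
#' @export
build_paired_dataset <- function(sharp_images,
                                 intensities = c(0.25, 0.5, 0.75),
                                 ratios = c(0.8, 0.1, 0.1), seed = 1L,
                                 blur_args = list()) {
  if (length(sharp_images) == 0L)
    stop("empty dataset: at least one sharp image is required",
         call. = FALSE)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three proportions summing to 1", call. = FALSE)
  n <- length(sharp_images)
  ids <- names(sharp_images)
  if (is.null(ids)) ids <- sprintf("img%05d", seq_len(n))
  manifest <- data.frame(id = ids,
                         split = assign_splits(n, ratios, seed),
                         intensity = rep_len(intensities, n),
                         stringsAsFactors = FALSE)
  pairs <- vector("list", n)
  names(pairs) <- ids
  for (j in seq_len(n)) {
    spec <- do.call(blur_spec, c(list(intensity = manifest$intensity[j],
                                      seed = seed + j), blur_args))
    pairs[[j]] <- synthesize_blur(sharp_images[[j]], spec)
  }
  structure(list(manifest = manifest, pairs = pairs, split_ratio = ratios),
            class = "paired_dataset")
}

assign_splits <- function(n, ratios, seed) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  bounds <- round(cumsum(ratios) * n)
  sizes <- diff(c(0L, bounds))
  labels <- rep(c("train", "val", "test"), times = sizes)
  labels[sample.int(n)]
}

#' Write a paired dataset to disk
#'
#' Writes `<id>_sharp.png` / `<id>_blur.png` images plus a JSON manifest.
#'
#' @param dataset a [build_paired_dataset] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_paired_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in dataset$manifest$id) {
    write_image(dataset$pairs[[id]]$sharp,
                file.path(dir, paste0(id, "_sharp.png")))
    write_image(dataset$pairs[[id]]$blurred,
                file.path(dir, paste0(id, "_blur.png")))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(split_ratio = dataset$split_ratio,
                            entries = dataset$manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
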