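# Blur-aware dynamic routing: images are dispatched to the deblurring
# network only when the variance of their Laplacian falls below a
# threshold; sharp images bypass restoration and go straight to the
# downstream task.

#' Variance-of-Laplacian sharpness
#'
#' Converts the image to BT.601 luma, convolves with the 4-neighbour
#' Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]` under reflective
#' borders, and returns the population variance of the response. Constant
#' images score exactly 0; blur suppresses high frequencies and lowers
#' the score.
#'
#' @param image RGB or grayscale array in \[0, 1\], at least 3 x 3.
#' @return non-negative sharpness value.
#' @export
laplacian_variance <- function(image) {
  check_image(image)
  d <- dim(image)
  if (d[1L] < 3L || d[2L] < 3L)
    stop("image must be at least 3 x 3", call. = FALSE)
  g <- luma(image)
  up <- g[c(2L, seq_len(d[1L] - 1L)), ]
  dn <- g[c(seq_len(d[1L] - 1L) + 1L, d[1L] - 1L), ]
  lf <- g[, c(2L, seq_len(d[2L] - 1L))]
  rt <- g[, c(seq_len(d[2L] - 1L) + 1L, d[2L] - 1L)]
  resp <- up + dn + lf + rt - 4 * g
  mean((resp - mean(resp))^2)
}

#' Route an image by blur level
#'
#' Dispatch rule: sharpness `L < T` sends the image to deblurring;
#' `L >= T` bypasses it (the boundary is strict, an image exactly at the
#' threshold is considered sharp enough).
#'
#' @param image RGB image in \[0, 1\].
#' @param threshold positive sharpness threshold `T`.
#' @return a `routing_decision`: list with `sharpness`, `threshold` and
#'   `route` (`"deblur"` or `"bypass"`).
#' @export
route_image <- function(image, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive number", call. = FALSE)
  l <- laplacian_variance(image)
  structure(list(sharpness = l, threshold = threshold,
                 route = if (l < threshold) "deblur" else "bypass"),
            class = "routing_decision")
}

#' Calibrate a routing threshold from sharp references
#'
#' The threshold is the 25th percentile of the Laplacian-variance scores
#' of a sharp reference set: images scoring below the bulk of known-sharp
#' material are routed to restoration. The value is scenario-dependent
#' and should be overridden when a better operating point is known.
#'
#' @param sharp_images list of sharp RGB images.
#' @param probs quantile used for the threshold.
#' @return positive threshold.
#' @export
calibrate_threshold <- function(sharp_images, probs = 0.25) {
  if (length(sharp_images) == 0L)
    stop("need at least one sharp reference image", call. = FALSE)
  ls <- vapply(sharp_images, laplacian_variance, numeric(1))
  as.numeric(stats::quantile(ls, probs = probs, type = 7))
}

#' Process an image through the routed pipeline
#'
#' Applies `deblur_fn` only when the routing decision is `"deblur"`, then
#' always applies `downstream_fn`, and returns the downstream output
#' together with the decision.
#'
#' @param image RGB image in \[0, 1\].
#' @param threshold positive routing threshold.
#' @param deblur_fn function(image) -> image, the restoration stage.
#' @param downstream_fn function(image) -> any, the downstream consumer
#'   (default passes the image through).
#' @return list with `output`, `decision`.
#' @export
process_routed <- function(image, threshold, deblur_fn,
                           downstream_fn = identity) {
  stopifnot(is.function(deblur_fn), is.function(downstream_fn))
  decision <- route_image(image, threshold)
  staged <- if (decision$route == "deblur") {
    tryCatch(deblur_fn(image), error = function(e)
      stop(sprintf("deblurring stage failed (route=%s, L=%.4g): %s",
                   decision$route, decision$sharpness,
                   conditionMessage(e)), call. = FALSE))
  } else {
    image
  }
  out <- tryCatch(downstream_fn(staged), error = function(e)
    stop(sprintf("downstream stage failed (route=%s, L=%.4g): %s",
                 decision$route, decision$sharpness, conditionMessage(e)),
         call. = FALSE))
  list(output = out, decision = decision)
}
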