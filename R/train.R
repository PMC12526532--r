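# Composite loss, relativistic least-squares adversarial objective,
# learning-rate schedule, and the adversarial training loop.

#' Loss weights
#'
#' Content loss is `0.7 * L_p + 0.3 * L_1` (perceptual + pixel terms) and
#' the generator total is `L_content + 0.005 * L_adv`.
#'
#' @param w_perceptual,w_l1,w_adv positive weights; the two content
#'   weights must sum to 1.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(w_perceptual = 0.7, w_l1 = 0.3, w_adv = 0.005) {
  if (any(c(w_perceptual, w_l1, w_adv) <= 0))
    stop("loss weights must be positive", call. = FALSE)
  if (abs(w_perceptual + w_l1 - 1) > 1e-8)
    stop("w_perceptual + w_l1 must equal 1", call. = FALSE)
  structure(list(w_perceptual = w_perceptual, w_l1 = w_l1, w_adv = w_adv),
            class = "loss_weights")
}

#' Identity feature extractor
#'
#' Uses raw pixels as the perceptual feature space. This is the default
#' extractor: it keeps the loss self-contained while remaining a strictly
#' positive-definite distance. A learned deep-feature extractor can be
#' plugged in through the same interface (`forward(x)` and
#' `backward(x, dfeat)`).
#' @return an extractor object.
#' @export
identity_extractor <- function() {
  structure(list(forward = function(x) x,
                 backward = function(x, dfeat) dfeat),
            class = "feature_extractor")
}

#' Fixed random-projection feature extractor
#'
#' Projects RGB pixels through a frozen random 1x1 convolution followed
#' by a leaky rectifier. A cheap stand-in for a deep perceptual space in
#' small-scale experiments: it mixes channels so the perceptual term is
#' not identical to the pixel term.
#'
#' @param n_features projection width.
#' @param seed RNG seed of the frozen weights.
#' @return an extractor object.
#' @export
random_projection_extractor <- function(n_features = 8L, seed = 1L) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  par <- init_conv(3L, n_features, 1L)
  structure(list(
    forward = function(x) {
      r <- conv_fwd(as_t4(x), par)
      lrelu_fwd(r$y)$y
    },
    backward = function(x, dfeat) {
      r <- conv_fwd(as_t4(x), par)
      l <- lrelu_fwd(r$y)
      conv_bwd(lrelu_bwd(dfeat, l$cache), par, r$cache)$dx
    }), class = "feature_extractor")
}

as_extractor <- function(fe) {
  if (inherits(fe, "feature_extractor")) return(fe)
  if (is.null(fe)) return(identity_extractor())
  stop("feature_extractor must be built by identity_extractor(), ",
       "random_projection_extractor() or follow the same interface",
       call. = FALSE)
}

#' Content loss
#'
#' `w_perceptual * L_p + w_l1 * L_1`, where `L_p` is the mean squared
#' distance between extractor features of prediction and target and
#' `L_1` is the mean absolute pixel error.
#'
#' @param pred,target image batches of identical shape.
#' @param feature_extractor an extractor (default identity).
#' @param weights a [loss_weights].
#' @return non-negative loss with attributes `l_p` and `l_1`.
#' @export
content_loss <- function(pred, target, feature_extractor = NULL,
                         weights = loss_weights()) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target must have identical shape", call. = FALSE)
  fe <- as_extractor(feature_extractor)
  fdiff <- fe$forward(pred) - fe$forward(target)
  l_p <- mean(fdiff^2)
  l_1 <- mean(abs(pred - target))
  structure(weights$w_perceptual * l_p + weights$w_l1 * l_1,
            l_p = l_p, l_1 = l_1)
}

content_loss_grad <- function(pred, target, fe, weights) {
  fp <- fe$forward(pred)
  ft <- fe$forward(target)
  fdiff <- fp - ft
  l_p <- mean(fdiff^2)
  l_1 <- mean(abs(pred - target))
  d_lp <- fe$backward(pred, 2 * fdiff / length(fdiff))
  d_l1 <- sign(pred - target) / length(pred)
  list(value = weights$w_perceptual * l_p + weights$w_l1 * l_1,
       l_p = l_p, l_1 = l_1,
       grad = weights$w_perceptual * d_lp + weights$w_l1 * d_l1)
}

ra_ls_pair <- function(dr, df) {
  mr <- mean(dr); mf <- mean(df)
  d_loss <- 0.5 * (mean((dr - mf - 1)^2) + mean((df - mr + 1)^2))
  g_loss <- 0.5 * (mean((df - mr - 1)^2) + mean((dr - mf + 1)^2))
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Relativistic least-squares adversarial losses
#'
#' Averaged relativistic form: each critic score is compared with the
#' mean score of the opposing class, under a least-squares objective.
#' `d_loss = 0.5 * (mean((D_r - mean(D_f) - 1)^2) +
#' mean((D_f - mean(D_r) + 1)^2))`; the generator loss swaps the roles.
#' A shared shift of all scores leaves both losses unchanged.
#'
#' @param real_scores,fake_scores numeric arrays of critic scores, or
#'   lists of arrays (one per critic).
#' @param aggregate how to combine per-critic losses when lists are
#'   given: `"sum"` (default) or `"mean"`.
#' @return list with `g_loss` and `d_loss`.
#' @export
adversarial_losses <- function(real_scores, fake_scores,
                               aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(real_scores)) real_scores <- list(real_scores)
  if (!is.list(fake_scores)) fake_scores <- list(fake_scores)
  stopifnot(length(real_scores) == length(fake_scores))
  ok <- function(s) length(s) > 0L && all(is.finite(s))
  if (!all(vapply(real_scores, ok, logical(1))) ||
      !all(vapply(fake_scores, ok, logical(1))))
    stop("scores must be non-empty and finite", call. = FALSE)
  per <- mapply(ra_ls_pair, real_scores, fake_scores, SIMPLIFY = FALSE)
  agg <- if (aggregate == "sum") sum else mean
  list(g_loss = agg(vapply(per, `[[`, numeric(1), "g_loss")),
       d_loss = agg(vapply(per, `[[`, numeric(1), "d_loss")))
}

# gradients of the averaged relativistic least-squares objectives
ra_ls_d_grad <- function(dr, df) {
  nr <- length(dr); nf <- length(df)
  mr <- mean(dr); mf <- mean(df)
  ddr <- (dr - mf - 1) / nr - mean(df - mr + 1) / nr
  ddf <- (df - mr + 1) / nf - mean(dr - mf - 1) / nf
  list(ddr = ddr, ddf = ddf)
}

ra_ls_g_grad_fake <- function(dr, df) {
  nf <- length(df)
  (df - mean(dr) - 1) / nf - mean(dr - mean(df) + 1) / nf
}

#' Total generator loss
#'
#' @param content content-loss value.
#' @param adv adversarial generator loss.
#' @param weights a [loss_weights].
#' @return `content + w_adv * adv`.
#' @export
total_generator_loss <- function(content, adv, weights = loss_weights()) {
  stopifnot(is.finite(content), is.finite(adv))
  as.numeric(content) + weights$w_adv * adv
}

#' Training configuration
#'
#' Defaults follow the published schedule: Adam with default moments and
#' no weight decay, initial learning rate 1e-4 decaying linearly from
#' epoch 10 to 1e-6 at the final epoch, batch size 4, 200 epochs, and
#' one discriminator update per generator update.
#'
#' @param lr_init,lr_final initial/final learning rates.
#' @param decay_start_epoch epoch at which linear decay begins.
#' @param total_epochs schedule length.
#' @param batch_size images per update.
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param seed run seed.
#' @return a `train_config`.
#' @export
train_config <- function(lr_init = 1e-4, lr_final = 1e-6,
                         decay_start_epoch = 10L, total_epochs = 200L,
                         batch_size = 4L, d_steps_per_g_step = 1L,
                         seed = 1L) {
  if (lr_final >= lr_init)
    stop("lr_final must be below lr_init", call. = FALSE)
  if (decay_start_epoch >= total_epochs)
    stop("decay_start_epoch must precede total_epochs", call. = FALSE)
  structure(list(lr_init = lr_init, lr_final = lr_final,
                 decay_start_epoch = as.integer(decay_start_epoch),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' Constant at `lr_init` until `decay_start_epoch`, then linear decay
#' reaching `lr_final` at `total_epochs`. Continuous at the knee and
#' non-increasing afterwards.
#'
#' @param epoch epoch index in `[0, total_epochs]`.
#' @param cfg a [train_config].
#' @return learning rate.
#' @export
learning_rate <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0 | epoch > cfg$total_epochs))
    stop("epoch out of schedule range", call. = FALSE)
  frac <- pmax(0, epoch - cfg$decay_start_epoch) /
    (cfg$total_epochs - cfg$decay_start_epoch)
  cfg$lr_init + frac * (cfg$lr_final - cfg$lr_init)
}

batch_from_pairs <- function(pairs, field) {
  d <- dim(pairs[[1L]][[field]])
  out <- array(0, c(d[1L], d[2L], d[3L], length(pairs)))
  for (j in seq_along(pairs)) out[, , , j] <- pairs[[j]][[field]]
  out
}

#' Train the deblurring network
#'
#' Alternating adversarial training: per batch, the double-scale
#' discriminator is updated `d_steps_per_g_step` times with the
#' relativistic least-squares objective (per-critic losses averaged),
#' then the generator is updated once on
#' `L_content + w_adv * L_adv`. Adam with default moments, no weight
#' decay, no gradient clipping; fully seeded.
#'
#' @param generator an `agg_generator`.
#' @param discriminator an `agg_discriminator`.
#' @param dataset a `paired_dataset` (its train split is used) or a bare
#'   list of `sharp_blur_pair`s.
#' @param cfg a [train_config]; training runs for
#'   `min(cfg$total_epochs, epochs)` epochs.
#' @param epochs number of epochs to actually run (the schedule still
#'   spans `cfg$total_epochs`).
#' @param feature_extractor perceptual extractor (default identity).
#' @param weights a [loss_weights].
#' @param checkpoint_path optional RDS path; the trained models and
#'   config are stored there after the final epoch.
#' @param verbose print per-epoch losses.
#' @return list with the trained `generator`, `discriminator`, `history`
#'   data.frame (epoch, lr, loss_content, loss_adv, loss_total, loss_d)
#'   and update counters.
#' @export
fit_deblur_gan <- function(generator, discriminator, dataset,
                           cfg = train_config(), epochs = cfg$total_epochs,
                           feature_extractor = NULL,
                           weights = loss_weights(),
                           checkpoint_path = NULL, verbose = FALSE) {
  pairs <- if (inherits(dataset, "paired_dataset")) {
    ids <- dataset$manifest$id[dataset$manifest$split == "train"]
    dataset$pairs[ids]
  } else {
    dataset
  }
  if (length(pairs) == 0L)
    stop("empty training dataset", call. = FALSE)
  fe <- as_extractor(feature_extractor)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  opt_g <- adam_state(generator$params)
  opt_d <- adam_state(discriminator$params)
  n <- length(pairs)
  bs <- cfg$batch_size
  hist <- list()
  g_updates <- 0L
  d_updates <- 0L
  for (epoch in seq_len(min(epochs, cfg$total_epochs))) {
    lr <- learning_rate(epoch, cfg)
    ord <- sample.int(n)
    ec <- ea <- et <- ed <- 0
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      sel <- ord[start:min(start + bs - 1L, n)]
      sharp <- batch_from_pairs(pairs[sel], "sharp")
      blur <- batch_from_pairs(pairs[sel], "blurred")
      fake <- generator_forward(generator, blur)
      # -- discriminator step(s)
      d_loss <- NA_real_
      for (k in seq_len(cfg$d_steps_per_g_step)) {
        sr <- discriminator_forward(discriminator, sharp,
                                    with_cache = TRUE)
        sf <- discriminator_forward(discriminator, fake,
                                    with_cache = TRUE)
        gg <- ra_ls_d_grad(sr$global, sf$global)
        gl <- ra_ls_d_grad(sr$local, sf$local)
        d_loss <- adversarial_losses(
          list(sr$global, sr$local), list(sf$global, sf$local),
          aggregate = "mean")$d_loss
        if (!is.finite(d_loss))
          stop(sprintf("non-finite discriminator loss at epoch %d",
                       epoch), call. = FALSE)
        br <- discriminator_backward(discriminator, sr$cache,
                                     array(gg$ddr / 2, dim(sr$global)),
                                     array(gl$ddr / 2, dim(sr$local)))
        bf <- discriminator_backward(discriminator, sf$cache,
                                     array(gg$ddf / 2, dim(sf$global)),
                                     array(gl$ddf / 2, dim(sf$local)))
        grads_d <- tree_map2(`+`, br$grads, bf$grads)
        st <- adam_step(discriminator$params, grads_d, opt_d, lr)
        discriminator$params <- st$params
        opt_d <- st$state
        d_updates <- d_updates + 1L
      }
      # -- generator step
      fw <- generator_forward(generator, blur, with_cache = TRUE)
      cl <- content_loss_grad(fw$y, sharp, fe, weights)
      sr <- discriminator_forward(discriminator, sharp)
      sf <- discriminator_forward(discriminator, fw$y, with_cache = TRUE)
      adv <- adversarial_losses(
        list(sr$global, sr$local), list(sf$global, sf$local),
        aggregate = "mean")$g_loss
      dgf_g <- ra_ls_g_grad_fake(sr$global, sf$global)
      dgf_l <- ra_ls_g_grad_fake(sr$local, sf$local)
      bimg <- discriminator_backward(discriminator, sf$cache,
                                     array(dgf_g / 2, dim(sf$global)),
                                     array(dgf_l / 2, dim(sf$local)))
      total <- total_generator_loss(cl$value, adv, weights)
      if (!is.finite(total))
        stop(sprintf("non-finite generator loss at epoch %d", epoch),
             call. = FALSE)
      dy <- cl$grad + weights$w_adv * bimg$dx
      bw <- generator_backward(generator, fw$cache, dy)
      st <- adam_step(generator$params, bw$grads, opt_g, lr)
      generator$params <- st$params
      opt_g <- st$state
      g_updates <- g_updates + 1L
      ec <- ec + cl$value; ea <- ea + adv; et <- et + total
      ed <- ed + d_loss; nb <- nb + 1L
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, loss_content = ec / nb, loss_adv = ea / nb,
      loss_total = et / nb, loss_d = ed / nb)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.2e content %.5f adv %.4f total %.5f d %.4f",
        epoch, lr, ec / nb, ea / nb, et / nb, ed / nb))
  }
  out <- list(generator = generator, discriminator = discriminator,
              history = do.call(rbind, hist),
              g_updates = g_updates, d_updates = d_updates)
  if (!is.null(checkpoint_path)) {
    saveRDS(list(generator = generator, discriminator = discriminator,
                 cfg = cfg, history = out$history), checkpoint_path)
    out$checkpoint <- checkpoint_path
  }
  out
}
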