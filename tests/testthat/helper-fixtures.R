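# shared fixtures and independent oracles (deliberately naive implementations)

make_scene <- function(seed, size = 64L) {
  generate_synthetic_scene(size, size, seed = seed)
}

# dense O(n^2 k^2) 2-D convolution with reflective borders; the slow
# reference against which the fft-based path is checked
naive_conv2_reflect <- function(channel, kernel) {
  kh <- nrow(kernel)
  r <- (kh - 1L) %/% 2L
  h <- nrow(channel); w <- ncol(channel)
  refl <- function(p, n) {
    if (p < 1L) return(2L - p)
    if (p > n) return(2L * n - p)
    p
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in seq_len(kh)) {
        for (b in seq_len(kh)) {
          ii <- refl(i - (a - r - 1L), h)
          jj <- refl(j - (b - r - 1L), w)
          acc <- acc + kernel[a, b] * channel[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# learned-metric stand-ins: plain pixel distances (0 for identical images,
# so the normalized score of a perfect restoration is 1)
with_learned_mocks <- function(code) {
  iqa_register_backend("DISTS", function(ref, test) mean(abs(ref - test)))
  iqa_register_backend("LPIPS", function(ref, test) mean((ref - test)^2))
  on.exit({
    iqa_register_backend("DISTS", NULL)
    iqa_register_backend("LPIPS", NULL)
  })
  force(code)
}

# desk-scale training conditions used by the training acceptance check:
# 250 scenes at 64 x 64 split 8:1:1 (200 train), 13-px kernels, 5 epochs,
# reduced-width generator, identity perceptual extractor
run_desk_training <- function(seed, lr = 2e-4, n_scenes = 250L,
                              epochs = 5L) {
  scenes <- lapply(seq_len(n_scenes) + 1000L * seed,
                   function(s) generate_synthetic_scene(64, 64, seed = s))
  ds <- build_paired_dataset(scenes, seed = seed,
                             blur_args = list(kernel_size = 13,
                                              n_steps = 500))
  gen <- build_generator(generator_config_small(), seed = seed,
                         proj_gain = 0.01)
  disc <- build_double_scale_discriminator(16L, seed = seed)
  cfg <- train_config(lr_init = lr, lr_final = lr / 100, seed = seed)
  fit <- fit_deblur_gan(gen, disc, ds, cfg, epochs = epochs)
  ids <- ds$manifest$id[ds$manifest$split == "val"]
  ev <- vapply(ids, function(id) {
    p <- ds$pairs[[id]]
    rest <- deblur_image(fit$generator, p$blurred)
    c(rest = iqa_report(p$sharp, rest)$composite,
      blur = iqa_report(p$sharp, p$blurred)$composite)
  }, numeric(2))
  list(history = fit$history,
       content_drop = fit$history$loss_content[1L] -
         fit$history$loss_content[epochs],
       median_restored = stats::median(ev["rest", ]),
       median_blurred = stats::median(ev["blur", ]))
}
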