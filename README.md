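# aggdeblur

Motion blur from camera shake and plant movement is a leading cause of
failed fruit detection in orchard vision systems. `aggdeblur` is an R
toolkit for that problem: it synthesizes realistic motion blur to build
paired training data, restores blurred images with a lightweight
attention-ghost generative adversarial network, scores restoration
quality with a seven-metric composite, routes images past the restorer
when they are already sharp, and reports how detection metrics change
across sharp / blurred / restored conditions. It is aimed at
agricultural-vision researchers who need a CPU-friendly, fully seeded,
dependency-light restoration pipeline.

## The models in brief

**Blur synthesis.** A camera trajectory is a random walk in the complex
plane, `z_j = sum_{k<=j} s_k e^{i theta_k}`, with Beta-distributed step
lengths and intensity-bounded turning angles; a blur intensity in
[0, 1] moves the path from a straight line to an erratic scrawl. The
path is splatted onto a kernel grid, Gaussian-smoothed, normalized to
unit mass, and convolved with each RGB channel (reflective borders).

**Restoration network.** A feature-pyramid generator over a Ghost
convolution encoder (stage widths 16/24/40/80/160), with fusion stages
refined by Attention-Ghost modules (squeeze-and-excitation over the
concatenated intrinsic + cheap features) and gated half-instance
normalization `y = (1 + S) x`, `S = gamma * alpha * x_norm + beta`,
which is an exact identity at its initialization `alpha = 1, gamma = 0,
beta = 0`. The output is a residual correction of the input. The built
generator has 1,527,807 trainable parameters (the published 1.53 M
budget). Training pairs a relativistic least-squares double-scale
critic with the content loss `0.7 L_p + 0.3 L_1`, total
`L_content + 0.005 L_adv`. Forward and backward passes are implemented
in this package (R + C++ kernels) and validated against
central-difference gradients.

**Quality scoring.** DISTS, LPIPS, VSI, MS-SSIM, FSIM, GMSD and NLPD,
each normalized to [0, 1] (1 = best), averaged into a composite score
`S`, and banded: `S < 0.6` severe, 0.6–0.7 moderate, 0.7–0.8 mild,
`>= 0.8` sharp. The five classical metrics are implemented natively;
the two learned ones are pluggable backends.

**Routing.** Variance of the Laplacian `L` against a threshold `T`:
`L < T` goes through the restorer, otherwise straight to the detector.

## Worked example

```r
library(aggdeblur)

# a deterministic orchard-like test scene and a strong synthetic blur
sharp <- generate_synthetic_scene(64, 64, seed = 0)
pair  <- synthesize_blur(sharp, blur_spec(intensity = 0.75, seed = 5))

laplacian_variance(sharp)         # 0.1972
laplacian_variance(pair$blurred)  # 0.0002
route_image(pair$blurred, threshold = 0.02)$route  # "deblur"

# score the blurred image against its sharp reference
# (learned metrics need a backend; here: simple pixel-distance stand-ins)
iqa_register_backend("DISTS", function(r, t) mean(abs(r - t)))
iqa_register_backend("LPIPS", function(r, t) mean((r - t)^2))
iqa_report(sharp, pair$blurred)
#>     name    raw normalized
#>    DISTS 0.0810     0.9190
#>    LPIPS 0.0181     0.9819
#>      VSI 0.8198     0.8198
#>  MS-SSIM 0.6558     0.6558
#>     FSIM 0.6997     0.6997
#>     GMSD 0.2432     0.3051
#>     NLPD 0.1313     0.8687
#> composite S = 0.750 (mild)
```

A 0.75-intensity blur drops the composite to 0.750 — "mild" on the
severity scale — with the gradient-based metrics (GMSD, FSIM) reacting
most strongly, exactly the behaviour the composite is designed to
capture. Training a reduced-width generator on 200 synthetic pairs for
five epochs (`fit_deblur_gan()`, ~2 minutes on one CPU) lowers the
content loss below the identity baseline and lifts the median composite
of restored held-out images above their blurred inputs; the full-width
model and schedule are the same code at larger settings.

A command-line front end is installed at
`system.file("cli", "aggdeblur", package = "aggdeblur")` with
`synth`, `deblur`, `train`, `score` and `route` subcommands.

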