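# sampen2d

Exact and fast Monte Carlo estimation of **two-dimensional sample entropy
(SampEn2D)** for grayscale images, in R.

SampEn2D quantifies the irregularity of an image texture: it is the
negative log conditional probability that two image patches which are
similar at size *m* × *m* (Chebyshev distance within a tolerance *r*)
remain similar when extended to (*m*+1) × (*m*+1),

```
SampEn2D(U, m, r) = −log( φ^(m+1)(r) / φ^m(r) )
```

where φ^m(r) is the average fraction of template pairs within distance
*r* (self-matches excluded, natural log, and by convention
*r* = 0.3 × SD of the image). Low values mean regular, predictable
texture; high values mean irregularity. It is used as a complexity
feature for medical images (e.g. distinguishing benign from malignant
histology slices) and natural textures.

Direct computation enumerates all template pairs and scales quadratically
with the pixel count, which is prohibitive for large images. This package
implements, alongside the exact method:

* **MCSampEn2D** — a Monte Carlo estimator that repeatedly subsamples
  `N0` template anchors over `N1` epochs and averages the match counts;
  its cost is independent of image size.
* **UCBMCSampEn2D** — the same epochs, but weighted by a softmax over
  per-epoch upper confidence bounds `a·R(b·er_k) + c·sqrt(2 ln k)`, where
  the reward `R` (cosine or Gaussian kernel) favors epochs whose entropy
  sits close to the running mean — a multi-armed-bandit-style
  reweighting that damps unrepresentative epochs.

A synthetic `MIX(p)` image generator, an evaluation harness
(convergence curves, per-round error spread), raster I/O (PNG, TIFF,
PGM/PPM) and a command-line tool round out the package. See the vignette
`vignettes/sampen2d-methods.Rmd` for the model, conventions and design
decisions.

## Worked example

```r
library(sampen2d)

# a 128 x 128 median-binarized MIX(0.9) image: mostly noise, high entropy
u <- mix2d(0.9, 128, 128, binarize = TRUE, seed = 42)

sampen2d(u, m = 2, r_value = 0.3)                      # exact
#> Two-dimensional sample entropy
#>   method: exact (direct template enumeration)
#>   image:  128 x 128    m = 2, r = 0.3 (sd_relative, r_eff = 0.15)
#>   SampEn2D = 3.46738

sampen2d(u, method = "mc", N0 = 128, N1 = 300, seed = 1)
#> ...
#>   epochs: N1 = 300, N0 = 128, replacement = FALSE, seed = 1
#>   SampEn2D = 3.4658

ucb <- sampen2d(u, method = "ucb", N0 = 128, N1 = 300, seed = 1)
summary(ucb)
#> ...
#>   SampEn2D = 3.46665
#>   per-epoch entropy: mean = 3.49789, sd = 0.256407, undefined = 0
#>   softmax weights: min = 0.000153, max = 0.00448, effective sample size = 280.4 / 300
```

The exact entropy is 3.46738; the two Monte Carlo estimates land within
1.6e-3 and 7.3e-4 of it while looking at only 128 of the 15,876 anchors
per epoch. `plot(ucb)` shows the running estimate by round;
`running_estimates()`, `convergence_curve()` and `stddev_by_round()`
expose the convergence diagnostics programmatically.

From a shell (after install):

```sh
Rscript exec/sampen2d simulate --kind mix -p 0.9 --binarize \
    --height 128 --width 128 --seed 42 --output mix.pgm
Rscript exec/sampen2d mc --input mix.pgm --n0 128 --n1 300 --seed 1
Rscript exec/sampen2d exact --input some_directory_of_images/ --output batch.csv
```

Subcommands `exact`, `mc`, `ucb` emit JSON (CSV in directory batch
mode); `simulate` writes PGM fixtures; `bench` emits tidy convergence
CSVs. Exit codes: 0 success, 2 usage error, 3 undefined entropy.

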