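#' Two-dimensional sample entropy of a grayscale image
#'
#' Front end for the three methods. SampEn2D is
#' \eqn{-\log(\phi^{m+1}(r)/\phi^m(r))}: the negative log conditional
#' probability that two image patches within Chebyshev distance `r` of
#' each other at size `m` x `m` remain within `r` when extended to
#' `(m+1)` x `(m+1)`. Higher values mean a more irregular, less
#' predictable texture.
#'
#' `method = "exact"` enumerates all template pairs (cost quadratic in the
#' number of pixels). `method = "mc"` ([mcsampen2d()]) subsamples `N0`
#' anchors per epoch over `N1` epochs and averages the match counts;
#' `method = "ucb"` ([ucbmcsampen2d()]) replaces the uniform epoch average
#' with softmax weights over per-epoch upper confidence bounds, which
#' damps poorly representative epochs and typically lowers both the error
#' and its spread at the same `N0`, `N1`.
#'
#' @param image numeric matrix of intensities (any finite scale; with the
#'   default `r_mode` the result is invariant to affine intensity
#'   rescaling).
#' @param m template side length, default 2.
#' @param r_value matching tolerance, default 0.3; interpreted per
#'   `r_mode` (see [effective_tolerance()]).
#' @param r_mode `"sd_relative"` (default) or `"absolute"`.
#' @param method `"exact"`, `"mc"`, or `"ucb"`.
#' @param ... further arguments passed to the selected estimator
#'   ([mcsampen2d()] or [ucbmcsampen2d()]): `N0`, `N1`, `seed`,
#'   `replacement`, and for `"ucb"` also `a`, `b`, `c`, `reward_kind`,
#'   `running_mean`.
#' @return an object of class `"sampen2d"` with `print()`, `summary()`,
#'   `coef()` and (for the Monte Carlo methods) `plot()` and
#'   [running_estimates()] methods.
#' @export
#' @examples
#' u <- mix2d(0.9, 64, 64, binarize = TRUE, seed = 7)
#' fit <- sampen2d(u, method = "exact")
#' coef(fit)
#' sampen2d(u, method = "mc", N0 = 64, N1 = 100, seed = 1)
sampen2d <- function(image, m = 2, r_value = 0.3,
                     r_mode = c("sd_relative", "absolute"),
                     method = c("exact", "mc", "ucb"), ...) {
  method <- match.arg(method)
  r_mode <- match.arg(r_mode)
  switch(method,
         exact = sampen2d_exact(image, m = m, r_value = r_value,
                                r_mode = r_mode, ...),
         mc = mcsampen2d(image, m = m, r_value = r_value, r_mode = r_mode,
                         ...),
         ucb = ucbmcsampen2d(image, m = m, r_value = r_value,
                             r_mode = r_mode, ...))
}
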