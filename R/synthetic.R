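#' MIX(p) synthetic images
#'
#' The MIX(p) family interpolates between a deterministic doubly periodic
#' field and pure noise: the base field is
#' `s[i, j] = sin(2*pi*i/period) * sin(2*pi*j/period)` and each pixel is
#' independently replaced, with probability `p`, by a uniform random value
#' on `[-1, 1]`. Irregularity — and hence SampEn2D — grows with `p`.
#' With `binarize = TRUE` the result is thresholded at its median to a
#' 0/1 image (values strictly below the median become 0), the form used
#' for binary-image experiments.
#'
#' @param p replacement probability in `[0, 1]`.
#' @param height,width image dimensions.
#' @param period sinusoid period in pixels, default 12.
#' @param binarize threshold at the median to a binary image? Default
#'   `FALSE`.
#' @param seed optional integer seed; the caller's random number stream is
#'   left untouched. A fixed seed gives a bit-identical image.
#' @return a `height` x `width` numeric matrix.
#' @export
#' @examples
#' u <- mix2d(0.9, 64, 64, binarize = TRUE, seed = 1)
#' mean(u)  # close to 0.5: median split
mix2d <- function(p, height, width, period = 12, binarize = FALSE,
                  seed = NULL) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]", call. = FALSE)
  if (height < 1 || width < 1) stop("invalid dimensions", call. = FALSE)
  if (period <= 0) stop("period must be positive", call. = FALSE)
  base <- outer(seq_len(height), seq_len(width),
                function(i, j) sin(2 * pi * i / period) * sin(2 * pi * j / period))
  u <- .with_seed(seed, {
    replace <- matrix(runif(height * width) < p, height, width)
    noise <- matrix(runif(height * width, -1, 1), height, width)
    ifelse(replace, noise, base)
  })
  if (binarize) u <- (u >= median(u)) + 0
  u
}

#' Deterministic and seeded toy images
#'
#' Small named fixtures used throughout the test suite and examples:
#' `"constant"` (all pixels 0.5), `"checkerboard"` (`(i + j) mod 2`),
#' `"gradient"` (`i + j`, a smooth ramp), and `"random_int"` (iid uniform
#' integers in `0..max_int`, seeded).
#'
#' @param kind one of `"constant"`, `"checkerboard"`, `"gradient"`,
#'   `"random_int"`.
#' @param height,width image dimensions.
#' @param seed seed for `"random_int"` (ignored otherwise).
#' @param max_int largest integer value for `"random_int"`, default 3.
#' @return a `height` x `width` numeric matrix.
#' @export
#' @examples
#' toy_image("checkerboard", 4, 4)
toy_image <- function(kind = c("constant", "checkerboard", "gradient",
                               "random_int"),
                      height, width, seed = NULL, max_int = 3) {
  kind <- match.arg(kind)
  if (height < 1 || width < 1) stop("invalid dimensions", call. = FALSE)
  switch(kind,
         constant = matrix(0.5, height, width),
         checkerboard = outer(seq_len(height), seq_len(width),
                              function(i, j) (i + j) %% 2),
         gradient = outer(seq_len(height), seq_len(width), `+`),
         random_int = .with_seed(seed,
           matrix(sample.int(max_int + 1L, height * width, replace = TRUE) - 1,
                  height, width)))
}
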