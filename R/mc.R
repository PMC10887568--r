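#' Sample template anchors uniformly
#'
#' Draws `N0` anchors uniformly from the restricted anchor rectangle
#' `k` in `1..h-m`, `l` in `1..w-m`, the set of coordinates valid for both
#' an `m` and an `(m+1)` template, so one draw serves both sizes within an
#' epoch. Uses the current R random number stream; seed it (or use the
#' `seed` argument of the estimators) for reproducibility.
#'
#' @param h,w image dimensions.
#' @param m template side length.
#' @param N0 number of anchors to draw (at least 2).
#' @param replacement logical; may an epoch re-draw the same anchor?
#' @return an `N0` x 2 integer matrix with columns `k`, `l`.
#' @export
#' @examples
#' set.seed(1)
#' sample_coordinates(8, 8, 2, 5)
sample_coordinates <- function(h, w, m, N0, replacement = FALSE) {
  m <- .check_m(m)
  if (length(N0) != 1L || !is.finite(N0) || N0 < 2)
    stop("N0 must be an integer >= 2", call. = FALSE)
  N0 <- as.integer(N0)
  nk <- h - m; nl <- w - m
  if (nk < 1L || nl < 1L)
    stop(sprintf("no valid anchors: image %d x %d too small for m = %d", h, w, m),
         call. = FALSE)
  n <- as.numeric(nk) * as.numeric(nl)
  if (!replacement && N0 > n)
    stop(sprintf("N0 = %d exceeds the %d valid anchors; reduce N0 or sample with replacement",
                 N0, as.integer(n)), call. = FALSE)
  idx <- sample.int(n, N0, replace = replacement)
  cbind(k = as.integer((idx - 1) %% nk) + 1L,
        l = as.integer((idx - 1) %/% nk) + 1L)
}

#' Run one Monte Carlo epoch
#'
#' Counts matching template pairs at sizes `m` and `m+1` on the same
#' anchor set and forms the per-epoch entropy
#' `e = -log(B_tilde / A_tilde)` when both counts are positive
#' (`NA` otherwise).
#'
#' @param image numeric matrix.
#' @param coords two-column `(k, l)` anchor matrix, valid for size `m+1`.
#' @param m template side length.
#' @param r_eff absolute matching tolerance.
#' @return a list with `A_tilde`, `B_tilde`, `e` and the `coords` used.
#' @export
run_epoch <- function(image, coords, m, r_eff) {
  m <- .check_m(m)
  .check_image(image)
  coords <- .check_coords(coords, nrow(image), ncol(image), m + 1L)
  c0 <- .coords0(coords)
  ab <- epoch_pair_counts_cpp(image, c0[, 1L], c0[, 2L], m, r_eff)
  e <- if (ab[1L] > 0 && ab[2L] > 0) -log(ab[2L] / ab[1L]) else NA_real_
  list(coords = coords, A_tilde = ab[1L], B_tilde = ab[2L], e = e)
}

# Shared epoch loop for both Monte Carlo estimators: one seeded generator
# drives all epochs in order, so mcsampen2d() and ucbmcsampen2d() produce
# identical epoch records for an identical seed.
.run_epochs <- function(image, m, r_eff, N0, N1, seed, replacement) {
  h <- nrow(image); w <- ncol(image)
  A <- numeric(N1); B <- numeric(N1); e <- numeric(N1)
  .with_seed(seed, {
    for (k in seq_len(N1)) {
      coords <- sample_coordinates(h, w, m, N0, replacement)
      c0 <- .coords0(coords)
      ab <- epoch_pair_counts_cpp(image, c0[, 1L], c0[, 2L], m, r_eff)
      A[k] <- ab[1L]; B[k] <- ab[2L]
      e[k] <- if (ab[1L] > 0 && ab[2L] > 0) -log(ab[2L] / ab[1L]) else NA_real_
    }
  })
  data.frame(epoch = seq_len(N1), A_tilde = A, B_tilde = B, e = e)
}

.check_mc_params <- function(N0, N1) {
  if (length(N0) != 1L || !is.finite(N0) || N0 < 2 || N0 != as.integer(N0))
    stop("N0 must be an integer >= 2", call. = FALSE)
  if (length(N1) != 1L || !is.finite(N1) || N1 < 1 || N1 != as.integer(N1))
    stop("N1 must be an integer >= 1", call. = FALSE)
  c(as.integer(N0), as.integer(N1))
}

#' Monte Carlo estimate of two-dimensional sample entropy (MCSampEn2D)
#'
#' Repeats `N1` epochs; each epoch draws `N0` anchors uniformly and counts
#' matching template pairs at sizes `m` (`A_tilde`) and `m+1` (`B_tilde`)
#' on the same anchors. The estimate is the log of averaged counts,
#' `-log(mean(B_tilde) / mean(A_tilde))` — averaging before the log, not
#' the mean of per-epoch entropies. The cost per epoch is `O(N0^2)`
#' template comparisons, independent of image size.
#'
#' Epochs with zero counts still contribute their zeros to the averages;
#' only an all-zero average is an error.
#'
#' @inheritParams sampen2d_exact
#' @param N0 anchors per epoch (default 128).
#' @param N1 number of epochs (default 300).
#' @param seed optional integer seed for the epoch sampler; recorded in
#'   the result. The caller's random number stream is left untouched.
#' @param replacement sample anchors with replacement within an epoch?
#'   Default `FALSE` (distinct anchors; a fresh independent draw each
#'   epoch).
#' @return an object of classes `"mcsampen2d"`, `"sampen2d"`.
#' @seealso [sampen2d()], [sampen2d_exact()], [ucbmcsampen2d()]
#' @export
#' @examples
#' u <- mix2d(0.5, 64, 64, seed = 1)
#' mcsampen2d(u, m = 2, r_value = 0.3, N0 = 64, N1 = 50, seed = 42)
mcsampen2d <- function(image, m = 2, r_value = 0.3,
                       r_mode = c("sd_relative", "absolute"),
                       N0 = 128, N1 = 300, seed = NULL, replacement = FALSE) {
  m <- .check_m(m)
  r_mode <- match.arg(r_mode)
  .check_image(image, m)
  nn <- .check_mc_params(N0, N1); N0 <- nn[1L]; N1 <- nn[2L]
  r_eff <- effective_tolerance(image, r_value, r_mode)
  ep <- .run_epochs(image, m, r_eff, N0, N1, seed, replacement)
  A_bar <- mean(ep$A_tilde); B_bar <- mean(ep$B_tilde)
  if (A_bar == 0 || B_bar == 0)
    stop("undefined entropy: insufficient matches (increase N0/N1 or r)",
         call. = FALSE)
  new_sampen2d(
    entropy = -log(B_bar / A_bar), method = "mc",
    image_dim = dim(image), m = m, r_value = r_value, r_mode = r_mode,
    r_eff = r_eff, A = A_bar, B = B_bar,
    N0 = N0, N1 = N1, seed = seed, replacement = replacement,
    epochs = ep, n_undefined = sum(is.na(ep$e)))
}
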