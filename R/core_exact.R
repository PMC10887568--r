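#' Effective matching tolerance for an image
#'
#' Converts a tolerance specification into the absolute Chebyshev threshold
#' used for template matching. In `"sd_relative"` mode (the field's
#' convention) the tolerance is `r_value` times the population standard
#' deviation of the image (denominator `N`), which makes SampEn2D invariant
#' to affine rescaling of the intensities; in `"absolute"` mode `r_value`
#' is used as-is. Values between 0.1 and 0.4 SD are the usual working
#' range: smaller tolerances give poor conditional-probability estimates,
#' larger ones wash out image detail.
#'
#' @param image numeric matrix of intensities.
#' @param r_value non-negative tolerance value.
#' @param r_mode `"sd_relative"` (default) or `"absolute"`.
#' @return a single non-negative number, the absolute matching threshold.
#' @export
#' @examples
#' u <- toy_image("checkerboard", 8, 8)
#' effective_tolerance(u, 0.3)            # 0.3 * SD = 0.15
#' effective_tolerance(u, 0.3, "absolute")
effective_tolerance <- function(image, r_value,
                                r_mode = c("sd_relative", "absolute")) {
  r_mode <- match.arg(r_mode)
  .check_image(image)
  if (length(r_value) != 1L || !is.finite(r_value) || r_value < 0)
    stop("r_value must be a single non-negative number", call. = FALSE)
  if (r_mode == "sd_relative") r_value * .pop_sd(image) else r_value
}

#' Extract a square template matrix from an image
#'
#' Returns the `m` x `m` patch anchored at coordinate `(k, l)` (1-based,
#' top-left corner). Anchors are restricted to `k <= h - m`,
#' `l <= w - m`, so that the same coordinate is also valid for the
#' `(m+1)`-template used in the conditional-probability ratio.
#'
#' @param image numeric matrix.
#' @param coord length-2 integer vector `(k, l)`.
#' @param m template side length.
#' @return an `m` x `m` numeric matrix.
#' @export
#' @examples
#' u <- outer(1:4, 1:4, function(i, j) 10 * i + j)
#' extract_template(u, c(1, 1), 2)
extract_template <- function(image, coord, m) {
  m <- .check_m(m)
  .check_image(image)
  if (length(coord) != 2L || !all(is.finite(coord)))
    stop("coord must be a length-2 (k, l) vector", call. = FALSE)
  k <- as.integer(coord[1L]); l <- as.integer(coord[2L])
  h <- nrow(image); w <- ncol(image)
  if (k < 1L || k > h - m)
    stop(sprintf("row anchor k = %d outside the valid range [1, %d]", k, h - m),
         call. = FALSE)
  if (l < 1L || l > w - m)
    stop(sprintf("column anchor l = %d outside the valid range [1, %d]", l, w - m),
         call. = FALSE)
  image[k:(k + m - 1L), l:(l + m - 1L), drop = FALSE]
}

#' Chebyshev distance between two equally shaped matrices
#'
#' The greatest absolute element-wise difference, the matching metric for
#' template comparison.
#'
#' @param X,Y numeric matrices of identical shape.
#' @return a single non-negative number.
#' @export
#' @examples
#' chebyshev_distance(matrix(1:4, 2), matrix(c(1, 2, 3, 6), 2))
chebyshev_distance <- function(X, Y) {
  if (!is.numeric(X) || !is.numeric(Y))
    stop("X and Y must be numeric", call. = FALSE)
  if (!identical(dim(X), dim(Y)) || is.null(dim(X)))
    stop("X and Y must be matrices of identical shape", call. = FALSE)
  max(abs(X - Y))
}

#' Count matching template pairs among a set of anchors
#'
#' Counts the unordered pairs of distinct anchors whose `m` x `m` templates
#' lie within Chebyshev distance `r_eff` of each other. Self-pairs are
#' never counted; duplicated coordinates in `coords` (possible when
#' sampling with replacement) count as distinct list entries, but a pair of
#' identical coordinates is skipped.
#'
#' @param image numeric matrix.
#' @param coords two-column integer matrix of 1-based `(k, l)` anchors;
#'   each anchor's template of size `m` must lie inside the image.
#' @param m template side length.
#' @param r_eff absolute matching tolerance (see [effective_tolerance()]).
#' @return a count (numeric scalar; counts can exceed the integer range).
#' @export
#' @examples
#' u <- toy_image("constant", 4, 4)
#' anchors <- as.matrix(expand.grid(k = 1:2, l = 1:2))
#' count_matching_pairs(u, anchors, 2, 0.1)  # all C(4,2) = 6 pairs match
count_matching_pairs <- function(image, coords, m, r_eff) {
  m <- .check_m(m)
  .check_image(image)
  if (length(r_eff) != 1L || !is.finite(r_eff) || r_eff < 0)
    stop("r_eff must be a single non-negative number", call. = FALSE)
  if (is.null(coords) || NROW(coords) == 0L) return(0)
  coords <- .check_coords(coords, nrow(image), ncol(image), m)
  c0 <- .coords0(coords)
  count_pairs_cpp(image, c0[, 1L], c0[, 2L], m, r_eff)
}

# Identity-hash fast path: when all distinct intensity values are separated
# by more than r_eff, two templates match iff they are element-wise equal,
# so pair counts follow from the sizes of identical-pattern bins. Patterns
# are keyed in base-#levels; exact only while base^(s^2) stays below 2^53.
# Returns NULL when the path does not apply.
.hash_pair_count <- function(u, s, r_eff, margin) {
  vals <- sort(unique(as.vector(u)))
  base <- length(vals)
  if (base > 1L && r_eff >= min(diff(vals))) return(NULL)
  if (s * s * log2(max(base, 2L)) > 52) return(NULL)
  nk <- nrow(u) - margin; nl <- ncol(u) - margin
  if (nk < 1L || nl < 1L) return(NULL)
  code <- matrix(match(u, vals) - 1, nrow(u), ncol(u))
  key <- matrix(0, nk, nl)
  p <- 1
  for (dc in 0:(s - 1L)) {
    for (dr in 0:(s - 1L)) {
      key <- key + code[(1:nk) + dr, (1:nl) + dc, drop = FALSE] * p
      p <- p * base
    }
  }
  cnt <- tabulate(match(key, unique(as.vector(key))))
  sum(cnt * (cnt - 1)) / 2
}

# Matching pairs at size s over the full restricted anchor grid
# k in 1..h-margin, l in 1..w-margin (margin = base m for the shared set).
.pair_count_all <- function(u, s, r_eff, margin) {
  cnt <- .hash_pair_count(u, s, r_eff, margin)
  if (!is.null(cnt)) return(cnt)
  count_pairs_margin_cpp(u, s, r_eff, margin)
}

#' Template match density \eqn{\phi^m(r)}
#'
#' The mean over all anchors `(k, l)` of the fraction of other templates
#' within Chebyshev distance `r_eff` of the template at `(k, l)`
#' (self-matches excluded). Anchors range over `k` in `1..h-m`, `l` in
#' `1..w-m`, so the denominator is `(h-m)(w-m) - 1` per anchor.
#'
#' @inheritParams count_matching_pairs
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' phi_m(toy_image("constant", 8, 8), 2, 0.1)  # 1: every pair matches
phi_m <- function(image, m, r_eff) {
  m <- .check_m(m)
  .check_image(image)
  nk <- nrow(image) - m; nl <- ncol(image) - m
  n <- as.numeric(nk) * as.numeric(nl)
  if (nk < 1L || nl < 1L || n < 2)
    stop("degenerate template set: fewer than 2 templates", call. = FALSE)
  pairs <- .pair_count_all(image, m, r_eff, margin = m)
  2 * pairs / (n * (n - 1))
}

#' Exact two-dimensional sample entropy
#'
#' Direct SampEn2D: \eqn{-\log(\phi^{m+1}(r) / \phi^m(r))}, both match
#' densities computed over the shared restricted anchor set `k` in
#' `1..h-m`, `l` in `1..w-m` so that every `(m+1)`-match is also an
#' `m`-match and the entropy is non-negative. Uses an exact
#' identity-hashing count when the image's distinct intensity levels are
#' separated by more than the tolerance (e.g. binary images), and a
#' compiled pairwise Chebyshev scan otherwise.
#'
#' @param image numeric matrix of intensities.
#' @param m template side length (default 2).
#' @param r_value tolerance (default 0.3).
#' @param r_mode `"sd_relative"` (default) or `"absolute"`.
#' @return an object of class `"sampen2d"`; see [sampen2d()].
#' @seealso [sampen2d()], [mcsampen2d()], [ucbmcsampen2d()]
#' @export
#' @examples
#' sampen2d_exact(mix2d(0.5, 32, 32, seed = 1), m = 2, r_value = 0.3)
sampen2d_exact <- function(image, m = 2, r_value = 0.3,
                           r_mode = c("sd_relative", "absolute")) {
  m <- .check_m(m)
  r_mode <- match.arg(r_mode)
  .check_image(image, m)
  r_eff <- effective_tolerance(image, r_value, r_mode)
  nk <- nrow(image) - m; nl <- ncol(image) - m
  n <- as.numeric(nk) * as.numeric(nl)
  if (n < 2) stop("degenerate template set: fewer than 2 templates", call. = FALSE)
  cnt_hash <- .hash_pair_count(image, m, r_eff, margin = m)
  if (!is.null(cnt_hash)) {
    A <- cnt_hash
    B <- .hash_pair_count(image, m + 1L, r_eff, margin = m)
  } else {
    ab <- exact_pair_counts_cpp(image, m, r_eff)
    A <- ab[1L]; B <- ab[2L]
  }
  if (A == 0 || B == 0)
    stop("undefined entropy: no matches at the given tolerance", call. = FALSE)
  new_sampen2d(
    entropy = -log(B / A), method = "exact",
    image_dim = dim(image), m = m, r_value = r_value, r_mode = r_mode,
    r_eff = r_eff,
    A = A, B = B, n_templates = n,
    phi_m = 2 * A / (n * (n - 1)), phi_m1 = 2 * B / (n * (n - 1)))
}
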