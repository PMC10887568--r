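# Internal validation and indexing helpers.
#
# Coordinates are 1-based in the user-facing API (anchor (k, l) marks the
# top-left pixel of a template) and 0-based in the C++ kernels; the
# conversion lives in .coords0() and nowhere else.

.check_image <- function(u, m = NULL) {
  if (!is.matrix(u) || !is.numeric(u))
    stop("image must be a numeric matrix", call. = FALSE)
  if (length(u) == 0L) stop("image is empty", call. = FALSE)
  if (!all(is.finite(u)))
    stop("image contains non-finite values", call. = FALSE)
  if (!is.null(m)) {
    if (nrow(u) < m + 2L || ncol(u) < m + 2L)
      stop(sprintf("image (%d x %d) too small for embedding m = %d: need at least (m+2) x (m+2)",
                   nrow(u), ncol(u), m), call. = FALSE)
  }
  invisible(u)
}

.check_m <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m))
    stop("m must be a positive integer", call. = FALSE)
  as.integer(m)
}

# Population standard deviation (denominator N), the tolerance convention
# for r expressed in SD units.
.pop_sd <- function(u) sqrt(mean((u - mean(u))^2))

# Shared restricted anchor range for base size m: k in 1..h-m, l in 1..w-m.
# Every anchor in this range admits both an m and an (m+1) template.
.anchor_dims <- function(h, w, m) c(nk = h - m, nl = w - m)

.check_coords <- function(coords, h, w, m) {
  if (is.null(dim(coords)) && length(coords) == 2L)
    coords <- matrix(as.integer(coords), 1L, 2L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be a two-column (k, l) matrix", call. = FALSE)
  storage.mode(coords) <- "integer"
  if (nrow(coords)) {
    bad <- which(coords[, 1L] < 1L | coords[, 2L] < 1L |
                 coords[, 1L] + m - 1L > h | coords[, 2L] + m - 1L > w)
    if (length(bad))
      stop(sprintf("coordinate out of range for template size %d: (%d, %d)",
                   m, coords[bad[1L], 1L], coords[bad[1L], 2L]), call. = FALSE)
  }
  coords
}

.coords0 <- function(coords) coords - 1L

# Run an expression under a private, seeded RNG stream, restoring the
# caller's stream afterwards (the simulate.lm idiom).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
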