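#' Error ratio of an epoch's entropy against the running mean
#'
#' For round `i`, the relative deviation of the epoch entropy from the
#' running mean entropy: `er_i = (em - e_i) / em` where `em` is the mean
#' of the per-epoch entropies. With `running_mean = "inclusive"` (default)
#' `em` averages rounds `1..i`, so `er_1 = 0` by construction; the
#' `"preceding"` variant averages rounds `1..i-1` only (with `er_1 := 0`
#' since there is no history yet). Undefined epoch entropies (`NA`) are
#' excluded from the mean, and an undefined current epoch gets `er = 0`.
#' A zero running mean is a degenerate anchor (e.g. a constant image) and
#' also yields 0.
#'
#' @param entropies numeric vector of per-epoch entropies (may contain
#'   `NA` for undefined epochs); at least `i` entries.
#' @param i round index (1-based).
#' @param running_mean `"inclusive"` (mean over rounds `1..i`, the
#'   pseudocode convention and default) or `"preceding"` (mean over
#'   rounds `1..i-1`, the prose convention).
#' @return a single finite number.
#' @export
#' @examples
#' error_ratio(c(1, 3), 2)  # em = 2, (2 - 3)/2 = -0.5
error_ratio <- function(entropies, i,
                        running_mean = c("inclusive", "preceding")) {
  running_mean <- match.arg(running_mean)
  if (length(i) != 1L || !is.finite(i) || i < 1 || i != as.integer(i))
    stop("i must be a positive integer", call. = FALSE)
  i <- as.integer(i)
  if (length(entropies) < i)
    stop(sprintf("need entropies up to round %d, got %d", i, length(entropies)),
         call. = FALSE)
  e_i <- entropies[i]
  if (is.na(e_i)) return(0)
  hist <- if (running_mean == "inclusive") entropies[seq_len(i)]
          else entropies[seq_len(i - 1L)]
  hist <- hist[!is.na(hist)]
  if (length(hist) == 0L) return(0)
  em <- mean(hist)
  if (em == 0) return(0)
  (em - e_i) / em
}

#' Reward of an epoch from its error ratio
#'
#' Maps an error ratio to a non-negative reward that is maximal (equal to
#' `a`) when the epoch's entropy sits exactly on the running mean and
#' non-increasing in `|er|`. Two kernels: `"cosine"`,
#' `a * cos(min(b * |er|, pi/2))` (argument clamped so large deviations
#' get reward 0, never a negative or rebounding value), and `"normal"`,
#' the unnormalized Gaussian kernel `a * exp(-(b * er)^2 / 2)`.
#'
#' @param er error ratio(s) from [error_ratio()]; only `|er|` matters.
#' @param a reward scale (peak value), default 8.
#' @param b error-ratio scale, default 1.
#' @param kind `"cosine"` (default) or `"normal"`.
#' @return reward value(s) in `[0, a]`.
#' @export
#' @examples
#' ucb_reward(0, a = 8)              # 8
#' ucb_reward(2, a = 8, b = 1)       # 0: clamped at pi/2
ucb_reward <- function(er, a = 8, b = 1, kind = c("cosine", "normal")) {
  kind <- match.arg(kind)
  if (!all(is.finite(er))) stop("er must be finite", call. = FALSE)
  if (a <= 0 || b <= 0) stop("a and b must be positive", call. = FALSE)
  x <- b * abs(er)
  switch(kind,
         cosine = ifelse(x >= pi / 2, 0, a * cos(x)),
         normal = a * exp(-x^2 / 2))
}

#' Upper confidence bound of an epoch
#'
#' `ucb_i = q_hat + c * sqrt(2 * log(i))`: the epoch's average reward plus
#' an exploration bonus. Each epoch is used exactly once, so the pull
#' count is fixed at 1 and the average reward equals the reward.
#'
#' @param q_hat average reward of the epoch.
#' @param i round index (1-based).
#' @param c exploration coefficient (non-negative), default 1.
#' @return the bound (scalar or vector, following `q_hat`/`i`).
#' @export
#' @examples
#' ucb_bound(5, 1)        # 5: log(1) = 0
#' ucb_bound(0, exp(2), 1)  # 2
ucb_bound <- function(q_hat, i, c = 1) {
  if (any(i < 1)) stop("i must be >= 1", call. = FALSE)
  if (any(c < 0)) stop("c must be non-negative", call. = FALSE)
  q_hat + c * sqrt(2 * log(i))
}

#' Softmax weights from upper confidence bounds
#'
#' Shift-stable softmax: `w_i = exp(u_i - max(u)) / sum(exp(u_j - max(u)))`.
#' Weights are strictly positive and sum to 1; adding a constant to all
#' bounds leaves them unchanged.
#'
#' @param ucbs non-empty numeric vector of finite bounds.
#' @return a weight vector of the same length summing to 1.
#' @export
#' @examples
#' softmax_weights(c(0, log(2)))  # 1/3, 2/3
softmax_weights <- function(ucbs) {
  if (length(ucbs) == 0L) stop("ucbs must be non-empty", call. = FALSE)
  if (!all(is.finite(ucbs))) stop("ucbs must be finite", call. = FALSE)
  z <- exp(ucbs - max(ucbs))
  z / sum(z)
}

#' UCB-weighted Monte Carlo sample entropy (UCBMCSampEn2D)
#'
#' Runs the same seeded epoch loop as [mcsampen2d()] (identical epoch
#' records for an identical seed), then replaces the uniform `1/N1` epoch
#' weights with softmax weights over per-epoch upper confidence bounds:
#' each epoch's entropy is compared with the running mean entropy
#' ([error_ratio()]), turned into a reward ([ucb_reward()]) and an
#' exploration bound ([ucb_bound()]), and the final estimate is
#' `-log(sum(S * B_tilde) / sum(S * A_tilde))` with `S` the softmax of all
#' `N1` bounds. Epochs whose entropy is undefined get `er = 0` for the
#' reward, but their raw counts still enter the weighted sums.
#'
#' @inheritParams mcsampen2d
#' @param a reward scale, default 8 (recommended range 7–9).
#' @param b error-ratio scale, default 1 (recommended range 0.4–0.6 for
#'   large images; 1 matches the reference experiment settings).
#' @param c exploration coefficient, default 1.
#' @param reward_kind `"cosine"` (default) or `"normal"`.
#' @param running_mean see [error_ratio()].
#' @return an object of classes `"ucbmcsampen2d"`, `"sampen2d"`; the
#'   `epochs` data frame carries per-epoch `er`, `q_hat`, `ucb` and
#'   `weight` diagnostics.
#' @seealso [sampen2d()], [mcsampen2d()]
#' @export
#' @examples
#' u <- mix2d(0.5, 64, 64, seed = 1)
#' ucbmcsampen2d(u, N0 = 64, N1 = 50, seed = 42)
ucbmcsampen2d <- function(image, m = 2, r_value = 0.3,
                          r_mode = c("sd_relative", "absolute"),
                          N0 = 128, N1 = 300, seed = NULL,
                          replacement = FALSE,
                          a = 8, b = 1, c = 1,
                          reward_kind = c("cosine", "normal"),
                          running_mean = c("inclusive", "preceding")) {
  m <- .check_m(m)
  r_mode <- match.arg(r_mode)
  reward_kind <- match.arg(reward_kind)
  running_mean <- match.arg(running_mean)
  .check_image(image, m)
  nn <- .check_mc_params(N0, N1); N0 <- nn[1L]; N1 <- nn[2L]
  if (a <= 0 || b <= 0) stop("a and b must be positive", call. = FALSE)
  if (c < 0) stop("c must be non-negative", call. = FALSE)
  r_eff <- effective_tolerance(image, r_value, r_mode)
  ep <- .run_epochs(image, m, r_eff, N0, N1, seed, replacement)
  er <- vapply(seq_len(N1), function(k) error_ratio(ep$e, k, running_mean),
               numeric(1L))
  q_hat <- ucb_reward(er, a = a, b = b, kind = reward_kind)
  ucb <- ucb_bound(q_hat, seq_len(N1), c = c)
  wts <- softmax_weights(ucb)
  ep$er <- er; ep$q_hat <- q_hat; ep$ucb <- ucb; ep$weight <- wts
  A_w <- sum(wts * ep$A_tilde); B_w <- sum(wts * ep$B_tilde)
  if (A_w == 0 || B_w == 0)
    stop("undefined entropy: insufficient matches (increase N0/N1 or r)",
         call. = FALSE)
  n_undef <- sum(is.na(ep$e))
  if (n_undef > 0)
    warning(sprintf("%d of %d epochs had no m-matches; their zero counts remain in the weighted sums",
                    n_undef, N1), call. = FALSE)
  new_sampen2d(
    entropy = -log(B_w / A_w), method = "ucb",
    image_dim = dim(image), m = m, r_value = r_value, r_mode = r_mode,
    r_eff = r_eff, A = A_w, B = B_w,
    N0 = N0, N1 = N1, seed = seed, replacement = replacement,
    epochs = ep, n_undefined = n_undef,
    ucb = list(a = a, b = b, c = c, reward_kind = reward_kind,
               running_mean = running_mean))
}
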