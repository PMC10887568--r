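#' Mean absolute error between exact entropies and estimates
#'
#' `MeanError = sum(|d_i - e_i|) / W` over `W` paired images: `d_i` the
#' exact SampEn2D, `e_i` the estimate.
#'
#' @param exact,estimates equal-length numeric vectors of finite values.
#' @return a single non-negative number.
#' @export
#' @examples
#' mean_error(c(1, 2), c(1.5, 1.5))  # 0.5
mean_error <- function(exact, estimates) {
  if (length(exact) != length(estimates))
    stop(sprintf("length mismatch: %d exact vs %d estimates",
                 length(exact), length(estimates)), call. = FALSE)
  if (length(exact) == 0L) stop("empty input", call. = FALSE)
  if (!all(is.finite(exact)) || !all(is.finite(estimates)))
    stop("inputs must be finite", call. = FALSE)
  mean(abs(exact - estimates))
}

# Dispatch an estimator run by tag; extra estimator arguments in `...`.
.fit_method <- function(image, method, m, r_value, r_mode, N0, N1, seed,
                        ...) {
  switch(method,
         mc = mcsampen2d(image, m = m, r_value = r_value, r_mode = r_mode,
                         N0 = N0, N1 = N1, seed = seed, ...),
         ucb = ucbmcsampen2d(image, m = m, r_value = r_value,
                             r_mode = r_mode, N0 = N0, N1 = N1, seed = seed,
                             ...),
         stop("method must be 'mc' or 'ucb'", call. = FALSE))
}

#' Error of a Monte Carlo estimator as a function of the epoch count
#'
#' For each seed, runs the estimator once at `max(N1_grid)` epochs and
#' reads off the running estimate at every grid point (the prefix of a
#' seeded run is exactly the estimate a shorter run would have produced).
#' Errors are taken against the exact SampEn2D of the image, computed
#' once.
#'
#' @param image numeric matrix.
#' @param method `"mc"` or `"ucb"`.
#' @param N1_grid increasing vector of epoch counts to report.
#' @param n_seeds number of independent runs; seeds are
#'   `seed_base + 1:n_seeds`.
#' @param m,r_value,r_mode entropy parameters (defaults 2, 0.3,
#'   sd-relative).
#' @param N0 anchors per epoch, default 128.
#' @param seed_base offset for the run seeds, default 0.
#' @param ... further estimator arguments (e.g. `a`, `b`, `c`,
#'   `reward_kind` for `"ucb"`).
#' @return a tidy data frame, one row per `method` x `N1` x `seed`, with
#'   columns `method`, `N0`, `N1`, `seed`, `estimate`, `exact`,
#'   `abs_error` (`NA` estimate where the prefix had no matches).
#' @export
#' @examples
#' u <- mix2d(0.5, 48, 48, seed = 3)
#' cc <- convergence_curve(u, "mc", c(10, 50), n_seeds = 3, N0 = 32)
#' aggregate(abs_error ~ N1, cc, mean)
convergence_curve <- function(image, method = c("mc", "ucb"),
                              N1_grid = c(10, 100, 1000), n_seeds = 10,
                              m = 2, r_value = 0.3,
                              r_mode = c("sd_relative", "absolute"),
                              N0 = 128, seed_base = 0, ...) {
  method <- match.arg(method)
  r_mode <- match.arg(r_mode)
  N1_grid <- sort(unique(as.integer(N1_grid)))
  exact <- sampen2d_exact(image, m = m, r_value = r_value,
                          r_mode = r_mode)$entropy
  rows <- lapply(seq_len(n_seeds), function(s) {
    fit <- .fit_method(image, method, m, r_value, r_mode, N0,
                       N1 = max(N1_grid), seed = seed_base + s, ...)
    est <- running_estimates(fit, N1_grid)
    data.frame(method = method, N0 = N0, N1 = N1_grid,
               seed = seed_base + s, estimate = est, exact = exact,
               abs_error = abs(est - exact))
  })
  do.call(rbind, rows)
}

#' Per-round error mean and spread across repeated runs
#'
#' Runs the estimator `n_runs` times with distinct seeds and, for each
#' round `k`, reports the mean and standard deviation across runs of the
#' running-estimate error (the estimate from rounds `1..k`, the quantity
#' that converges) and of the single-epoch error `|e_k - exact|`.
#'
#' @inheritParams convergence_curve
#' @param N1 epochs per run, default 300.
#' @param n_runs number of repeated runs, default 30.
#' @return a data frame with one row per round: `round`,
#'   `mean_error`, `sd_error` (running estimate), `mean_epoch_error`,
#'   `sd_epoch_error` (per-epoch entropy), `n_runs`.
#' @export
#' @examples
#' u <- mix2d(0.5, 48, 48, seed = 3)
#' sr <- stddev_by_round(u, "mc", N0 = 32, N1 = 20, n_runs = 3)
#' head(sr)
stddev_by_round <- function(image, method = c("mc", "ucb"), N0 = 128,
                            N1 = 300, n_runs = 30, m = 2, r_value = 0.3,
                            r_mode = c("sd_relative", "absolute"),
                            seed_base = 0, ...) {
  method <- match.arg(method)
  r_mode <- match.arg(r_mode)
  exact <- sampen2d_exact(image, m = m, r_value = r_value,
                          r_mode = r_mode)$entropy
  run_err <- matrix(NA_real_, n_runs, N1)
  epoch_err <- matrix(NA_real_, n_runs, N1)
  for (s in seq_len(n_runs)) {
    fit <- .fit_method(image, method, m, r_value, r_mode, N0, N1,
                       seed = seed_base + s, ...)
    run_err[s, ] <- abs(running_estimates(fit) - exact)
    epoch_err[s, ] <- abs(fit$epochs$e - exact)
  }
  sd0 <- function(v) {            # spread across runs; one run has none
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else sd(v)
  }
  data.frame(
    round = seq_len(N1),
    mean_error = colMeans(run_err, na.rm = TRUE),
    sd_error = apply(run_err, 2L, sd0),
    mean_epoch_error = colMeans(epoch_err, na.rm = TRUE),
    sd_epoch_error = apply(epoch_err, 2L, sd0),
    n_runs = n_runs)
}
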