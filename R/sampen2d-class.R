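# The "sampen2d" result object: one class for all three methods, so the
# evaluation harness and the S3 methods can treat them uniformly.

new_sampen2d <- function(entropy, method, image_dim, m, r_value, r_mode, r_eff,
                         A, B, n_templates = NULL, phi_m = NULL, phi_m1 = NULL,
                         N0 = NULL, N1 = NULL, seed = NULL, replacement = NULL,
                         epochs = NULL, ucb = NULL, n_undefined = NULL,
                         call = sys.call(-1L)) {
  obj <- list(entropy = entropy, method = method,
              image_dim = as.integer(image_dim),
              m = m, r_value = r_value, r_mode = r_mode, r_eff = r_eff,
              A = A, B = B, n_templates = n_templates,
              phi_m = phi_m, phi_m1 = phi_m1,
              N0 = N0, N1 = N1, seed = seed, replacement = replacement,
              epochs = epochs, ucb = ucb, n_undefined = n_undefined,
              call = call)
  cls <- switch(method,
                exact = "sampen2d",
                mc = c("mcsampen2d", "sampen2d"),
                ucb = c("ucbmcsampen2d", "sampen2d"))
  structure(obj[!vapply(obj, is.null, logical(1L))], class = cls)
}

.method_label <- function(x) {
  switch(x$method,
         exact = "exact (direct template enumeration)",
         mc = "Monte Carlo (MCSampEn2D, plain epoch averaging)",
         ucb = "Monte Carlo (UCBMCSampEn2D, UCB-weighted epochs)")
}

#' @export
print.sampen2d <- function(x, digits = 6, ...) {
  cat("Two-dimensional sample entropy\n")
  cat("  method:", .method_label(x), "\n")
  cat(sprintf("  image:  %d x %d    m = %d, r = %g (%s, r_eff = %.6g)\n",
              x$image_dim[1L], x$image_dim[2L], x$m, x$r_value, x$r_mode,
              x$r_eff))
  if (!is.null(x$N1)) {
    cat(sprintf("  epochs: N1 = %d, N0 = %d, replacement = %s%s\n",
                x$N1, x$N0, x$replacement,
                if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
    if (isTRUE(x$n_undefined > 0))
      cat(sprintf("  undefined epochs (no m-matches): %d of %d\n",
                  x$n_undefined, x$N1))
  }
  cat(sprintf("  SampEn2D = %s\n", format(x$entropy, digits = digits)))
  invisible(x)
}

#' @export
coef.sampen2d <- function(object, ...) c(SampEn2D = object$entropy)

#' @export
summary.sampen2d <- function(object, ...) {
  out <- list(fit = object)
  if (!is.null(object$epochs)) {
    e <- object$epochs$e
    out$epoch_entropy <- c(mean = mean(e, na.rm = TRUE),
                           sd = sd(e, na.rm = TRUE),
                           undefined = sum(is.na(e)))
    if (!is.null(object$epochs$weight)) {
      wts <- object$epochs$weight
      out$weights <- c(min = min(wts), max = max(wts),
                       ess = 1 / sum(wts^2), uniform_ess = length(wts))
    }
  } else {
    out$phi <- c(phi_m = object$phi_m, phi_m1 = object$phi_m1,
                 A = object$A, B = object$B)
  }
  class(out) <- "summary.sampen2d"
  out
}

#' @export
print.summary.sampen2d <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$phi)) {
    cat(sprintf("  phi^m = %.6g (A = %s pairs), phi^(m+1) = %.6g (B = %s pairs)\n",
                x$phi[["phi_m"]], format(x$phi[["A"]], big.mark = ","),
                x$phi[["phi_m1"]], format(x$phi[["B"]], big.mark = ",")))
  }
  if (!is.null(x$epoch_entropy)) {
    cat(sprintf("  per-epoch entropy: mean = %.6g, sd = %.6g, undefined = %d\n",
                x$epoch_entropy[["mean"]], x$epoch_entropy[["sd"]],
                as.integer(x$epoch_entropy[["undefined"]])))
  }
  if (!is.null(x$weights)) {
    cat(sprintf("  softmax weights: min = %.3g, max = %.3g, effective sample size = %.1f / %d\n",
                x$weights[["min"]], x$weights[["max"]], x$weights[["ess"]],
                as.integer(x$weights[["uniform_ess"]])))
  }
  invisible(x)
}

#' Running estimates from a Monte Carlo fit
#'
#' The estimate that would have been reported had the run stopped after
#' round `k`, for each requested `k`. For MCSampEn2D this is
#' `-log(cumsum(B)/cumsum(A))`; for UCBMCSampEn2D the softmax weights are
#' recomputed over the first `k` upper confidence bounds (each bound
#' depends only on rounds up to its own, so the prefix is exactly the
#' online computation). Rounds with no matches yet yield `NA`.
#'
#' @param object a fit from [mcsampen2d()] or [ucbmcsampen2d()].
#' @param rounds integer vector of round indices (default all rounds).
#' @return numeric vector of entropies, one per requested round.
#' @export
running_estimates <- function(object, rounds = NULL) {
  if (!inherits(object, "sampen2d") || is.null(object$epochs))
    stop("running_estimates() needs a Monte Carlo sampen2d fit", call. = FALSE)
  ep <- object$epochs
  if (is.null(rounds)) rounds <- seq_len(nrow(ep))
  rounds <- as.integer(rounds)
  if (any(rounds < 1L | rounds > nrow(ep)))
    stop("rounds out of range", call. = FALSE)
  if (inherits(object, "ucbmcsampen2d")) {
    vapply(rounds, function(k) {
      wts <- softmax_weights(ep$ucb[seq_len(k)])
      a <- sum(wts * ep$A_tilde[seq_len(k)])
      b <- sum(wts * ep$B_tilde[seq_len(k)])
      if (a > 0 && b > 0) -log(b / a) else NA_real_
    }, numeric(1L))
  } else {
    ca <- cumsum(ep$A_tilde); cb <- cumsum(ep$B_tilde)
    ifelse(ca[rounds] > 0 & cb[rounds] > 0, -log(cb[rounds] / ca[rounds]),
           NA_real_)
  }
}

#' @export
plot.sampen2d <- function(x, ...) {
  if (is.null(x$epochs)) {
    stop("nothing to plot for an exact fit; plot a Monte Carlo fit", call. = FALSE)
  }
  traj <- running_estimates(x)
  plot(seq_along(traj), traj, type = "l", xlab = "Monte Carlo round k",
       ylab = "running SampEn2D estimate",
       main = .method_label(x), ...)
  abline(h = x$entropy, lty = 2, col = "grey40")
  invisible(x)
}
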