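#' Optimal-segments smoothing of clamp time series
#'
#' Fits a piecewise-cubic curve with continuous value and first derivative
#' (C1) to a noisy analyte time series, choosing the number of segments by a
#' forward extra-sum-of-squares F test. The fitted curve supplies the time
#' derivatives dG/dt and dSA/dt required by Steele's non-steady-state
#' equation; raw finite differences of noisy assay data are never used.
#'
#' Segment boundaries ("knots") are chosen adaptively at sample times by
#' greedy forward insertion: the k+1-segment model adds, to the k-segment
#' model's knots, the interior sample point whose insertion most reduces
#' the residual sum of squares. Successive models are therefore nested, so
#' RSS is non-increasing in the segment count by construction, and knots
#' concentrate where the signal bends (e.g. the insulin-activation
#' transient of a clamp). Within each segment the curve is a cubic
#' polynomial; the segments share value and slope at interior knots. The
#' basis is the truncated-power basis
#' \{1, u, u^2, u^3, (u-k_i)_+^2, (u-k_i)_+^3\} on times rescaled to
#' [0, 1], which spans exactly the C1 piecewise cubics for the knots.
#'
#' The segment count is the smallest k such that no finer admissible model
#' improves on it significantly (extra-sum-of-squares F test at level
#' `alpha`, applied to k against every refinement, not only k+1: a locally
#' flat step must not hide a strongly better finer model).
#'
#' @param t sample times (min), strictly increasing, length >= 6.
#' @param y analyte values at `t` (same length).
#' @param sigma known assay SD (same units as `y`), or `"estimate"` to use
#'   the residual SD of the most flexible admissible fit.
#' @param max_segments largest number of segments considered (default 6,
#'   conservative for ~30-point clamp series).
#' @param alpha level of the forward F test (default 0.05).
#' @param n_segments optionally force the number of segments, skipping
#'   selection (used e.g. to compare fits on a common knot set).
#' @return an object of class `smooth_curve` with elements `knots`
#'   (segment boundaries, min), `coefficients` (n_segments x 4 matrix of
#'   per-segment cubic coefficients in powers of `t - left knot`),
#'   `n_segments`, `rss`, `sigma_hat`, `fitted`, and the data range.
#' @seealso [eval_smooth()] to query value and first derivative.
#' @export
fit_optimal_segments <- function(t, y, sigma = "estimate", max_segments = 6L,
                                 alpha = 0.05, n_segments = NULL) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 6L) stop("insufficient data: need at least 6 samples")
  if (any(diff(t) <= 0)) stop("unsorted input: t must be strictly increasing")
  if (is.character(sigma)) {
    if (!identical(sigma, "estimate")) stop("sigma must be positive or \"estimate\"")
  } else if (!is.numeric(sigma) || sigma < 0) {
    stop("sigma must be positive or \"estimate\"")
  }
  n <- length(t)
  max_segments <- max(1L, as.integer(max_segments))
  kmax <- .admissible_kmax(n, max_segments)

  fits <- .forward_knot_fits(t, y, kmax)
  kmax <- length(fits)                     # insertion may exhaust candidates
  if (!is.null(n_segments)) {
    k <- as.integer(n_segments)
    if (k < 1L || k > kmax) stop("n_segments outside admissible range")
  } else {
    # smallest k that no finer admissible fit improves significantly
    k <- kmax
    for (kc in seq_len(kmax - 1L)) {
      improves <- vapply((kc + 1L):kmax, function(k1)
        .ftest_improves(fits[[kc]], fits[[k1]], n, alpha), logical(1))
      if (!any(improves)) { k <- kc; break }
    }
  }
  sel <- fits[[k]]
  full <- fits[[kmax]]

  if (is.numeric(sigma)) {
    sigma_hat <- sigma
  } else {
    dfree <- n - full$df
    sigma_hat <- if (dfree > 0) sqrt(max(full$rss, 0) / dfree) else NA_real_
  }

  structure(list(
    knots = sel$knots,
    coefficients = sel$coefficients,
    n_segments = sel$k,
    rss = sel$rss,
    sigma_hat = sigma_hat,
    fitted = sel$fitted,
    range = range(t)
  ), class = "smooth_curve")
}

# Largest segment count with >= 2 residual df (2 extra parameters per knot).
.admissible_kmax <- function(n, max_segments) {
  kmax <- 1L
  for (k in seq_len(max_segments)) {
    dfk <- 4L + 2L * (k - 1L)
    if (n - dfk >= 2L) kmax <- k
  }
  kmax
}

# Nested fit sequence by greedy forward knot insertion at interior sample
# points. fits[[k]] has k segments; fits[[k+1]] adds the single candidate
# knot that minimizes RSS, so RSS is non-increasing in k by construction.
.forward_knot_fits <- function(t, y, kmax) {
  n <- length(t)
  fits <- vector("list", kmax)
  knot_idx <- integer(0)                 # interior knots, as data indices
  fits[[1L]] <- .fit_with_knots(t, y, knot_idx)
  if (kmax == 1L) return(fits)
  for (k in 2L:kmax) {
    cand <- setdiff(2:(n - 1L), knot_idx)
    if (!length(cand)) return(fits[seq_len(k - 1L)])
    best <- NULL
    for (ci in cand) {
      f <- .fit_with_knots(t, y, sort(c(knot_idx, ci)))
      if (is.null(best) || f$rss < best$rss) { best <- f; best_ci <- ci }
    }
    knot_idx <- sort(c(knot_idx, best_ci))
    fits[[k]] <- best
  }
  fits
}

# Forward extra-sum-of-squares F test: does k+1 segments beat k?
.ftest_improves <- function(fit_k, fit_k1, n, alpha) {
  drop_ss <- fit_k$rss - fit_k1$rss
  scale <- max(fit_k$rss, fit_k1$rss, sum(fit_k$fitted^2), .Machine$double.eps)
  if (drop_ss <= 1e-12 * scale) return(FALSE)   # no material improvement
  df2 <- n - fit_k1$df
  if (df2 < 1L) return(FALSE)
  if (fit_k1$rss <= 1e-12 * scale) return(TRUE) # near-perfect refinement
  fstat <- (drop_ss / (fit_k1$df - fit_k$df)) / (fit_k1$rss / df2)
  stats::pf(fstat, fit_k1$df - fit_k$df, df2, lower.tail = FALSE) < alpha
}

# Least-squares C1 piecewise cubic with interior knots at the given data
# indices.
.fit_with_knots <- function(t, y, knot_idx) {
  n <- length(t)
  t0 <- t[1L]; span <- t[n] - t[1L]
  u <- (t - t0) / span
  idx <- c(1L, knot_idx, n)
  knots_u <- u[idx]
  k <- length(idx) - 1L
  X <- .c1_basis(u, knots_u)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  coefs <- .segment_coefs(beta, knots_u, span)
  list(k = k, knots = t[idx], coefficients = coefs, rss = rss,
       fitted = fitted, df = ncol(X))
}

# Truncated-power C1 cubic basis on [0, 1] with interior knots.
.c1_basis <- function(u, knots_u) {
  inner <- knots_u[-c(1L, length(knots_u))]
  cols <- list(rep(1, length(u)), u, u^2, u^3)
  for (ki in inner) {
    d <- pmax(u - ki, 0)
    cols <- c(cols, list(d^2, d^3))
  }
  do.call(cbind, cols)
}

# Per-segment cubic coefficients in powers of (t - left knot), original units.
# Obtained from the exact value and derivatives of the basis expansion at the
# left knot of each segment (Taylor coefficients of a cubic are exact).
.segment_coefs <- function(beta, knots_u, span) {
  k <- length(knots_u) - 1L
  inner <- knots_u[-c(1L, length(knots_u))]
  out <- matrix(0, nrow = k, ncol = 4L,
                dimnames = list(NULL, c("a0", "a1", "a2", "a3")))
  for (j in seq_len(k)) {
    ku <- knots_u[j]
    # value and u-derivatives of the global cubic part
    d0 <- beta[1L] + beta[2L] * ku + beta[3L] * ku^2 + beta[4L] * ku^3
    d1 <- beta[2L] + 2 * beta[3L] * ku + 3 * beta[4L] * ku^2
    d2 <- 2 * beta[3L] + 6 * beta[4L] * ku
    d3 <- 6 * beta[4L]
    if (length(inner)) {
      for (m in seq_along(inner)) {
        ki <- inner[m]
        if (ki <= ku + 1e-15) {   # knot active on this segment
          z <- ku - ki
          b2 <- beta[3L + 2L * m]; b3 <- beta[4L + 2L * m]
          d0 <- d0 + b2 * z^2 + b3 * z^3
          d1 <- d1 + 2 * b2 * z + 3 * b3 * z^2
          d2 <- d2 + 2 * b2 + 6 * b3 * z
          d3 <- d3 + 6 * b3
        }
      }
    }
    # chain rule u -> t (u = (t - t0)/span), Taylor coefficients in (t - knot)
    out[j, ] <- c(d0, d1 / span, d2 / 2 / span^2, d3 / 6 / span^3)
  }
  out
}

#' Evaluate a fitted smooth curve and its first derivative
#'
#' Evaluates the piecewise-cubic fit analytically. Queries outside the
#' fitted time range are refused (the smoother is not an extrapolator).
#' At interior knots value and slope are continuous by construction, so the
#' shared value is returned.
#'
#' @param curve a `smooth_curve` from [fit_optimal_segments()].
#' @param t_query times (min) within the fitted range.
#' @return list with numeric vectors `value` and `derivative` (units of y,
#'   and y per min).
#' @export
eval_smooth <- function(curve, t_query) {
  stopifnot(inherits(curve, "smooth_curve"))
  t_query <- as.numeric(t_query)
  lo <- curve$range[1L]; hi <- curve$range[2L]
  tol <- 1e-9 * max(hi - lo, 1)
  if (any(t_query < lo - tol | t_query > hi + tol)) {
    stop("extrapolation refused: query outside fitted range [",
         format(lo), ", ", format(hi), "]")
  }
  t_query <- pmin(pmax(t_query, lo), hi)
  kn <- curve$knots
  seg <- findInterval(t_query, kn, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), curve$n_segments)
  a <- curve$coefficients
  dt <- t_query - kn[seg]
  value <- a[seg, 1L] + a[seg, 2L] * dt + a[seg, 3L] * dt^2 + a[seg, 4L] * dt^3
  deriv <- a[seg, 2L] + 2 * a[seg, 3L] * dt + 3 * a[seg, 4L] * dt^2
  list(value = as.numeric(value), derivative = as.numeric(deriv))
}

#' @export
predict.smooth_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$knots
  ev <- eval_smooth(object, newdata)
  data.frame(t = as.numeric(newdata), value = ev$value, derivative = ev$derivative)
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("Optimal-segments smooth:", x$n_segments, "cubic segment(s) on [",
      format(x$range[1L]), ",", format(x$range[2L]), "] min\n")
  cat("  RSS:", format(x$rss), "  sigma_hat:", format(x$sigma_hat), "\n")
  invisible(x)
}
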