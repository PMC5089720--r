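# Shared fixtures and independent reference implementations used as oracles.

# A perfectly steady clamp record: constant glucose, tracer and insulin.
make_steady_record <- function(n = 13, G = 100, SA = 4000, I = 8,
                               GINF = 0, Fstar = 20000, SA_inf = 0,
                               insulin_start = 60) {
  tm <- seq(0, by = 10, length.out = n)
  clamp_record(time = tm, G = rep(G, n), Gstar = rep(SA * G / 100, n),
               I = rep(I, n), GINF = GINF, Fstar = Fstar, SA_inf = SA_inf,
               weight = 28, insulin_rate = 1, insulin_start = insulin_start)
}

# Independent C1 piecewise-cubic least squares via lm() on a truncated-power
# basis, used to cross-check the package fitter. Knots given as data indices.
ref_c1_fit <- function(t, y, knot_idx) {
  u <- (t - t[1]) / (t[length(t)] - t[1])
  X <- cbind(u, u^2, u^3)
  for (ki in knot_idx) {
    d <- pmax(u - u[ki], 0)
    X <- cbind(X, d^2, d^3)
  }
  fit <- stats::lm(y ~ X)
  sum(stats::resid(fit)^2)
}

# Exhaustive minimum RSS over every placement of (k-1) interior knots at
# data indices, for a k-segment C1 cubic fit.
ref_best_rss <- function(t, y, k) {
  n <- length(t)
  if (k == 1) return(ref_c1_fit(t, y, integer(0)))
  combs <- utils::combn(2:(n - 1), k - 1)
  min(apply(combs, 2, function(ix) ref_c1_fit(t, y, sort(ix))))
}

# One noise-free simulated clamp (lean-conscious defaults), shared across
# test files; simulation is deterministic without noise.
noise_free_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_clamp(sim_config(cv_G = 0, cv_I = 0,
                                          tracer_sd_scale = 0))
    }
    cache
  }
})

# Matched analysis constants for single-pool simulations (no model mismatch).
matched_constants <- function(sim) kinetic_constants(p = 1, V = sim$config$V)

# Smoother settings for time-resolved flux recovery on noise-free records:
# infusion compensation (exact accounting of the pump steps) plus a larger
# segment budget (no noise to overfit). Window-based summaries (basal /
# steady state) use the package defaults, which are grid-stable.
noise_free_smooth <- list(max_segments = 12, compensate_infusion = TRUE)
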