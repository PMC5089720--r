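#' Disintegrations per minute per microcurie
#'
#' Conversion constant used at every I/O boundary where tracer amounts are
#' given in microcuries: 1 uCi = 2.22e6 dpm.
#' @export
DPM_PER_UCI <- 2.22e6

#' Construct a clamp record
#'
#' One animal's sampled hyperinsulinemic-euglycemic clamp time series plus
#' the protocol metadata needed to analyze it. Internal units are fixed:
#' min, mg/dl (glucose), dpm/ml (plasma tracer), uU/ml (insulin),
#' mg/kg/min (glucose infusion), dpm/kg/min (tracer infusion),
#' dpm/mg (infusate specific activity).
#'
#' @param time sample times, min, strictly increasing.
#' @param G plasma glucose, mg/dl, all positive.
#' @param Gstar plasma [3-3H]glucose activity, dpm/ml, non-negative.
#' @param I plasma insulin, uU/ml.
#' @param GINF exogenous glucose infusion rate, mg/kg/min (scalar recycled).
#' @param Fstar tracer pump infusion rate, dpm/kg/min (scalar recycled).
#' @param SA_inf specific activity of the labeled glucose infusate, dpm/mg.
#'   Must be given explicitly (0 for an unlabeled "cold" infusate) whenever
#'   GINF is nonzero.
#' @param weight body weight, kg.
#' @param insulin_rate insulin infusion rate during the clamp, mU/kg/min.
#' @param insulin_start time insulin infusion begins, min (within the record).
#' @param diet group label, "lean" or "fat_fed".
#' @param state group label, "conscious" or "anesthetized".
#' @param id animal identifier.
#' @return an object of class `clamp_record` (a list; time series entries
#'   have equal length).
#' @export
clamp_record <- function(time, G, Gstar, I, GINF, Fstar, SA_inf = NULL,
                         weight, insulin_rate, insulin_start,
                         diet = c("lean", "fat_fed"),
                         state = c("conscious", "anesthetized"),
                         id = "animal") {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2L) stop("clamp record needs at least 2 samples")
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop("unsorted input: time not strictly increasing at row ", bad)
  }
  G <- as.numeric(G); Gstar <- as.numeric(Gstar); I <- as.numeric(I)
  GINF <- rep_len(as.numeric(GINF), n)
  Fstar <- rep_len(as.numeric(Fstar), n)
  if (length(G) != n || length(Gstar) != n || length(I) != n)
    stop("time series columns must have equal length")
  if (any(!is.finite(G)) || any(G <= 0)) {
    stop("negative or non-finite glucose at rows: ",
         paste(which(!is.finite(G) | G <= 0), collapse = ", "))
  }
  if (any(Gstar < 0)) stop("tracer activity must be non-negative")
  if (any(GINF < 0)) stop("GINF must be non-negative")
  if (any(GINF > 0) && is.null(SA_inf)) {
    stop("unlabeled infusate requires SA_inf = 0 explicitly")
  }
  if (is.null(SA_inf)) SA_inf <- 0
  if (weight <= 0) stop("weight must be positive")
  if (insulin_start < time[1L] || insulin_start > time[n]) {
    stop("insulin_start must lie within the sampled time range")
  }
  structure(list(
    time = time, G = G, Gstar = Gstar, I = I, GINF = GINF, Fstar = Fstar,
    SA_inf = as.numeric(SA_inf), weight = as.numeric(weight),
    insulin_rate = as.numeric(insulin_rate),
    insulin_start = as.numeric(insulin_start),
    diet = match.arg(diet), state = match.arg(state), id = as.character(id)
  ), class = "clamp_record")
}

#' @export
print.clamp_record <- function(x, ...) {
  cat("Clamp record", x$id, "(", x$diet, ",", x$state, "):",
      length(x$time), "samples over", format(diff(range(x$time))), "min;",
      "insulin", format(x$insulin_rate), "mU/kg/min from t =",
      format(x$insulin_start), "min\n")
  invisible(x)
}

#' Steele kinetic constants
#'
#' Pool fraction p and glucose distribution volume V for the single-pool
#' non-steady-state treatment. The conventional values p = 0.65 and
#' V = 2.2 dl/kg are the defaults; analyses against matched single-pool
#' simulations use p = 1 with the simulator's V so that no model mismatch
#' enters.
#'
#' @param p pool fraction, dimensionless, in (0, 1].
#' @param V glucose distribution volume, dl/kg, positive.
#' @export
kinetic_constants <- function(p = 0.65, V = 2.2) {
  if (!(p > 0 && p <= 1)) stop("pool fraction p must be in (0, 1]")
  if (V <= 0) stop("distribution volume V must be positive")
  list(p = p, V = V)
}

#' Compute glucose fluxes with Steele's equation (labeled infusion form)
#'
#' Smooths plasma glucose G(t) and tracer specific activity
#' SA(t) = 100 * Gstar(t) / G(t) (dpm/ml to dpm/dl via the factor 100,
#' divided by mg/dl gives dpm/mg), then applies the single-pool
#' non-steady-state equations at the sample times:
#' \deqn{F^*_{tot}(t) = F^*(t) + GINF(t) \cdot SA_{inf}}
#' \deqn{Ra_{tot}(t) = [F^*_{tot}(t) - p V G(t) \, dSA/dt] / SA(t)}
#' \deqn{EGP(t) = Ra_{tot}(t) - GINF(t)}
#' \deqn{Rd(t) = Ra_{tot}(t) - p V \, dG/dt}
#' The label delivered by the labeled ("hot") exogenous glucose infusate is
#' accounted for in \eqn{F^*_{tot}}; with an unlabeled infusate pass
#' SA_inf = 0. Negative EGP values are reported as computed and flagged —
#' clipping would bias the hepatic insulin effect.
#'
#' By default G(t) and SA(t) are smoothed directly. For low-noise, densely
#' informative records, `smooth_control$compensate_infusion = TRUE` enables
#' infusion compensation: because the exogenous infusion is a recorded pump
#' schedule (a step function held constant from each sample to the next),
#' its direct contribution to the glucose and tracer pools is subtracted
#' before smoothing and restored analytically afterwards. The smoother
#' then sees the kink-free endogenous trajectories G - cum(GINF)/V and
#' C* - SA_inf * cum(GINF)/V, and the right-sided derivatives
#' dG/dt = dH/dt + GINF/V (and the tracer analogue) pair consistently with
#' the infusion rate in force at each sample; SA and dSA/dt follow by the
#' quotient rule. This removes the derivative ambiguity at infusion-step
#' times (visible when assay noise is negligible), at the cost of widening
#' the dynamic range the smoother must track, which inflates variance on
#' noisy data - hence direct smoothing is the default.
#'
#' @param record a [clamp_record()].
#' @param constants a [kinetic_constants()] list.
#' @param smooth_control list of arguments for [fit_optimal_segments()]
#'   (e.g. `max_segments`, `alpha`, `sigma_G`, `sigma_SA`,
#'   `compensate_infusion`).
#' @param at evaluation times (min); default the record's sample times.
#' @return a `data.frame` of class `flux_series` with columns `time`, `SA`
#'   (dpm/mg), `Ra_total`, `EGP`, `Rd` (mg/kg/min), `dGdt`, `dSAdt` and
#'   logical `flag_neg_egp`.
#' @export
compute_fluxes <- function(record, constants = kinetic_constants(),
                           smooth_control = list(), at = record$time) {
  stopifnot(inherits(record, "clamp_record"))
  if (all(record$Gstar <= 0)) stop("Gstar identically zero: no tracer signal")
  sc <- function(nm, default) if (!is.null(smooth_control[[nm]])) smooth_control[[nm]] else default
  max_seg <- sc("max_segments", 6L)
  alpha <- sc("alpha", 0.05)
  compensate <- isTRUE(sc("compensate_infusion", FALSE))

  GINF <- .series_at(record$time, record$GINF, at)
  Fstar <- .series_at(record$time, record$Fstar, at)
  V <- constants$V

  if (compensate) {
    # cumulative exogenous glucose delivered up to each sample (mg/kg),
    # treating recorded GINF as a step function held until the next sample
    dt <- diff(record$time)
    cum_ginf <- c(0, cumsum(record$GINF[-length(record$GINF)] * dt))
    Cs_obs <- 100 * record$Gstar                     # dpm/dl
    fit_H <- fit_optimal_segments(record$time, record$G - cum_ginf / V,
                                  sigma = sc("sigma_G", "estimate"),
                                  max_segments = max_seg, alpha = alpha)
    fit_C <- fit_optimal_segments(record$time,
                                  Cs_obs - record$SA_inf * cum_ginf / V,
                                  sigma = sc("sigma_SA", "estimate"),
                                  max_segments = max_seg, alpha = alpha)
    cum_at <- stats::approx(record$time, cum_ginf, xout = at)$y
    eh <- eval_smooth(fit_H, at)
    ec <- eval_smooth(fit_C, at)
    G_s <- eh$value + cum_at / V
    dG <- eh$derivative + GINF / V
    Cs_s <- ec$value + record$SA_inf * cum_at / V
    dCs <- ec$derivative + record$SA_inf * GINF / V
    if (any(G_s <= 0)) stop("smoothed glucose nonpositive at evaluation point")
    SA_s <- Cs_s / G_s
    dSA <- (dCs * G_s - Cs_s * dG) / G_s^2
    eg <- list(value = G_s, derivative = dG)
    es <- list(value = SA_s, derivative = dSA)
    fits <- list(G = fit_H, SA = fit_C, compensated = TRUE)
  } else {
    SA_obs <- 100 * record$Gstar / record$G
    fit_G <- fit_optimal_segments(record$time, record$G,
                                  sigma = sc("sigma_G", "estimate"),
                                  max_segments = max_seg, alpha = alpha)
    fit_SA <- fit_optimal_segments(record$time, SA_obs,
                                   sigma = sc("sigma_SA", "estimate"),
                                   max_segments = max_seg, alpha = alpha)
    eg <- eval_smooth(fit_G, at)
    es <- eval_smooth(fit_SA, at)
    fits <- list(G = fit_G, SA = fit_SA, compensated = FALSE)
  }
  if (any(es$value <= 0)) stop("specific activity nonpositive at evaluation point")
  F_total <- Fstar + GINF * record$SA_inf
  pV <- constants$p * constants$V
  Ra <- (F_total - pV * eg$value * es$derivative) / es$value
  EGP <- Ra - GINF
  Rd <- Ra - pV * eg$derivative
  if (any(EGP < 0)) {
    warning("negative EGP at ", sum(EGP < 0),
            " sample(s); reported as computed and flagged")
  }
  out <- data.frame(time = at, SA = es$value, Ra_total = Ra, EGP = EGP,
                    Rd = Rd, dGdt = eg$derivative, dSAdt = es$derivative,
                    flag_neg_egp = EGP < 0)
  attr(out, "fits") <- fits
  class(out) <- c("flux_series", "data.frame")
  out
}

# Infusion-rate series at evaluation times: pump settings are step functions
# held constant until the next sample, so use last-observation-carried-forward.
.series_at <- function(time, v, at) {
  if (identical(time, at)) return(v)
  idx <- findInterval(at, time, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  v[idx]
}

#' Basal-period flux and concentration averages
#'
#' Time-averages Rd, EGP and the measured glucose and insulin over the last
#' `window` minutes before insulin infusion starts, using the half-open
#' convention (insulin_start - window, insulin_start]: a sample at exactly
#' insulin_start is still basal (infused insulin has not acted).
#'
#' @param series a flux series from [compute_fluxes()].
#' @param record the corresponding [clamp_record()].
#' @param window basal averaging window, min (default 30).
#' @return list with `Rd_basal`, `EGP_basal` (mg/kg/min), `G_basal` (mg/dl),
#'   `I_basal` (uU/ml), and the `window` endpoints.
#' @export
basal_flux <- function(series, record, window = 30) {
  stopifnot(inherits(record, "clamp_record"))
  t0 <- record$insulin_start - window
  if (t0 < record$time[1L]) stop("basal window overlaps clamp: window extends before the record")
  sel <- series$time > t0 & series$time <= record$insulin_start
  if (!any(sel)) stop("basal window underpopulated")
  mrec <- record$time > t0 & record$time <= record$insulin_start
  list(Rd_basal = mean(series$Rd[sel]),
       EGP_basal = mean(series$EGP[sel]),
       G_basal = mean(record$G[mrec]),
       I_basal = mean(record$I[mrec]),
       window = c(t0, record$insulin_start))
}
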