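#' Steady-state summary of a clamp
#'
#' Steady state is the final 30 minutes of the clamp record. Glucose and
#' insulin (measured) and Rd and EGP (tracer-derived) are time-averaged over
#' that window, half-open on the left: samples with
#' t in (t_end - window, t_end].
#'
#' @param series flux series from [compute_fluxes()].
#' @param record the corresponding [clamp_record()].
#' @param window steady-state window, min (default 30).
#' @return list with `Gluc_SS` (mg/dl), `Ins_SS` (uU/ml), `Rd_SS`, `EGP_SS`
#'   (mg/kg/min) and the `window` endpoints.
#' @export
steady_state_summary <- function(series, record, window = 30) {
  stopifnot(inherits(record, "clamp_record"))
  t_end <- record$time[length(record$time)]
  if (t_end - record$insulin_start < window) {
    stop("record must extend at least ", window, " min beyond insulin start")
  }
  t0 <- t_end - window
  sel <- series$time > t0 & series$time <= t_end
  if (sum(sel) < 2L) stop("steady-state window underpopulated")
  mrec <- record$time > t0 & record$time <= t_end
  list(Gluc_SS = mean(record$G[mrec]),
       Ins_SS = mean(record$I[mrec]),
       Rd_SS = mean(series$Rd[sel]),
       EGP_SS = mean(series$EGP[sel]),
       window = c(t0, t_end))
}

#' Insulin sensitivity indices and insulin clearance
#'
#' Peripheral insulin sensitivity is the insulin-stimulated increment in
#' glucose disposal normalized by the insulin increment and the steady-state
#' glucose concentration, SI_P = dRd / (dIns * Gluc_SS); hepatic insulin
#' sensitivity is the analogous ratio for the suppression of endogenous
#' glucose production, SI_H = dEGP / (dIns * Gluc_SS). dEGP is defined
#' suppression-positive (basal minus clamp), so a healthy liver has
#' SI_H > 0 and an insulin-paradoxical rise in EGP yields SI_H < 0. Both
#' indices are reported times 1e4, in dl/kg/min per uU/ml x 10^4. The
#' insulin metabolic clearance rate proxy is the insulin infusion rate
#' divided by the steady-state insulin level, stored as the raw ratio
#' (mU/kg/min)/(uU/ml).
#'
#' @param ss steady-state summary from [steady_state_summary()].
#' @param basal basal tuple from [basal_flux()].
#' @param insulin_rate insulin infusion rate, mU/kg/min.
#' @return list of class `sensitivity_result`: `dRd`, `dEGP` (mg/kg/min),
#'   `dIns` (uU/ml), `SI_P`, `SI_H` (dl/kg/min per uU/ml x 1e4), `MCR`,
#'   plus the basal and steady-state components.
#' @export
compute_sensitivity <- function(ss, basal, insulin_rate) {
  dIns <- ss$Ins_SS - basal$I_basal
  if (!is.finite(dIns) || dIns <= 0) stop("no insulin elevation; SI undefined")
  dRd <- ss$Rd_SS - basal$Rd_basal
  dEGP <- basal$EGP_basal - ss$EGP_SS
  structure(list(
    dRd = dRd, dEGP = dEGP, dIns = dIns,
    SI_P = 1e4 * dRd / (dIns * ss$Gluc_SS),
    SI_H = 1e4 * dEGP / (dIns * ss$Gluc_SS),
    MCR = insulin_rate / ss$Ins_SS,
    Gluc_SS = ss$Gluc_SS, Ins_SS = ss$Ins_SS,
    Rd_SS = ss$Rd_SS, EGP_SS = ss$EGP_SS,
    Rd_basal = basal$Rd_basal, EGP_basal = basal$EGP_basal,
    G_basal = basal$G_basal, I_basal = basal$I_basal,
    insulin_rate = insulin_rate
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("SI_P = %.3f, SI_H = %.3f (dl/kg/min per uU/ml x 1e4), MCR = %.4f\n",
              x$SI_P, x$SI_H, x$MCR))
  cat(sprintf("  dRd = %.3f, dEGP = %.3f mg/kg/min, dIns = %.1f uU/ml, Gluc_SS = %.1f mg/dl\n",
              x$dRd, x$dEGP, x$dIns, x$Gluc_SS))
  invisible(x)
}

#' Percent reduction of a sensitivity index between conditions
#'
#' 100 * (reference - test) / reference. A reduction greater than 100%
#' means the test-condition index changed sign (e.g. insulin-paradoxical
#' stimulation of glucose production under anesthesia).
#'
#' @param si_reference mean index in the reference condition (nonzero).
#' @param si_test mean index in the test condition.
#' @return percent reduction (may exceed 100 or be negative).
#' @export
percent_reduction <- function(si_reference, si_test) {
  if (si_reference == 0) stop("undefined reduction: reference index is zero")
  100 * (si_reference - si_test) / si_reference
}

#' Per-animal sensitivity analysis of one clamp record
#'
#' Convenience wrapper running the full per-animal pipeline: smooth, apply
#' Steele's equation, average the basal and steady-state windows, and form
#' the sensitivity indices.
#'
#' @param record a [clamp_record()].
#' @param constants [kinetic_constants()].
#' @param basal_window,ss_window averaging windows, min.
#' @param smooth_control passed to [compute_fluxes()].
#' @return one-row `data.frame` with group labels, basal and steady-state
#'   values, dRd, dEGP, dIns, SI_P, SI_H, MCR.
#' @export
analyze_record <- function(record, constants = kinetic_constants(),
                           basal_window = 30, ss_window = 30,
                           smooth_control = list()) {
  series <- compute_fluxes(record, constants, smooth_control)
  basal <- basal_flux(series, record, basal_window)
  ss <- steady_state_summary(series, record, ss_window)
  sens <- compute_sensitivity(ss, basal, record$insulin_rate)
  data.frame(id = record$id, diet = record$diet, state = record$state,
             weight = record$weight, insulin_rate = record$insulin_rate,
             G_basal = sens$G_basal, I_basal = sens$I_basal,
             Rd_basal = sens$Rd_basal, EGP_basal = sens$EGP_basal,
             Gluc_SS = sens$Gluc_SS, Ins_SS = sens$Ins_SS,
             Rd_SS = sens$Rd_SS, EGP_SS = sens$EGP_SS,
             dRd = sens$dRd, dEGP = sens$dEGP, dIns = sens$dIns,
             SI_P = sens$SI_P, SI_H = sens$SI_H, MCR = sens$MCR,
             stringsAsFactors = FALSE)
}
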