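#' Configuration of a virtual hyperinsulinemic-euglycemic clamp
#'
#' Full parameterization of the simulated protocol: primed-continuous
#' [3-3H]glucose tracer, somatostatin-suppressed endogenous insulin,
#' constant exogenous insulin infusion after a tracer-equilibration basal
#' period, and labeled ("hot") exogenous glucose infused at variable rates
#' by a feedback controller to hold plasma glucose at its basal level.
#'
#' Physiology (single glucose pool, remote insulin action):
#' \itemize{
#'   \item `G_b` basal glucose, mg/dl; `EGP_b` basal endogenous glucose
#'     production, mg/kg/min; `I_b` basal insulin, uU/ml (0 under
#'     somatostatin); `V` glucose distribution volume, dl/kg.
#'   \item `s_P` peripheral insulin action per uU/ml (fractional increase of
#'     glucose clearance per unit remote insulin); `s_H` hepatic insulin
#'     action per uU/ml (fractional EGP suppression per unit remote
#'     insulin; may be <= 0 for insulin-paradoxical production).
#'   \item `p2` remote-insulin equilibration rate, 1/min; `n_I` insulin
#'     clearance rate, 1/min; `V_I` insulin distribution volume, ml/kg.
#' }
#' Protocol: `prime_uCi` (25 uCi), `pump_uCi_min` (0.25 uCi/min),
#' `SA_inf_uCi_g` infusate labeling (2.7 uCi per g glucose),
#' `insulin_rate` mU/kg/min (0.75-1.0), `basal_duration` min (120-180
#' tracer equilibration), `clamp_duration` min, `sampling_interval` min
#' (10-15), `weight` kg.
#' Controller: proportional gain `Kp` (mg/kg/min per mg/dl), integral gain
#' `Ki` (mg/kg/min per mg/dl/min over the update interval), slope
#' compensation `Kd` (dimensionless; scales the demand-matching term
#' -Kd * V * dG/dt estimated from the last two glucose readings, the way a
#' clamp operator corrects for a falling glucose), `update_interval` min
#' (default NULL: the operator adjusts GINF at each sample draw, i.e. at
#' the sampling interval). Noise: `cv_G`, `cv_I` multiplicative CVs on
#' glucose and insulin assays; `tracer_sd_scale` scales a counting noise SD
#' proportional to the square root of the plasma activity (dpm/ml).
#'
#' @param ... named overrides of any default listed above, plus `seed`.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # physiology
    G_b = 95, EGP_b = 2.5, I_b = 0, V = 2.2,
    s_P = 8e-4, s_H = 0.012, p2 = 0.05, n_I = 0.09, V_I = 150,
    # protocol
    prime_uCi = 25, pump_uCi_min = 0.25, SA_inf_uCi_g = 2.7,
    insulin_rate = 1.0, basal_duration = 120, clamp_duration = 180,
    sampling_interval = 10, weight = 28.5,
    # controller
    Kp = 0.25, Ki = 0.01, Kd = 1, update_interval = NULL,
    # noise
    cv_G = 0.02, cv_I = 0.05, tracer_sd_scale = 1.0,
    seed = NULL,
    diet = "lean", state = "conscious", id = "sim"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  rates <- c("EGP_b", "prime_uCi", "pump_uCi_min", "SA_inf_uCi_g",
             "insulin_rate", "n_I", "p2")
  bad <- rates[vapply(rates, function(nm) cfg[[nm]] < 0, logical(1))]
  if (length(bad)) stop("rates must be non-negative: ", paste(bad, collapse = ", "))
  if (cfg$sampling_interval < 10 || cfg$sampling_interval > 15)
    stop("sampling_interval must be in [10, 15] min")
  if (cfg$basal_duration < 120 || cfg$basal_duration > 180)
    stop("basal_duration must be in [120, 180] min")
  if (cfg$V <= 0 || cfg$V_I <= 0) stop("distribution volumes must be positive")
  if (cfg$G_b <= 0 || cfg$weight <= 0) stop("G_b and weight must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Condition presets for the four diet-by-consciousness groups
#'
#' Anesthesia halves peripheral insulin action and suppresses hepatic
#' insulin action to near zero (lean) or slightly negative (fat-fed,
#' insulin-paradoxical EGP rise); fat feeding lowers both actions relative
#' to lean. The implied true indices are SI_P = 1e4 * s_P and
#' SI_H = 1e4 * EGP_b * s_H / G_b in the absence of EGP floor effects.
#'
#' @return named list of [sim_config()] override lists.
#' @export
clamp_presets <- function() {
  list(
    lean_conscious = list(diet = "lean", state = "conscious",
                          s_P = 8e-4, s_H = 0.012),
    lean_anesthetized = list(diet = "lean", state = "anesthetized",
                             s_P = 4e-4, s_H = 0.002),
    fat_conscious = list(diet = "fat_fed", state = "conscious",
                         s_P = 5e-4, s_H = 0.006),
    fat_anesthetized = list(diet = "fat_fed", state = "anesthetized",
                            s_P = 2.5e-4, s_H = -0.001)
  )
}

#' Build a preset configuration
#' @param name one of the names of [clamp_presets()].
#' @param ... further [sim_config()] overrides.
#' @export
preset_config <- function(name, ...) {
  pr <- clamp_presets()
  if (!name %in% names(pr)) stop("unknown preset: ", name)
  do.call(sim_config, utils::modifyList(pr[[name]], list(...)))
}

# Simulator right-hand side. States (per kg where applicable):
#   G mg/dl, Cs dpm/dl, I uU/ml, X uU/ml (remote insulin), Eint (mg/dl)*min,
#   lab_in / lab_out dpm/kg (cumulative label infused / cleared),
#   glu_net mg/kg (cumulative EGP + GINF - Rd).
.clamp_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    EGP <- max(0, EGP_b * (1 - s_H * X))
    Rd <- (k_b + s_P * X) * G
    lab_in_rate <- Fpump + GINF * SA_inf_dpm
    dG <- (EGP + GINF - Rd) / V
    dCs <- (lab_in_rate - Rd * Cs / G) / V
    dI <- ins_on * 1000 * insulin_rate / V_I - n_I * I
    dX <- -p2 * (X - (I - I_b))
    dEint <- ins_on * (G_b - G)
    list(c(dG, dCs, dI, dX, dEint, lab_in_rate, Rd * Cs / G, EGP + GINF - Rd))
  })
}

#' Simulate one clamp experiment
#'
#' Integrates the single-pool glucose, tracer, insulin and remote-insulin
#' dynamics over a basal tracer-equilibration period followed by the
#' hyperinsulinemic clamp, with a proportional-integral controller
#' adjusting the labeled glucose infusion (GINF) at discrete update times
#' to hold glucose at `G_b`, as an operator would at each sample draw.
#' Samples are then drawn at the configured interval with multiplicative
#' assay noise on glucose and insulin and additive counting noise on the
#' plasma tracer. Deterministic for a given `seed`.
#'
#' @param config a [sim_config()].
#' @return list with `record` (a [clamp_record()] of noisy samples),
#'   `truth` (data.frame on a 1-min grid: true G, I, X, GINF, EGP, Rd,
#'   Ra_total, SA, plasma activity and cumulative mass-balance ledgers) and
#'   the `config`.
#' @export
simulate_clamp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  total <- cfg$basal_duration + cfg$clamp_duration
  ins_start <- cfg$basal_duration

  parms0 <- c(G_b = cfg$G_b, EGP_b = cfg$EGP_b, I_b = cfg$I_b, V = cfg$V,
              s_P = cfg$s_P, s_H = cfg$s_H, p2 = cfg$p2, n_I = cfg$n_I,
              V_I = cfg$V_I, k_b = cfg$EGP_b / cfg$G_b,
              Fpump = cfg$pump_uCi_min * DPM_PER_UCI / cfg$weight,
              SA_inf_dpm = cfg$SA_inf_uCi_g * DPM_PER_UCI / 1000,
              insulin_rate = cfg$insulin_rate,
              GINF = 0, ins_on = 0)

  y <- c(G = cfg$G_b, Cs = cfg$prime_uCi * DPM_PER_UCI / (cfg$V * cfg$weight),
         I = cfg$I_b, X = 0, Eint = 0, lab_in = 0, lab_out = 0, glu_net = 0)

  # chunk boundaries: basal period in one piece, then controller updates;
  # the operator adjusts GINF at each sample draw, so updates default to
  # the sampling interval (keeping pump steps aligned with the record)
  upd <- if (is.null(cfg$update_interval)) cfg$sampling_interval else cfg$update_interval
  updates <- seq(ins_start, total, by = upd)
  bounds <- unique(c(0, updates, total))
  grid_all <- NULL
  ginf_steps <- data.frame(time = numeric(0), GINF = numeric(0))
  GINF <- 0
  Eint_prev <- 0
  G_prev <- y[["G"]]
  t_prev <- 0

  for (j in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[j]; t1 <- bounds[j + 1L]
    clamp_on <- t0 >= ins_start
    if (clamp_on) {
      err <- cfg$G_b - y[["G"]]
      int_err <- y[["Eint"]] - Eint_prev   # integral over the last interval
      Eint_prev <- y[["Eint"]]
      slope <- if (t0 > t_prev) (y[["G"]] - G_prev) / (t0 - t_prev) else 0
      GINF <- max(0, GINF - cfg$Kd * cfg$V * slope +
                    cfg$Kp * err + cfg$Ki * int_err)
      if (abs(y[["G"]] - cfg$G_b) / cfg$G_b > 0.5) {
        stop("clamp failed: |G - G_b|/G_b > 50% at t = ", t0,
             " min (G = ", signif(y[["G"]], 4), ")")
      }
    }
    parms <- parms0
    parms[["GINF"]] <- if (clamp_on) GINF else 0
    parms[["ins_on"]] <- as.numeric(clamp_on)
    ginf_steps <- rbind(ginf_steps, data.frame(time = t0, GINF = parms[["GINF"]]))
    G_prev <- y[["G"]]; t_prev <- t0
    times <- unique(c(seq(t0, t1, by = 1), t1))
    sol <- deSolve::lsoda(y, times, .clamp_rhs, parms,
                          rtol = 1e-10, atol = 1e-10)
    if (any(sol[, "G"] <= 0) || any(sol[, "Cs"] < 0)) {
      stop("integrator error: negative state")
    }
    seg <- as.data.frame(sol)
    seg$GINF <- parms[["GINF"]]
    grid_all <- rbind(grid_all, if (j < length(bounds) - 1L) seg[-nrow(seg), ] else seg)
    y <- unlist(seg[nrow(seg), names(y)])
  }

  truth <- grid_all
  truth$EGP <- pmax(0, cfg$EGP_b * (1 - cfg$s_H * truth$X))
  truth$Rd <- (cfg$EGP_b / cfg$G_b + cfg$s_P * truth$X) * truth$G
  truth$Ra_total <- truth$EGP + truth$GINF
  truth$SA <- truth$Cs / truth$G     # dpm/dl over mg/dl = dpm/mg
  truth$Gstar <- truth$Cs / 100      # dpm/ml

  # sample draws with assay noise
  ts <- seq(0, total, by = cfg$sampling_interval)
  ti <- match(round(ts), round(truth$time))
  stopifnot(!anyNA(ti))
  G_true <- truth$G[ti]; I_true <- truth$I[ti]; Cs_true <- truth$Cs[ti]
  n_s <- length(ts)
  G_obs <- G_true * (1 + cfg$cv_G * stats::rnorm(n_s))
  I_obs <- pmax(0, I_true * (1 + cfg$cv_I * stats::rnorm(n_s)))
  Gstar_true <- Cs_true / 100
  Gstar_obs <- pmax(0, Gstar_true +
                      cfg$tracer_sd_scale * sqrt(pmax(Gstar_true, 0)) * stats::rnorm(n_s))
  # GINF is a pump setting, recorded exactly (step function held since update)
  GINF_obs <- ginf_steps$GINF[findInterval(ts, ginf_steps$time)]
  Fpump_kg <- cfg$pump_uCi_min * DPM_PER_UCI / cfg$weight

  record <- clamp_record(
    time = ts, G = G_obs, Gstar = Gstar_obs, I = I_obs,
    GINF = GINF_obs, Fstar = rep(Fpump_kg, n_s),
    SA_inf = cfg$SA_inf_uCi_g * DPM_PER_UCI / 1000,
    weight = cfg$weight, insulin_rate = cfg$insulin_rate,
    insulin_start = ins_start, diet = cfg$diet, state = cfg$state,
    id = cfg$id)

  list(record = record, truth = truth, config = cfg)
}

#' Tracer and glucose mass-balance residuals of a simulation
#'
#' The label in the glucose pool must equal prime plus cumulative label
#' infused minus cumulative label cleared; the glucose pool excess must
#' equal the cumulative net flux. Returns the maximum absolute residual of
#' each ledger, relative to the running totals.
#'
#' @param sim result of [simulate_clamp()].
#' @return list with `tracer_rel` and `glucose_rel`.
#' @export
mass_balance <- function(sim) {
  tr <- sim$truth; cfg <- sim$config
  pool <- tr$Cs * cfg$V                       # dpm/kg
  prime <- cfg$prime_uCi * DPM_PER_UCI / (cfg$weight)
  res_t <- (prime + tr$lab_in - tr$lab_out) - pool
  scale_t <- pmax(prime + tr$lab_in, prime)
  res_g <- tr$glu_net - cfg$V * (tr$G - tr$G[1L])
  scale_g <- pmax(cumsum(c(0, abs(diff(tr$glu_net)))) + abs(tr$glu_net[1L]), 1)
  list(tracer_rel = max(abs(res_t / scale_t)),
       glucose_rel = max(abs(res_g / scale_g)))
}

#' Generator-implied true sensitivity indices
#'
#' Computes the same basal / steady-state window averages as the estimation
#' pipeline, but on the simulator's noise-free ground-truth trajectories,
#' giving the per-animal true SI_P, SI_H and MCR against which estimates
#' are judged. Accounts for controller imperfection and any EGP floor.
#'
#' @param sim result of [simulate_clamp()].
#' @param basal_window,ss_window averaging windows, min.
#' @return list with true `Rd_basal`, `EGP_basal`, `Rd_SS`, `EGP_SS`,
#'   `Gluc_SS`, `Ins_SS`, `dIns`, `SI_P`, `SI_H`, `MCR`.
#' @export
true_sensitivity <- function(sim, basal_window = 30, ss_window = 30) {
  tr <- sim$truth; cfg <- sim$config
  t_ins <- cfg$basal_duration
  t_end <- max(tr$time)
  b <- tr$time > t_ins - basal_window & tr$time <= t_ins
  s <- tr$time > t_end - ss_window & tr$time <= t_end
  Ins_SS <- mean(tr$I[s]); I_basal <- mean(tr$I[b])
  Gluc_SS <- mean(tr$G[s])
  dIns <- Ins_SS - I_basal
  dRd <- mean(tr$Rd[s]) - mean(tr$Rd[b])
  dEGP <- mean(tr$EGP[b]) - mean(tr$EGP[s])
  list(Rd_basal = mean(tr$Rd[b]), EGP_basal = mean(tr$EGP[b]),
       Rd_SS = mean(tr$Rd[s]), EGP_SS = mean(tr$EGP[s]),
       Gluc_SS = Gluc_SS, Ins_SS = Ins_SS, dIns = dIns,
       SI_P = 1e4 * dRd / (dIns * Gluc_SS),
       SI_H = 1e4 * dEGP / (dIns * Gluc_SS),
       MCR = cfg$insulin_rate / Ins_SS)
}

#' Simulate a cohort across condition presets
#'
#' Draws per-animal physiological parameters log-normally around the preset
#' means (multiplicative factors with unit mean and the given CV, applied
#' to G_b, EGP_b, s_P and s_H), body weights normally around 28.5 kg
#' (SD 2), and simulates each animal independently. The default group
#' sizes mirror a 16/16/16/8 design (conscious and anesthetized lean,
#' conscious and anesthetized fat-fed).
#'
#' @param n_per_group integer scalar or vector (recycled over
#'   `conditions`); default c(16, 16, 16, 8).
#' @param conditions preset names, default all four.
#' @param dispersion between-animal CV of the log-normal parameter
#'   variation (default 0.2).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param ... further [sim_config()] overrides applied to every animal
#'   (e.g. `cv_G = 0` for noise-free cohorts).
#' @return list of [simulate_clamp()] results.
#' @export
generate_cohort <- function(n_per_group = c(16L, 16L, 16L, 8L),
                            conditions = names(clamp_presets()),
                            dispersion = 0.2, seed = 1L, ...) {
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  unknown <- setdiff(conditions, names(clamp_presets()))
  if (length(unknown)) stop("unknown preset: ", paste(unknown, collapse = ", "))
  n_per_group <- rep_len(as.integer(n_per_group), length(conditions))
  set.seed(seed)
  sdlog <- sqrt(log(1 + dispersion^2))
  mulog <- -sdlog^2 / 2                      # unit-mean log-normal factors
  out <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (a in seq_len(n_per_group[ci])) {
      f <- stats::rlnorm(4, mulog, sdlog)
      # no between-animal variability at all when dispersion = 0
      w <- if (dispersion > 0) max(15, stats::rnorm(1, 28.5, 2)) else 28.5
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      base <- clamp_presets()[[cond]]
      cfg <- preset_config(cond,
                           G_b = 95 * f[1L], EGP_b = 2.5 * f[2L],
                           s_P = base$s_P * f[3L], s_H = base$s_H * f[4L],
                           weight = w, seed = sub_seed,
                           id = paste0(cond, "_", a), ...)
      out[[length(out) + 1L]] <- simulate_clamp(cfg)
    }
  }
  out
}
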