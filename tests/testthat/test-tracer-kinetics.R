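test_that("steady-state Steele reduces to F*/SA", {
  rec <- make_steady_record()
  fx <- compute_fluxes(rec, kinetic_constants(p = 0.65, V = 2.2))
  expect_equal(fx$Ra_total, rep(5, nrow(fx)), tolerance = 1e-9)
  expect_equal(fx$EGP, fx$Ra_total, tolerance = 1e-12)
  expect_equal(fx$Rd, fx$Ra_total, tolerance = 1e-8)
})

test_that("labeled infusate contributes to total tracer delivery", {
  # SA_inf = 2.7 uCi/g x 2.22e6 dpm/uCi / 1000 mg/g = 5994 dpm/mg
  sa_inf <- 2.7 * DPM_PER_UCI / 1000
  expect_equal(sa_inf, 5994)
  rec <- make_steady_record(GINF = 8, Fstar = 20000, SA_inf = sa_inf)
  fx <- compute_fluxes(rec)
  expect_equal(fx$Ra_total, rep((20000 + 8 * 5994) / 4000, nrow(fx)),
               tolerance = 1e-9)
  expect_equal(fx$Ra_total[1], 16.988)
  expect_equal(fx$EGP, fx$Ra_total - 8, tolerance = 1e-12)
})

test_that("flux identities hold at every sample", {
  s <- noise_free_sim()
  kc <- matched_constants(s)
  fx <- compute_fluxes(s$record, kc, noise_free_smooth)
  ginf <- s$record$GINF
  expect_equal(fx$Ra_total, fx$EGP + ginf, tolerance = 1e-12)
  # EGP + GINF - Rd = p V dG/dt (rearrangement identity)
  expect_equal(fx$EGP + ginf - fx$Rd, kc$p * kc$V * fx$dGdt,
               tolerance = 1e-10)
})

test_that("fluxes are invariant under joint rescaling of tracer units", {
  s <- noise_free_sim()
  rec <- s$record
  c_scale <- 3.7
  rec2 <- clamp_record(time = rec$time, G = rec$G, Gstar = c_scale * rec$Gstar,
                       I = rec$I, GINF = rec$GINF, Fstar = c_scale * rec$Fstar,
                       SA_inf = c_scale * rec$SA_inf, weight = rec$weight,
                       insulin_rate = rec$insulin_rate,
                       insulin_start = rec$insulin_start)
  f1 <- compute_fluxes(rec)
  f2 <- compute_fluxes(rec2)
  expect_equal(f2$Ra_total, f1$Ra_total, tolerance = 1e-9)
  expect_equal(f2$EGP, f1$EGP, tolerance = 1e-9)
  expect_equal(f2$Rd, f1$Rd, tolerance = 1e-9)
  expect_equal(f2$SA, c_scale * f1$SA, tolerance = 1e-9)
})

test_that("matched-model analysis recovers simulated fluxes after the transient", {
  s <- noise_free_sim()
  fx <- compute_fluxes(s$record, matched_constants(s), noise_free_smooth)
  tr <- s$truth
  sel <- s$record$time >= s$config$basal_duration + 30
  ti <- match(s$record$time, tr$time)
  rd_err <- abs(fx$Rd[sel] - tr$Rd[ti][sel]) / tr$Rd[ti][sel]
  egp_err <- abs(fx$EGP[sel] - tr$EGP[ti][sel]) / pmax(tr$EGP[ti][sel], 1e-9)
  expect_lt(max(rd_err), 0.02)
  expect_lt(max(egp_err), 0.02)
})

test_that("degenerate tracer inputs are refused", {
  rec <- make_steady_record()
  rec$Gstar <- rep(0, length(rec$Gstar))
  expect_error(compute_fluxes(rec), "Gstar identically zero")
  expect_error(clamp_record(time = seq(0, 100, 10), G = rep(100, 11),
                            Gstar = rep(4000, 11), I = rep(8, 11),
                            GINF = 5, Fstar = 20000, SA_inf = NULL,
                            weight = 28, insulin_rate = 1,
                            insulin_start = 60),
               "unlabeled infusate requires SA_inf")
})

test_that("basal averages use the half-open window ending at insulin start", {
  # constant basal: averages reproduce the constants
  rec <- make_steady_record(G = 95, I = 8, insulin_start = 60)
  fx <- compute_fluxes(rec)
  b <- basal_flux(fx, rec, window = 30)
  expect_equal(b$G_basal, 95)
  expect_equal(b$I_basal, 8)
  expect_equal(b$Rd_basal, b$EGP_basal, tolerance = 1e-8)
  # hand-checked windowing: samples in (150, 180] only
  tm <- seq(0, 180, by = 10)
  series <- data.frame(time = tm, Rd = seq(0.8, 2.6, by = 0.1),
                       EGP = seq(0.8, 2.6, by = 0.1))
  rec2 <- make_steady_record(n = 19, insulin_start = 180)
  b2 <- basal_flux(series, rec2, window = 30)
  expect_equal(b2$Rd_basal, mean(c(2.4, 2.5, 2.6)))
  expect_error(basal_flux(series, rec2, window = 200), "basal window")
})

test_that("noise-free basal equilibrium recovers the simulator's EGP_b", {
  s <- noise_free_sim()
  fx <- suppressWarnings(compute_fluxes(s$record, matched_constants(s)))
  b <- basal_flux(fx, s$record, window = 30)
  expect_equal(b$EGP_basal, s$config$EGP_b, tolerance = 0.02)
  expect_equal(b$Rd_basal, s$config$EGP_b, tolerance = 0.02)
})
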