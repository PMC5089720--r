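test_that("basal equilibrium is a fixed point without insulin", {
  cfg <- sim_config(insulin_rate = 0, cv_G = 0, cv_I = 0, tracer_sd_scale = 0,
                    Kp = 0, Ki = 0, Kd = 0)
  s <- simulate_clamp(cfg)
  expect_equal(range(s$truth$G), c(cfg$G_b, cfg$G_b), tolerance = 1e-8)
  expect_equal(range(s$truth$EGP), c(cfg$EGP_b, cfg$EGP_b), tolerance = 1e-8)
  expect_equal(range(s$truth$Rd), c(cfg$EGP_b, cfg$EGP_b), tolerance = 1e-8)
})

test_that("steady-state insulin matches the analytic closed form", {
  cfg <- sim_config(cv_G = 0, cv_I = 0, tracer_sd_scale = 0)
  s <- simulate_clamp(cfg)
  fin <- s$truth$time > max(s$truth$time) - 30
  i_ss <- mean(s$truth$I[fin])
  expect_equal(i_ss, 1000 * cfg$insulin_rate / (cfg$n_I * cfg$V_I),
               tolerance = 1e-3)
})

test_that("tracer and glucose mass balances close to integrator tolerance", {
  s <- noise_free_sim()
  mb <- mass_balance(s)
  expect_lt(mb$tracer_rel, 1e-8)
  expect_lt(mb$glucose_rel, 1e-8)
})

test_that("default presets hold glucose within 5% of basal over the final 30 min", {
  for (p in names(clamp_presets())) {
    s <- simulate_clamp(preset_config(p, cv_G = 0, cv_I = 0,
                                      tracer_sd_scale = 0))
    fin <- s$truth$time > max(s$truth$time) - 30
    dev <- max(abs(s$truth$G[fin] - s$config$G_b)) / s$config$G_b
    expect_lt(dev, 0.05)
  }
})

test_that("simulation is deterministic given a seed", {
  s1 <- simulate_clamp(sim_config(seed = 123))
  s2 <- simulate_clamp(sim_config(seed = 123))
  expect_identical(s1$record$G, s2$record$G)
  expect_identical(s1$record$Gstar, s2$record$Gstar)
  c1 <- generate_cohort(n_per_group = 2, conditions = "lean_conscious",
                        seed = 9)
  c2 <- generate_cohort(n_per_group = 2, conditions = "lean_conscious",
                        seed = 9)
  expect_identical(lapply(c1, function(s) s$record),
                   lapply(c2, function(s) s$record))
})

test_that("zero dispersion and zero noise make cohort animals identical", {
  co <- generate_cohort(n_per_group = 3, conditions = "lean_conscious",
                        dispersion = 0, seed = 4,
                        cv_G = 0, cv_I = 0, tracer_sd_scale = 0)
  base_cfg <- co[[1]]$config
  for (s in co[-1]) {
    expect_equal(s$config$s_P, base_cfg$s_P)
    expect_equal(s$record$G, co[[1]]$record$G)
    expect_equal(s$record$Gstar, co[[1]]$record$Gstar)
  }
})

test_that("between-animal dispersion reproduces the requested CV", {
  co <- generate_cohort(n_per_group = 200, conditions = "lean_conscious",
                        dispersion = 0.2, seed = 31,
                        basal_duration = 120, clamp_duration = 30,
                        insulin_rate = 0)
  egp_b <- vapply(co, function(s) s$config$EGP_b, numeric(1))
  cv <- stats::sd(egp_b) / mean(egp_b)
  expect_gt(cv, 0.17)
  expect_lt(cv, 0.23)
  expect_equal(mean(egp_b), 2.5, tolerance = 0.05)
  w <- vapply(co, function(s) s$config$weight, numeric(1))
  expect_equal(mean(w), 28.5, tolerance = 0.5)
})

test_that("anesthetized presets have lower insulin action than conscious", {
  pr <- clamp_presets()
  expect_lt(pr$lean_anesthetized$s_P, pr$lean_conscious$s_P)
  expect_lt(pr$fat_anesthetized$s_P, pr$fat_conscious$s_P)
  expect_lt(pr$lean_anesthetized$s_H, pr$lean_conscious$s_H)
  expect_lt(pr$fat_anesthetized$s_H, pr$fat_conscious$s_H)
  expect_lt(pr$fat_anesthetized$s_H, 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sampling_interval = 5), "sampling_interval")
  expect_error(sim_config(basal_duration = 60), "basal_duration")
  expect_error(sim_config(EGP_b = -1), "non-negative")
  expect_error(sim_config(V = 0), "volumes")
  expect_error(preset_config("lean_vs_fat"), "unknown preset")
  expect_error(generate_cohort(n_per_group = 0), "n_per_group")
  expect_error(generate_cohort(conditions = "unknown_condition"),
               "unknown preset")
})

test_that("a dead controller under insulin fails the clamp loudly", {
  cfg <- sim_config(Kp = 0, Ki = 0, Kd = 0, cv_G = 0, cv_I = 0,
                    tracer_sd_scale = 0)
  expect_error(simulate_clamp(cfg), "clamp failed")
})
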