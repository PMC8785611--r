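test_that("sway generator is seed-deterministic and honours the OU closed form", {
  cfg <- default_generator_config(seed = 10)
  s1 <- simulate_sway(cfg, "control", "EO_NoDT", seed = 5)
  s2 <- simulate_sway(cfg, "control", "EO_NoDT", seed = 5)
  expect_identical(s1$trial$left$fz, s2$trial$left$fz)
  expect_identical(s1$trial$right$cop_x, s2$trial$right$cop_x)
  s3 <- simulate_sway(cfg, "control", "EO_NoDT", seed = 6)
  expect_false(identical(s1$trial$left$cop_x, s3$trial$left$cop_x))

  # raw OU (no band limit, no jitter, no plate noise): stationary per-axis
  # variance sigma^2/(2k), ellipse area pi * chi2 * variance
  cfg0 <- cfg
  cfg0$bandwidth_hz <- Inf
  cfg0$force_noise_sd_n <- 0
  cfg0$sway$control <- list(k = 1, sigma = 2, jitter = 0)
  areas <- vars <- numeric(6)
  for (i in 1:6) {
    s <- simulate_sway(cfg0, "control", "EO_NoDT", duration_s = 300,
                       seed = 100 + i)
    traj <- combine_plates(s$trial$left, s$trial$right)
    areas[i] <- ellipse_area_95(traj)
    vars[i] <- var(traj$ap)
    expect_equal(s$truth$var_axis, 2)
  }
  expect_equal(mean(vars), 2, tolerance = 0.08)
  expect_equal(mean(areas), pi * qchisq(0.95, 2) * 2, tolerance = 0.08)
})

test_that("doubling the mean-reversion rate halves the stationary variance", {
  cfg <- default_generator_config(seed = 10)
  cfg$bandwidth_hz <- Inf
  cfg$force_noise_sd_n <- 0
  v_at <- function(k) {
    cfg$sway$control <- list(k = k, sigma = 3, jitter = 0)
    v <- numeric(5)
    for (i in 1:5) {
      s <- simulate_sway(cfg, "control", "EO_NoDT", duration_s = 300,
                         seed = 200 + i)
      traj <- combine_plates(s$trial$left, s$trial$right)
      v[i] <- (var(traj$ap) + var(traj$ml)) / 2
    }
    mean(v)
  }
  expect_equal(v_at(2) / v_at(1), 0.5, tolerance = 0.1)
})

test_that("noise-free perturbation kernel reaches the configured peak and steps recover", {
  cfg <- default_generator_config(seed = 10)
  cfg$sway$control <- list(k = 2, sigma = 1e-9, jitter = 0)
  cfg$force_noise_sd_n <- 0
  cfg$anticipation_sigma_factor <- 1
  cfg$anticipation_jitter_factor <- 1
  cfg$stepping$p_step <- c(control = 0, PD = 0)
  sim <- simulate_perturbation_trial(cfg, "control", n_events = 2, seed = 3)
  rows <- analyze_trial(sim$trial)
  cm <- rows$value[rows$metric == "cop_max"]
  amps <- ifelse(startsWith(sim$truth$type, "trans"),
                 cfg$perturbation$amp_translation_mm,
                 cfg$perturbation$amp_tilt_mm)
  expect_equal(cm, amps, tolerance = 0.01)
  expect_true(all(rows$strategy[!is.na(rows$strategy)] == "in_place"))
})

test_that("injected step counts are recovered exactly on noise-free plates", {
  cfg <- default_generator_config(seed = 10)
  cfg$force_noise_sd_n <- 0
  cfg$stepping$p_step <- c(control = 1, PD = 1)   # every event steps
  hits <- 0L; total <- 0L
  for (i in 1:4) {
    sim <- simulate_perturbation_trial(cfg, "PD", n_events = 4,
                                       seed = 400 + i)
    rows <- analyze_trial(sim$trial)
    det <- rows[rows$metric == "n_steps", c("event", "value")]
    injected <- sim$truth$n_steps[match(det$event, sim$truth$event)]
    total <- total + nrow(det)
    hits <- hits + sum(det$value == injected)
  }
  expect_identical(hits, total)
})

test_that("longer recovery constants increase detected recovery times", {
  cfg <- default_generator_config(seed = 10)
  cfg$stepping$p_step <- c(control = 0, PD = 0)
  med_at <- function(tau) {
    cfg$perturbation$tau_recovery_s <- c(control = tau, PD = tau)
    out <- c()
    for (i in 1:6) {
      sim <- simulate_perturbation_trial(cfg, "control", n_events = 4,
                                         seed = 500 + i)
      rows <- analyze_trial(sim$trial)
      out <- c(out, rows$value[rows$metric == "recovery_time" &
                                 !rows$discarded])
    }
    median(out)
  }
  m1 <- med_at(0.5)
  m2 <- med_at(1.0)
  expect_gt(m2, m1)
})

test_that("pipeline recovery matches generator ground truth and rarely censors", {
  cfg <- default_generator_config(seed = 10)
  errs <- c(); cens <- c()
  for (i in 1:7) for (g in c("control", "PD")) {
    sim <- simulate_perturbation_trial(cfg, g, seed = 600 + i)
    rows <- analyze_trial(sim$trial)
    rt <- rows[rows$metric == "recovery_time" & !rows$discarded, ]
    errs <- c(errs, rt$value - sim$truth$true_recovery_s)
    cens <- c(cens, rt$censored)
  }
  expect_gte(length(errs), 100)
  expect_lt(abs(median(errs)), 0.15)
  expect_lt(mean(cens), 0.05)
})

test_that("pre-perturbation anticipation inflates standing sway area", {
  cfg <- default_generator_config(seed = 10)
  cfg$stepping$p_step <- c(control = 0, PD = 0)
  pre_areas <- c()
  for (i in 1:4) {
    sim <- simulate_perturbation_trial(cfg, "control", n_events = 4,
                                       seed = 700 + i)
    rows <- analyze_trial(sim$trial)
    pre_areas <- c(pre_areas, rows$value[rows$metric == "pre_area"])
  }
  sway_areas <- c()
  for (i in 1:8) {
    s <- simulate_sway(cfg, "control", "EO_NoDT", seed = 750 + i)
    sway_areas <- c(sway_areas, sway_metrics(s$trial)$ellipse_area)
  }
  # anticipation doubles sigma (variance x4): prior-standing area well
  # above quiet-sway area (5 s windows are noisier, hence the loose bound)
  expect_gt(median(pre_areas) / median(sway_areas), 2)
})

test_that("counting simulator is Poisson at the configured rate and deterministic", {
  cfg <- default_generator_config(seed = 10)
  r1 <- simulate_counting(cfg, "PD", "reference", 60, seed = 9)
  r2 <- simulate_counting(cfg, "PD", "reference", 60, seed = 9)
  expect_identical(r1$n_correct_counts, r2$n_correct_counts)
  rates <- vapply(1:300, function(i) {
    counting_rate(simulate_counting(cfg, "control", "sway", 60, seed = i,
                                    rate_ref = 20))
  }, numeric(1))
  expect_equal(mean(rates), 20 * cfg$counting$sway_factor[["control"]],
               tolerance = 0.05)
  z <- simulate_counting(cfg, "control", "reference", 60, seed = 1,
                         rate_ref = 1e-9)
  expect_identical(z$n_correct_counts, 0L)
})

test_that("cohorts are reproducible and carry matching truth keys", {
  cfg <- default_generator_config(n_pd = 2, n_control = 2, seed = 77)
  coh1 <- simulate_cohort(cfg, sway_conditions = "EO_NoDT",
                          pert_conditions = character(0))
  coh2 <- simulate_cohort(cfg, sway_conditions = "EO_NoDT",
                          pert_conditions = character(0))
  expect_identical(names(coh1$trials), names(coh2$trials))
  expect_identical(coh1$trials[[1]]$left$fz, coh2$trials[[1]]$left$fz)
  expect_setequal(names(coh1$truth), names(coh1$trials))
  expect_identical(coh1$counting$n_correct, coh2$counting$n_correct)
})
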