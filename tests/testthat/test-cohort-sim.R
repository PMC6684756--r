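test_that("simulation is fully reproducible for a fixed seed", {
  cfg <- cohort_sim_config(n_patients = 60, seed = 123)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$volumes, s2$volumes)
  s3 <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("with zero slopes the intercept fixes the prevalence", {
  cfg <- cohort_sim_config(
    n_patients = 50000,
    coefficients = c(intercept = qlogis(0.114)),
    seed = 2026)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$cohort$label) - 0.114), 0.005)
})

test_that("the calibrated intercept hits the target prevalence with slopes on", {
  cfg <- cohort_sim_config(n_patients = 50000, seed = 31)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(mean(sim$cohort$label) - 0.114), 0.01)
})

test_that("feature distributions are recovered at n = 10000", {
  cfg <- cohort_sim_config(n_patients = 10000, seed = 99)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  n <- nrow(co)
  # mean within 3 SE(mean), SD within 3 SE(SD), for both gland doses
  chk <- function(x, mean_target, sd_target) {
    expect_lt(abs(mean(x) - mean_target), 3 * sd_target / sqrt(n))
    expect_lt(abs(sd(x) - sd_target), 3 * sd_target / sqrt(2 * n))
  }
  chk(co$md_gy, 18.6, 5.9)
  chk(co$md_ipsi_gy, 25.6, 8.9)
  # log-normal GRADX: median at the configured value
  expect_equal(median(co$gradx_gy_per_mm), 1.27, tolerance = 0.05)
  expect_true(all(co$gradx_gy_per_mm > 0))
  # volume-change pathway: Normal(-2.0, 4.2) percent
  dv <- sim$migration$delta_vc2_pct
  expect_lt(abs(mean(dv) - (-2.0)), 3 * 4.2 / sqrt(n))
  expect_lt(abs(sd(dv) - 4.2), 3 * 4.2 / sqrt(2 * n))
  # control days inside the configured window
  expect_true(all(sim$migration$control_day >= 28 &
                    sim$migration$control_day <= 36))
})

test_that("the Gaussian copula reproduces the configured Kendall tau", {
  cfg <- cohort_sim_config(n_patients = 5000, ipsi_contra_tau = 0.5,
                           seed = 55)
  sim <- simulate_cohort(cfg)
  tau_md <- kendall_concordance(sim$cohort$md_gy,
                                sim$cohort$md_ipsi_gy)$tau
  tau_gx <- kendall_concordance(sim$cohort$gradx_gy_per_mm,
                                sim$cohort$gradx_ipsi_gy_per_mm)$tau
  expect_lt(abs(tau_md - 0.5), 0.05)
  expect_lt(abs(tau_gx - 0.5), 0.05)
  # the concordance screen of the study conditions: tau > 0.4
  expect_gt(tau_md, 0.4)
  expect_gt(tau_gx, 0.4)
})

test_that("outcome correlates with the migration dose increment", {
  # positive delivered-dose coefficient => positive partial correlation
  # of the outcome with GRADX * PGM after adjusting for planned MD
  cfg <- cohort_sim_config(n_patients = 5000,
                           coefficients = c(delivered_md = 1),
                           seed = 77)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  inc <- co$gradx_gy_per_mm * co$pgm_mm
  r_y <- residuals(lm(co$label ~ co$md_gy))
  r_i <- residuals(lm(inc ~ co$md_gy))
  expect_gt(cor(r_y, r_i), 0)
})

test_that("simulated reports support the endpoint round trip", {
  cfg <- cohort_sim_config(n_patients = 300, seed = 8)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$reports$grade %in% 0:4))
  expect_true(all(sim$reports$months_after_rt >= 6 &
                    sim$reports$months_after_rt <= 24))
  lab <- pool_reports(sim$reports)
  # every patient got at least one in-window report
  expect_setequal(lab$patient_id, sim$cohort$patient_id)
  # pooled labels agree with the generative labels for most patients
  # (grade noise flips only borderline cases)
  joined <- merge(lab, sim$cohort, by = "patient_id")
  expect_gt(mean(joined$label.x == joined$label.y), 0.9)
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_sim_config(n_patients = 3), "at least 4")
  expect_error(cohort_sim_config(ipsi_contra_tau = 1), "tau")
  expect_error(cohort_sim_config(gradx_sdlog = -1), "positive")
  expect_error(cohort_sim_config(coefficients = c(banana = 1)), "named")
  expect_error(cohort_sim_config(control_day_range = c(30, 50)),
               "control_day_range")
})
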