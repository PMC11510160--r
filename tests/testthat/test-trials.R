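# Trial orchestration: baseline trial sets, paired DDI protocols, fm
# calibration and sensitivity scans.

test_that("a single deterministic subject reproduces the closed-form Css", {
  design <- trial_design(1, 1, template = cv0_template(), seed = 4)
  out <- run_trial_set(design, chol, bohc)
  ss <- analytic_steady_state(chol, bohc,
                              sample_population(cv0_template(), 1, 5)[[1]],
                              infusion_rate_ref)
  expect_equal(out$mean_css_parent, ss$css_parent, tolerance = 1e-9)
  expect_equal(out$mean_css_metabolite, ss$css_metabolite, tolerance = 1e-9)
})

test_that("trial sets are reproducible and percentile-consistent", {
  design <- trial_design(3, 8, template = pm_template(), seed = 17)
  a <- run_trial_set(design, chol, bohc)
  b <- run_trial_set(design, chol, bohc)
  expect_identical(a$subjects, b$subjects)
  expect_lt(a$p5_css_metabolite, a$mean_css_metabolite)
  expect_gt(a$p95_css_metabolite, a$mean_css_metabolite)
  expect_equal(nrow(a$subjects), 24)
})

test_that("analytic and ODE trial engines agree for a mean individual", {
  design <- trial_design(1, 2, template = cv0_template(), seed = 2)
  an <- run_trial_set(design, chol, bohc, method = "analytic")
  od <- run_trial_set(design, chol, bohc, method = "ode")
  expect_equal(od$mean_css_metabolite, an$mean_css_metabolite, tolerance = 5e-3)
})

test_that("a saturating activity fold multiplies the population metabolite mean", {
  design <- trial_design(2, 10, template = pm_template(), seed = 8)
  base <- run_trial_set(design, chol, bohc, cyp3a_fold = 1)
  ind <- run_trial_set(design, chol, bohc, cyp3a_fold = 16)
  expect_equal(ind$mean_css_metabolite / base$mean_css_metabolite, 16,
               tolerance = 0.01)
})

test_that("ddi_protocol returns unit ratios for a null perturbation", {
  design <- trial_design(1, 2, template = cv0_template(), seed = 6,
                         baseline_days = 100, perpetrator_days = 30)
  res <- ddi_protocol(design, list(forced_fold = 1), parent = chol,
                      metabolite = bohc)
  expect_equal(res$ratios$ratio, rep(1, 2), tolerance = 1e-6)
  expect_error(
    ddi_protocol(trial_design(1, 1, template = cv0_template(),
                              baseline_days = 100, perpetrator_days = 0),
                 list(forced_fold = 2), parent = chol, metabolite = bohc),
    "perpetrator_days")
})

test_that("ddi_protocol under a sustained fold approaches that fold", {
  design <- trial_design(1, 2, template = pm_template(), seed = 12,
                         baseline_days = 100, perpetrator_days = 60)
  res <- ddi_protocol(design, list(forced_fold = 4), parent = chol,
                      metabolite = bohc)
  expect_equal(res$mean_ratio, 4, tolerance = 0.02)
  # paired design: ratio variance is far below Css variance
  expect_lt(stats::sd(res$ratios$ratio) / mean(res$ratios$ratio),
            0.1 * stats::sd(res$ratios$css_baseline) / mean(res$ratios$css_baseline))
})

test_that("an inducer perpetrator elevates the metabolite via its PK exposure", {
  design <- trial_design(1, 1, template = cv0_template(), seed = 30,
                         baseline_days = 100, perpetrator_days = 60)
  res <- ddi_protocol(design, test_cfg$perpetrators[["rifampicin-like"]],
                      parent = chol, metabolite = bohc)
  expect_gt(res$mean_ratio, 2)
  expect_lt(res$mean_ratio, 16)
})

test_that("calibration returns the fixed point and recovers synthetic truth", {
  design <- trial_design(1, 1, template = cv0_template(), seed = 1)
  current <- analytic_steady_state(chol, bohc, phys_ref,
                                   infusion_rate_ref)$css_metabolite
  cal <- calibrate_fm_cyp3a(current, design, chol, bohc, phys = phys_ref)
  expect_equal(cal$clint_3a4, 4.17e-7, tolerance = 0.01)
  expect_equal(cal$achieved_css, current, tolerance = 1e-4)
  expect_equal(cal$clint_3a5 / cal$clint_3a4, 0.056 / 0.916, tolerance = 1e-9)
  # parameter recovery from a noisy synthetic fixture
  fix <- recovery_fixture(3e-7, design, seed = 42, noise_cv = 5)
  cal2 <- calibrate_fm_cyp3a(fix$observed$css_baseline, design, chol, bohc,
                             phys = phys_ref)
  expect_equal(cal2$clint_3a4, fix$truth$clint_3a4, tolerance = 0.10)
  # unreachable target
  expect_error(calibrate_fm_cyp3a(1e-16, design, chol, bohc, phys = phys_ref),
               "not bracketed")
})

test_that("calibration curve is monotone in the CYP3A4 intrinsic clearance", {
  design <- trial_design(1, 1, template = cv0_template(), seed = 1)
  grid <- 10^seq(-8, -5, length.out = 8)
  css <- vapply(grid, function(x) {
    p <- ohcpbpk:::rebalanced_parent(chol, x, phys_ref)
    analytic_steady_state(p, bohc, phys_ref, infusion_rate_ref)$css_metabolite
  }, numeric(1))
  expect_true(all(diff(css) > 0))
})

test_that("sensitivity scan is linear in dose and resolves parameter paths", {
  scan <- sensitivity_scan(test_cfg, "regimens.1.dose", c(1, 3))
  expect_equal(scan$css_parent[2] / scan$css_parent[1], 3, tolerance = 1e-9)
  expect_equal(scan$css_metabolite[2] / scan$css_metabolite[1], 3,
               tolerance = 1e-9)
  empty <- sensitivity_scan(test_cfg, "regimens.1.dose", numeric())
  expect_equal(nrow(empty), 0)
  expect_error(sensitivity_scan(test_cfg, "physiology.nonsense", c(1)),
               "cannot resolve")
  # monotone: less CYP27A1 means higher steady-state levels
  scan27 <- sensitivity_scan(test_cfg, "physiology.abundances.CYP27A1",
                             c(40, 30, 20))
  expect_true(all(diff(scan27$css_metabolite) > 0))
  expect_true(all(diff(scan27$css_parent) > 0))
})
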