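# PBPK engine: induction model, enzyme turnover, analytic steady state,
# ODE consistency, DDI ratios and post-perturbation kinetics.

test_that("induction fold follows the Emax form and its bounds", {
  expect_equal(induction_fold(0, 16, 0.32), 1)
  expect_equal(induction_fold(0.32, 16, 0.32), 8.5)
  expect_equal(induction_fold(1e9, 16, 0.32), 16, tolerance = 1e-6)
  conc <- seq(0, 10, by = 0.1)
  folds <- induction_fold(conc, 16, 0.32)
  expect_true(all(diff(folds) > 0))
  expect_true(all(folds >= 1 & folds <= 16))
  expect_error(induction_fold(-1, 16, 0.32), "c_unbound_liver")
})

test_that("enzyme turnover has the right equilibria and closed-form relaxation", {
  expect_equal(enzyme_turnover_rhs(1, 1, 0.0193), 0)
  expect_equal(enzyme_turnover_rhs(8.5, 8.5, 0.0193), 0)
  # constant signal F from e = 1: e(t) = F + (1 - F) exp(-kdeg t)
  sim <- simulate_subject(phys_ref, chol, bohc,
                          list(dose_regimen("cholesterol", "iv_infusion", 1.73,
                                            duration_days = 30)),
                          duration_days = 30, forced_cyp3a_fold = 4, dt_out = 6)
  expected <- 4 + (1 - 4) * exp(-0.0193 * sim$time)
  expect_equal(sim$enzyme_level, expected, tolerance = 1e-5)
})

test_that("competitive inhibition scales clearance by 1/(1 + C/Ki)", {
  expect_equal(inhibited_clint(10, 0, 1), 10)
  expect_equal(inhibited_clint(10, 1, 1), 5)
  expect_equal(inhibited_clint(10, 9, 1), 1)
})

test_that("analytic steady state is linear in dose and zero without CYP3A formation", {
  ss1 <- analytic_steady_state(chol, bohc, phys_ref, infusion_rate_ref)
  ss2 <- analytic_steady_state(chol, bohc, phys_ref, 2 * infusion_rate_ref)
  expect_equal(ss2$css_parent, 2 * ss1$css_parent, tolerance = 1e-12)
  expect_equal(ss2$css_metabolite, 2 * ss1$css_metabolite, tolerance = 1e-12)
  expect_equal(ss1$liver_parent, 3.07 * ss1$css_parent, tolerance = 1e-12)
  no3a <- chol
  no3a$pathways <- no3a$pathways[c("CYP27A1", "HLM")]
  expect_equal(analytic_steady_state(no3a, bohc, phys_ref,
                                     infusion_rate_ref)$css_metabolite, 0)
})

test_that("parent steady state is insensitive to rifampicin-level CYP3A induction", {
  base <- analytic_steady_state(chol, bohc, phys_ref, infusion_rate_ref)
  ind <- analytic_steady_state(chol, bohc, phys_ref, infusion_rate_ref,
                               cyp3a_fold = 16)
  expect_lt(abs(ind$css_parent / base$css_parent - 1), 0.002)
  expect_gt(ind$css_metabolite / base$css_metabolite, 15.5)
})

test_that("ODE simulation reaches the analytic steady state and balances mass", {
  sim <- simulate_subject(phys_ref, chol, bohc, test_cfg$regimens,
                          duration_days = 700, init = "zero")
  ss <- analytic_steady_state(chol, bohc, phys_ref, infusion_rate_ref)
  expect_equal(sim$css_parent, ss$css_parent, tolerance = 5e-3)
  expect_equal(sim$css_metabolite, ss$css_metabolite, tolerance = 5e-3)
  b <- sim$balance
  expect_equal(b$infused, b$parent_amount + b$parent_eliminated,
               tolerance = 1e-6)
  expect_equal(b$metabolite_formed, b$metabolite_amount + b$metabolite_eliminated,
               tolerance = 1e-6)
})

test_that("a null perpetrator leaves the simulation unchanged", {
  null_perp <- list(
    compound = compound_params("null", 800, blood_to_plasma = 0.9,
                               fu_plasma = 0.2, vss = 0.65),
    interaction = interaction_spec("induction", ind_max = 1, ind_c50 = 0.32),
    pk = list(ka = 1, v = 46, cl = 7))
  regs <- list(dose_regimen("cholesterol", "iv_infusion", 1.73, duration_days = 120),
               dose_regimen("null", "oral", 600, start_day = 60, duration_days = 30))
  with_perp <- simulate_subject(phys_ref, chol, bohc, regs,
                                perpetrator = null_perp, duration_days = 120)
  without <- simulate_subject(phys_ref, chol, bohc, regs[1], duration_days = 120)
  expect_equal(with_perp$plasma_metabolite, without$plasma_metabolite,
               tolerance = 1e-6)
  expect_equal(with_perp$enzyme_level, rep(1, length(with_perp$time)),
               tolerance = 1e-8)
})

test_that("a step induction drives the metabolite towards fold x baseline", {
  fold <- 3
  base <- simulate_subject(phys_ref, chol, bohc,
                           list(dose_regimen("cholesterol", "iv_infusion", 1.73,
                                             duration_days = 160)),
                           duration_days = 160, init = "analytic")
  ind <- simulate_subject(phys_ref, chol, bohc,
                          list(dose_regimen("cholesterol", "iv_infusion", 1.73,
                                            duration_days = 160)),
                          duration_days = 160, init = "analytic",
                          forced_cyp3a_fold = list(fold = fold, from_day = 40))
  r <- ddi_ratio(base, ind)
  expect_equal(r, fold, tolerance = 0.01)
  expect_equal(ddi_ratio(base, base), 1)
  expect_error(ddi_ratio(base, ind, window = c(-10, 1e6)), "window")
})

test_that("induction and inhibition move the DDI ratio in opposite directions", {
  regs <- list(dose_regimen("cholesterol", "iv_infusion", 1.73, duration_days = 160))
  base <- simulate_subject(phys_ref, chol, bohc, regs, duration_days = 160,
                           init = "analytic")
  inh <- simulate_subject(phys_ref, chol, bohc, regs, duration_days = 160,
                          init = "analytic",
                          forced_cyp3a_fold = list(fold = 0.05, from_day = 40))
  expect_lt(ddi_ratio(base, inh), 0.1)
})

test_that("post-perturbation half-life recovers a known mono-exponential phase", {
  # synthetic decay profile with t1/2 = 62 h
  t <- seq(0, 62 * 12, by = 6)
  out <- structure(list(time = t, plasma_metabolite = 20 * exp(-log(2) / 62 * t)),
                   class = "simulation_output")
  expect_equal(post_perturbation_halflife(out, 0), 62 / 24, tolerance = 1e-3)
  flat <- structure(list(time = t, plasma_metabolite = rep(20, length(t))),
                    class = "simulation_output")
  expect_error(post_perturbation_halflife(flat, 0), "flat")
})

test_that("de-induction half-life reflects the slow parent-metabolite cascade", {
  regs <- list(dose_regimen("cholesterol", "iv_infusion", 1.73, duration_days = 300))
  washout <- simulate_subject(phys_ref, chol, bohc, regs, duration_days = 300,
                              init = "analytic",
                              forced_cyp3a_fold = list(fold = 1, from_day = 0),
                              dt_out = 12)
  ind <- simulate_subject(phys_ref, chol, bohc, regs, duration_days = 300,
                          init = "analytic",
                          forced_cyp3a_fold = list(fold = 8, from_day = 50),
                          dt_out = 12)
  t_half_days <- post_perturbation_halflife(ind, 51 * 24)
  # dominant phase is bounded below by the metabolite elimination half-life
  expect_gt(t_half_days, 62 / 24 * 0.9)
  expect_lt(t_half_days, 10)
})
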