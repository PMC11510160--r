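# Minimal parent-metabolite PBPK engine: one systemic compartment per
# analyte (Vss-based), hepatic elimination by the well-stirred liver model,
# CYP3A-mediated metabolite formation with molecular-weight conversion, and
# time-varying CYP3A activity through an enzyme-turnover induction model or
# competitive inhibition driven by a one-compartment perpetrator.

#' Emax-type induction fold
#'
#' `fold = 1 + (Ind_max - 1) x C / (IndC50 + C)`; monotone in `C`, equal to
#' `(Ind_max + 1)/2` at `C = IndC50` and bounded by `Ind_max`.
#'
#' @param c_unbound_liver Unbound liver perpetrator concentration, uM (>= 0).
#' @param ind_max Maximal fold induction (>= 1).
#' @param ind_c50 Concentration at half-maximal induction, uM.
#' @return Induction fold in `[1, ind_max]`.
#' @export
induction_fold <- function(c_unbound_liver, ind_max, ind_c50) {
  if (any(c_unbound_liver < 0)) stop_field("c_unbound_liver", "must be >= 0")
  check_positive(ind_max, "ind_max")
  check_positive(ind_c50, "ind_c50")
  1 + (ind_max - 1) * c_unbound_liver / (ind_c50 + c_unbound_liver)
}

#' Enzyme turnover rate
#'
#' First-order turnover of the relative enzyme level `E` (1 at baseline)
#' towards the induction signal: `dE/dt = kdeg x (fold_signal - E)`, so the
#' steady state is `E = fold_signal` and the onset/offset timescale is
#' `ln(2)/kdeg`.
#'
#' @param e_level Relative enzyme level (>= 0).
#' @param fold_signal Current induction fold.
#' @param kdeg Degradation rate constant, 1/h.
#' @return dE/dt, 1/h.
#' @export
enzyme_turnover_rhs <- function(e_level, fold_signal, kdeg) {
  if (any(e_level < 0)) stop_field("e_level", "must be >= 0")
  kdeg * (fold_signal - e_level)
}

#' Competitive inhibition of an intrinsic clearance
#'
#' @param clint Intrinsic clearance (any basis).
#' @param c_unbound_liver Unbound inhibitor concentration, uM.
#' @param ki Competitive inhibition constant, uM.
#' @return `clint / (1 + C/Ki)`.
#' @export
inhibited_clint <- function(clint, c_unbound_liver, ki) {
  check_positive(ki, "ki")
  clint / (1 + c_unbound_liver / ki)
}

# Effective per-pathway scaled CLint (L/h) under a CYP3A activity fold.
effective_clint <- function(compound, phys, cyp3a_fold = 1) {
  fold <- stats::setNames(rep(cyp3a_fold, length(CYP3A_ENZYMES)), CYP3A_ENZYMES)
  scaled_clint_by_pathway(compound, phys, enzyme_fold = fold)
}

#' Analytic steady state of the parent-metabolite system
#'
#' Closed-form steady state under a constant-rate parent infusion:
#' `Css_parent = rate / CL_H(parent)`; the metabolite formation rate is the
#' parent elimination rate times the CYP3A share of the parent's scaled
#' intrinsic clearance, mass-converted by the metabolite/parent molecular
#' weight ratio; `Css_metabolite = formation / CL_H(metabolite)`. Liver
#' concentrations are `Kp x` plasma.
#'
#' @param parent,metabolite [compound_params()] objects.
#' @param phys A [system_physiology()].
#' @param infusion_rate Parent infusion rate, mg/h.
#' @param cyp3a_fold Common activity fold applied to CYP3A4/5/7 pathways
#'   (induction > 1, inhibition < 1); CYP27A1/HLM are never scaled.
#' @return List with `css_parent` (mg/mL), `css_metabolite` (ng/mL),
#'   `liver_parent` (mg/mL), `liver_metabolite` (ng/mL), `cl_parent`,
#'   `cl_metabolite` (L/h), and `formation_share`.
#' @export
analytic_steady_state <- function(parent, metabolite, phys, infusion_rate,
                                  cyp3a_fold = 1) {
  check_positive(infusion_rate, "infusion_rate")
  by_p <- effective_clint(parent, phys, cyp3a_fold)
  by_m <- effective_clint(metabolite, phys, cyp3a_fold)
  if (sum(by_p) <= 0 || sum(by_m) <= 0) {
    stop("total scaled intrinsic clearance is zero", call. = FALSE)
  }
  cl_p <- forward_wellstirred(sum(by_p), phys$hepatic_blood_flow,
                              parent$fu_plasma, parent$blood_to_plasma)
  cl_m <- forward_wellstirred(sum(by_m), phys$hepatic_blood_flow,
                              metabolite$fu_plasma, metabolite$blood_to_plasma)
  share <- sum(by_p[names(by_p) %in% CYP3A_ENZYMES]) / sum(by_p)
  css_p_mgL <- infusion_rate / cl_p
  formation <- infusion_rate * share * metabolite$molecular_weight / parent$molecular_weight
  css_m_mgL <- formation / cl_m
  list(css_parent = css_p_mgL / 1000,
       css_metabolite = css_m_mgL * 1000,
       liver_parent = parent$kp_liver * css_p_mgL / 1000,
       liver_metabolite = metabolite$kp_liver * css_m_mgL * 1000,
       cl_parent = cl_p, cl_metabolite = cl_m, formation_share = share)
}

infusion_rate_fun <- function(regimens, body_weight) {
  regimens <- Filter(function(r) r$route == "iv_infusion", regimens)
  function(t) {
    rate <- 0
    for (r in regimens) {
      t0 <- r$start_day * 24
      if (t >= t0 && t < t0 + r$duration_days * 24) {
        rate <- rate + r$dose * body_weight / 24
      }
    }
    rate
  }
}

#' Simulate a virtual subject
#'
#' Integrates the coupled parent/metabolite/enzyme/perpetrator ODE system
#' for one subject. With a constant infusion and no perpetrator the terminal
#' concentrations match [analytic_steady_state()] (within integrator
#' tolerance); results are deterministic for a fixed subject.
#'
#' @param phys A [system_physiology()].
#' @param parent,metabolite [compound_params()] objects.
#' @param regimens List of [dose_regimen()]; `iv_infusion` entries drive the
#'   parent, `oral` entries dose the perpetrator.
#' @param perpetrator Optional list with `compound` ([compound_params()]),
#'   `interaction` ([interaction_spec()]) and `pk` (`ka` 1/h, `v` L, `cl`
#'   L/h), e.g. an entry of `default_model_config()$perpetrators`.
#' @param duration_days Simulated duration, days; must cover all regimens.
#' @param kdeg CYP3A degradation rate constant, 1/h (default 0.0193,
#'   ~36 h turnover half-life).
#' @param forced_cyp3a_fold Optional step function of CYP3A activity: a
#'   constant, or `list(fold =, from_day =)` applying the fold (as the
#'   turnover target) from a given day. Ignores the perpetrator.
#' @param init `"analytic"` warm-starts amounts at the baseline analytic
#'   steady state; `"zero"` starts empty.
#' @param dt_out Output resolution, h.
#' @param rtol,atol Integrator tolerances.
#' @return A `simulation_output` list: `time` (h), `plasma_parent` (mg/L),
#'   `plasma_metabolite` (ng/mL), `liver_parent`/`liver_metabolite` (via
#'   Kp), `enzyme_level`, `perpetrator_plasma` (mg/L), `css_parent` (mg/mL),
#'   `css_metabolite` (ng/mL) over the terminal steady-state window,
#'   `css_window` (h), and `balance` (cumulative mass accounting, mg).
#' @export
simulate_subject <- function(phys, parent, metabolite, regimens,
                             perpetrator = NULL, duration_days,
                             kdeg = 0.0193, forced_cyp3a_fold = NULL,
                             init = c("analytic", "zero"), dt_out = 24,
                             rtol = 1e-8, atol = 1e-10) {
  init <- match.arg(init)
  check_positive(duration_days, "duration_days")
  for (r in regimens) {
    if (r$start_day + r$duration_days > duration_days + 1e-9) {
      stop("simulation duration does not cover all regimens", call. = FALSE)
    }
  }
  t_end <- duration_days * 24
  rate_fun <- infusion_rate_fun(regimens, phys$body_weight)
  v_p <- parent$vss * phys$body_weight
  v_m <- metabolite$vss * phys$body_weight
  mw_ratio <- metabolite$molecular_weight / parent$molecular_weight
  by_p0 <- scaled_clint_by_pathway(parent, phys)
  by_m0 <- scaled_clint_by_pathway(metabolite, phys)
  is3a_p <- names(by_p0) %in% CYP3A_ENZYMES
  is3a_m <- names(by_m0) %in% CYP3A_ENZYMES

  forced <- NULL
  if (!is.null(forced_cyp3a_fold)) {
    forced <- if (is.list(forced_cyp3a_fold)) forced_cyp3a_fold
              else list(fold = forced_cyp3a_fold, from_day = 0)
    perpetrator <- NULL
  }
  has_perp <- !is.null(perpetrator)
  inh <- has_perp && perpetrator$interaction$mechanism == "competitive_inhibition"
  ind <- has_perp && perpetrator$interaction$mechanism == "induction"

  perp_conc_uM <- function(amount) {
    if (!has_perp) return(0)
    cp <- max(0, amount) / perpetrator$pk$v                          # mg/L
    cu <- perpetrator$compound$fu_plasma * perpetrator$compound$kp_liver * cp
    cu / perpetrator$compound$molecular_weight * 1000                # uM
  }

  rhs <- function(t, y, parms) {
    cu <- perp_conc_uM(y[["perp_c"]])
    signal <- 1
    if (ind) signal <- induction_fold(cu, perpetrator$interaction$ind_max,
                                      perpetrator$interaction$ind_c50)
    if (!is.null(forced) && t >= forced$from_day * 24) signal <- forced$fold
    e <- y[["enzyme"]]
    act <- e
    if (inh) act <- e / (1 + cu / perpetrator$interaction$ki)
    clint_p <- by_p0; clint_p[is3a_p] <- clint_p[is3a_p] * act
    clint_m <- by_m0; clint_m[is3a_m] <- clint_m[is3a_m] * act
    cl_p <- forward_wellstirred(sum(clint_p), phys$hepatic_blood_flow,
                                parent$fu_plasma, parent$blood_to_plasma)
    cl_m <- forward_wellstirred(sum(clint_m), phys$hepatic_blood_flow,
                                metabolite$fu_plasma, metabolite$blood_to_plasma)
    elim_p <- cl_p * y[["parent"]] / v_p
    elim_m <- cl_m * y[["metabolite"]] / v_m
    share <- if (sum(clint_p) > 0) sum(clint_p[is3a_p]) / sum(clint_p) else 0
    formation <- elim_p * share * mw_ratio
    rate_in <- rate_fun(t)
    dgut <- if (has_perp) -perpetrator$pk$ka * y[["perp_gut"]] else 0
    dperp <- if (has_perp) {
      perpetrator$pk$ka * y[["perp_gut"]] - perpetrator$pk$cl / perpetrator$pk$v * y[["perp_c"]]
    } else 0
    list(c(parent = rate_in - elim_p,
           metabolite = formation - elim_m,
           enzyme = enzyme_turnover_rhs(e, signal, kdeg),
           perp_gut = dgut, perp_c = dperp,
           cum_in = rate_in, cum_elim_p = elim_p,
           cum_formed = formation, cum_elim_m = elim_m))
  }

  y0 <- c(parent = 0, metabolite = 0, enzyme = 1, perp_gut = 0, perp_c = 0,
          cum_in = 0, cum_elim_p = 0, cum_formed = 0, cum_elim_m = 0)
  if (init == "analytic") {
    rate0 <- rate_fun(0)
    if (rate0 > 0) {
      ss <- analytic_steady_state(parent, metabolite, phys, rate0)
      y0[["parent"]] <- ss$css_parent * 1000 * v_p       # mg/mL -> mg/L -> mg
      y0[["metabolite"]] <- ss$css_metabolite / 1000 * v_m
    }
  }

  events <- NULL
  if (has_perp) {
    oral <- Filter(function(r) r$route == "oral", regimens)
    if (length(oral)) {
      times <- unlist(lapply(oral, function(r) {
        seq(r$start_day * 24, (r$start_day + r$duration_days) * 24 - 1e-6,
            by = r$interval)
      }))
      doses <- unlist(lapply(oral, function(r) {
        rep(r$dose, length(seq(r$start_day * 24,
                               (r$start_day + r$duration_days) * 24 - 1e-6,
                               by = r$interval)))
      }))
      events <- list(data = data.frame(var = "perp_gut", time = times,
                                       value = doses, method = "add"))
    }
  }

  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                        events = events)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge; istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  }
  sol <- as.data.frame(sol)

  plasma_p <- sol$parent / v_p                  # mg/L
  plasma_m <- sol$metabolite / v_m * 1000       # mg/L -> ng/mL (ug/mL x1000)
  window <- c(max(0, t_end - 30 * 24), t_end)
  in_win <- sol$time >= window[1]
  structure(list(
    time = sol$time,
    plasma_parent = plasma_p,
    plasma_metabolite = plasma_m,
    liver_parent = parent$kp_liver * plasma_p,
    liver_metabolite = metabolite$kp_liver * plasma_m,
    enzyme_level = sol$enzyme,
    perpetrator_plasma = if (has_perp) sol$perp_c / perpetrator$pk$v else rep(0, nrow(sol)),
    css_parent = mean(plasma_p[in_win]) / 1000,   # mg/mL
    css_metabolite = mean(plasma_m[in_win]),      # ng/mL
    css_window = window,
    balance = list(infused = utils::tail(sol$cum_in, 1),
                   parent_amount = utils::tail(sol$parent, 1) - sol$parent[1],
                   parent_eliminated = utils::tail(sol$cum_elim_p, 1),
                   metabolite_formed = utils::tail(sol$cum_formed, 1),
                   metabolite_amount = utils::tail(sol$metabolite, 1) - sol$metabolite[1],
                   metabolite_eliminated = utils::tail(sol$cum_elim_m, 1))),
    class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("<simulation_output> %d points over %.1f days\n",
              length(x$time), max(x$time) / 24))
  cat(sprintf("  Css parent %.4g mg/mL, Css metabolite %.4g ng/mL (window %.0f-%.0f h)\n",
              x$css_parent, x$css_metabolite, x$css_window[1], x$css_window[2]))
  invisible(x)
}

window_mean_metabolite <- function(output, window) {
  if (window[1] < min(output$time) - 1e-9 || window[2] > max(output$time) + 1e-9) {
    stop("window outside the simulated time range", call. = FALSE)
  }
  sel <- output$time >= window[1] & output$time <= window[2]
  mean(output$plasma_metabolite[sel])
}

#' Steady-state DDI ratio of two simulations
#'
#' Ratio of window-mean metabolite concentrations (perturbed / baseline).
#' Both outputs must come from the same subject; `window` (h) defaults to
#' each output's terminal steady-state window.
#'
#' @param output_baseline,output_perturbed `simulation_output` objects.
#' @param window Optional length-2 time window in h applied to both outputs;
#'   by default each output's own `css_window` is used.
#' @return Induced(or inhibited)/baseline metabolite Css ratio.
#' @export
ddi_ratio <- function(output_baseline, output_perturbed, window = NULL) {
  base <- window_mean_metabolite(output_baseline, window %||% output_baseline$css_window)
  pert <- window_mean_metabolite(output_perturbed, window %||% output_perturbed$css_window)
  pert / base
}

#' Apparent metabolite half-life after a perturbation
#'
#' Log-linear regression of the metabolite's mono-exponential approach to
#' its new steady state after `window_start`, returning the half-life of the
#' dominant eigen-phase in days.
#'
#' @param output A `simulation_output`.
#' @param window_start Start of the post-perturbation segment, h.
#' @return Apparent half-life, days.
#' @export
post_perturbation_halflife <- function(output, window_start) {
  sel <- output$time >= window_start
  t <- output$time[sel]
  conc <- output$plasma_metabolite[sel]
  if (length(conc) < 4) stop("too few points after window_start", call. = FALSE)
  d <- diff(conc)
  if (all(abs(d) < 1e-10 * max(abs(conc), 1e-12))) {
    stop("flat profile after window_start: no kinetic phase to fit", call. = FALSE)
  }
  # tolerate integrator-level wiggle near the plateau
  tol <- 1e-5 * diff(range(conc))
  if (!(all(d >= -tol) || all(d <= tol))) {
    stop("non-monotone segment after window_start", call. = FALSE)
  }
  # Aitken extrapolation of the asymptote from the last three points
  # (exact for a single surviving exponential; falls back to the terminal
  # value for a degenerate denominator)
  nlast <- length(conc)
  y1 <- conc[nlast - 2]; y2 <- conc[nlast - 1]; y3 <- conc[nlast]
  denom <- y1 + y3 - 2 * y2
  c_inf <- if (abs(denom) > 1e-12 * max(abs(conc))) {
    (y1 * y3 - y2^2) / denom
  } else y3
  gap <- abs(conc - c_inf)
  keep <- gap > 1e-3 * abs(conc[1] - c_inf)
  if (sum(keep) < 3) stop("segment already at steady state", call. = FALSE)
  fit <- stats::lm(log(gap[keep]) ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("segment does not decay towards its terminal value", call. = FALSE)
  log(2) / (-slope) / 24
}
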