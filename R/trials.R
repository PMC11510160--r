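# Multi-trial virtual studies: baseline steady-state trials, paired DDI
# protocols, fm calibration against a baseline target, and deterministic
# sensitivity scans.

#' Define a virtual trial set
#'
#' @param n_trials,n_subjects Number of trials and subjects per trial (>= 1).
#' @param template A [population_template()].
#' @param regimens List of [dose_regimen()]; the `iv_infusion` entry drives
#'   the endogenous parent.
#' @param baseline_days Baseline phase length, days (default 700: slow
#'   4beta-OHC kinetics need long runs to stabilize).
#' @param perpetrator_days Perpetrator phase length, days (DDI protocols).
#' @param seed Integer seed governing all sampling.
#' @return A `trial_design`.
#' @export
trial_design <- function(n_trials, n_subjects, template = population_template(),
                         regimens = list(dose_regimen("cholesterol", "iv_infusion",
                                                      1.73, duration_days = 700)),
                         baseline_days = 700, perpetrator_days = 0, seed = 1) {
  stopifnot(n_trials >= 1, n_subjects >= 1, baseline_days >= 1)
  structure(list(n_trials = n_trials, n_subjects = n_subjects,
                 template = template, regimens = regimens,
                 baseline_days = baseline_days,
                 perpetrator_days = perpetrator_days, seed = seed),
            class = "trial_design")
}

subject_infusion_rate <- function(design, phys) {
  iv <- Filter(function(r) r$route == "iv_infusion", design$regimens)
  if (!length(iv)) stop("design has no iv_infusion regimen", call. = FALSE)
  iv[[1]]$dose * phys$body_weight / 24
}

subject_css <- function(design, phys, parent, metabolite, method, cyp3a_fold = 1) {
  rate <- subject_infusion_rate(design, phys)
  if (method == "analytic") {
    ss <- analytic_steady_state(parent, metabolite, phys, rate, cyp3a_fold)
    c(css_parent = ss$css_parent, css_metabolite = ss$css_metabolite)
  } else {
    sim <- simulate_subject(phys, parent, metabolite, design$regimens,
                            duration_days = design$baseline_days,
                            forced_cyp3a_fold = if (cyp3a_fold != 1) cyp3a_fold else NULL,
                            init = "zero")
    c(css_parent = sim$css_parent, css_metabolite = sim$css_metabolite)
  }
}

#' Run a set of baseline virtual trials
#'
#' Samples `n_subjects` individuals per trial from the design template
#' (trial `i` uses seed `seed + i`, so results are reproducible and paired
#' across designs sharing a seed), computes each subject's steady-state
#' plasma concentrations, and aggregates per-trial and population summaries.
#'
#' @param design A [trial_design()].
#' @param parent,metabolite [compound_params()]; default from
#'   [default_model_config()].
#' @param method `"analytic"` (closed-form steady state, default) or
#'   `"ode"` (full integration; agrees within integrator tolerance).
#' @param cyp3a_fold Constant CYP3A activity fold applied to every subject.
#' @return A `trial_summary` with `subjects` (per-subject tibble-like
#'   data.frame), `per_trial`, `mean_css_parent`, `sd_css_parent`,
#'   `mean_css_metabolite`, `sd_css_metabolite` and 5th/95th percentiles of
#'   subject-level metabolite Css.
#' @export
run_trial_set <- function(design, parent = NULL, metabolite = NULL,
                          method = c("analytic", "ode"), cyp3a_fold = 1) {
  method <- match.arg(method)
  if (is.null(parent) || is.null(metabolite)) {
    cfg <- default_model_config()
    parent <- parent %||% cfg$compounds[["cholesterol"]]
    metabolite <- metabolite %||% cfg$compounds[["4b-hydroxycholesterol"]]
  }
  rows <- list()
  for (trial in seq_len(design$n_trials)) {
    subjects <- sample_population(design$template, design$n_subjects,
                                  seed = design$seed + trial)
    for (i in seq_along(subjects)) {
      css <- tryCatch(
        subject_css(design, subjects[[i]], parent, metabolite, method, cyp3a_fold),
        error = function(e) {
          stop(sprintf("trial %d subject %d: %s", trial, i, conditionMessage(e)),
               call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        trial = trial, subject = i, sex = subjects[[i]]$sex,
        css_parent = unname(css["css_parent"]),
        css_metabolite = unname(css["css_metabolite"]))
    }
  }
  subjects_df <- do.call(rbind, rows)
  per_trial <- do.call(rbind, lapply(split(subjects_df, subjects_df$trial), function(d) {
    data.frame(trial = d$trial[1],
               mean_css_parent = mean(d$css_parent), sd_css_parent = stats::sd(d$css_parent),
               mean_css_metabolite = mean(d$css_metabolite),
               sd_css_metabolite = stats::sd(d$css_metabolite))
  }))
  q <- stats::quantile(subjects_df$css_metabolite, c(0.05, 0.95), names = FALSE)
  structure(list(subjects = subjects_df, per_trial = per_trial,
                 mean_css_parent = mean(subjects_df$css_parent),
                 sd_css_parent = stats::sd(subjects_df$css_parent),
                 mean_css_metabolite = mean(subjects_df$css_metabolite),
                 sd_css_metabolite = stats::sd(subjects_df$css_metabolite),
                 p5_css_metabolite = q[1], p95_css_metabolite = q[2],
                 design = design),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %d trials x %d subjects\n",
              x$design$n_trials, x$design$n_subjects))
  cat(sprintf("  Css parent %.4g (SD %.2g) mg/mL; Css 4b-OHC %.4g (SD %.2g) ng/mL [P5 %.3g, P95 %.3g]\n",
              x$mean_css_parent, x$sd_css_parent, x$mean_css_metabolite,
              x$sd_css_metabolite, x$p5_css_metabolite, x$p95_css_metabolite))
  invisible(x)
}

#' Paired baseline/perturbed DDI protocol
#'
#' Runs, for every sampled subject, a baseline simulation and a simulation
#' with the perpetrator phase appended after the baseline steady state, and
#' returns the per-subject and mean induced/baseline metabolite Css ratios.
#' Paired sampling makes the ratio nearly independent of each subject's
#' absolute abundance scale.
#'
#' @param design A [trial_design()] with `perpetrator_days > 0`.
#' @param perpetrator List with `compound`, `interaction`, `pk` (see
#'   [simulate_subject()]), or `forced_fold` (a number) to impose a constant
#'   CYP3A activity fold during the perpetrator phase instead.
#' @param perp_regimen Optional oral [dose_regimen()] for the perpetrator;
#'   defaults to daily dosing of `perp_dose` mg starting at
#'   `baseline_days`. Must not overlap the baseline window.
#' @param perp_dose Daily perpetrator dose, mg (default 600).
#' @param parent,metabolite [compound_params()]; default bundled compounds.
#' @return List with `ratios` (per-subject data.frame), `mean_ratio`,
#'   `baseline_summary` and `induced_summary` population means.
#' @export
ddi_protocol <- function(design, perpetrator, perp_regimen = NULL,
                         perp_dose = 600, parent = NULL, metabolite = NULL) {
  if (design$perpetrator_days < 1) {
    stop("design$perpetrator_days must be >= 1 for a DDI protocol", call. = FALSE)
  }
  if (is.null(parent) || is.null(metabolite)) {
    cfg <- default_model_config()
    parent <- parent %||% cfg$compounds[["cholesterol"]]
    metabolite <- metabolite %||% cfg$compounds[["4b-hydroxycholesterol"]]
  }
  forced <- !is.null(perpetrator$forced_fold)
  if (!forced && is.null(perp_regimen)) {
    perp_regimen <- dose_regimen(perpetrator$compound$name, "oral", perp_dose,
                                 interval = 24, start_day = design$baseline_days,
                                 duration_days = design$perpetrator_days)
  }
  if (!forced && perp_regimen$start_day < design$baseline_days) {
    stop("perpetrator exposure overlaps the baseline steady-state window",
         call. = FALSE)
  }
  total_days <- design$baseline_days + design$perpetrator_days
  base_reg <- list(dose_regimen(parent$name, "iv_infusion",
                                design$regimens[[1]]$dose,
                                duration_days = total_days))
  rows <- list()
  for (trial in seq_len(design$n_trials)) {
    subjects <- sample_population(design$template, design$n_subjects,
                                  seed = design$seed + trial)
    for (i in seq_along(subjects)) {
      phys <- subjects[[i]]
      base <- simulate_subject(phys, parent, metabolite, base_reg,
                               duration_days = total_days, init = "analytic")
      pert <- if (forced) {
        simulate_subject(phys, parent, metabolite, base_reg,
                         duration_days = total_days,
                         forced_cyp3a_fold = list(fold = perpetrator$forced_fold,
                                                  from_day = design$baseline_days),
                         init = "analytic")
      } else {
        simulate_subject(phys, parent, metabolite, c(base_reg, list(perp_regimen)),
                         perpetrator = perpetrator,
                         duration_days = total_days, init = "analytic")
      }
      base_win <- c((design$baseline_days - 30) * 24, design$baseline_days * 24)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = trial, subject = i,
        css_baseline = window_mean_metabolite(pert, base_win),
        css_induced = pert$css_metabolite,
        ratio = pert$css_metabolite / window_mean_metabolite(pert, base_win),
        check_baseline = base$css_metabolite)
    }
  }
  ratios <- do.call(rbind, rows)
  list(ratios = ratios, mean_ratio = mean(ratios$ratio),
       baseline_summary = mean(ratios$css_baseline),
       induced_summary = mean(ratios$css_induced))
}

# Rebalance the parent compound for a candidate CYP3A4 CLint: siblings tied
# by their in vitro percentages and the HLM pathway adjusted so the total
# scaled CLint at the reference physiology is preserved.
rebalanced_parent <- function(parent, clint_3a4, phys, pct_3a5 = 5.6, pct_3a7 = 2.8) {
  sib <- sibling_isoform_clint(clint_3a4, pct_3a5, pct_3a7)
  total0 <- sum(scaled_clint_by_pathway(parent, phys))
  parent$pathways[["CYP3A4"]]$clint <- clint_3a4
  parent$pathways[["CYP3A5"]]$clint <- sib$clint_3a5
  parent$pathways[["CYP3A7"]]$clint <- sib$clint_3a7
  by <- scaled_clint_by_pathway(parent, phys)
  other <- sum(by[names(by) != "HLM"])
  hlm_scaled <- total0 - other
  if (hlm_scaled <= 0) {
    stop("candidate CYP3A4 CLint exceeds the total hepatic clearance budget",
         call. = FALSE)
  }
  parent$pathways[["HLM"]]$clint <- per_mg_intrinsic(hlm_scaled, phys)
  parent
}

#' Calibrate the CYP3A4 intrinsic clearance to a baseline target
#'
#' One-dimensional root search over the parent CYP3A4 CLint such that the
#' simulated mean-individual baseline metabolite Css matches `target_css`.
#' CYP3A5/CYP3A7 are tied by their in vitro percentage contributions and the
#' HLM pathway is rebalanced so the parent's total CLmet,H is preserved
#' (baseline metabolite Css is then strictly increasing in the CYP3A4 CLint,
#' so bisection is valid).
#'
#' @param target_css Target baseline metabolite Css, ng/mL (> 0).
#' @param design A [trial_design()] (supplies the infusion regimen).
#' @param parent,metabolite [compound_params()]; default bundled compounds.
#' @param phys Reference physiology for the mean individual.
#' @param bracket Length-2 search bracket on the CYP3A4 CLint, uL/min/pmol.
#' @param check_fold Optional CYP3A activity fold at which to report the
#'   implied steady-state DDI ratio of the calibrated model.
#' @param tol Relative tolerance on the matched Css.
#' @return List with `clint_3a4`, `clint_3a5`, `clint_3a7`, `clint_hlm`,
#'   `fm_map` (back-calculated fractions), `achieved_css` and, if requested,
#'   `ddi_ratio_at_fold`.
#' @export
calibrate_fm_cyp3a <- function(target_css, design, parent = NULL, metabolite = NULL,
                               phys = default_physiology(),
                               bracket = c(1e-9, 1e-4), check_fold = NULL,
                               tol = 1e-6) {
  check_positive(target_css, "target_css")
  if (is.null(parent) || is.null(metabolite)) {
    cfg <- default_model_config()
    parent <- parent %||% cfg$compounds[["cholesterol"]]
    metabolite <- metabolite %||% cfg$compounds[["4b-hydroxycholesterol"]]
  }
  rate <- subject_infusion_rate(design, phys)
  css_at <- function(clint_3a4) {
    p <- rebalanced_parent(parent, clint_3a4, phys)
    analytic_steady_state(p, metabolite, phys, rate)$css_metabolite
  }
  f <- function(log10x) css_at(10^log10x) - target_css
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    grid <- seq(lo, hi, length.out = 25)
    diag <- data.frame(clint_3a4 = 10^grid,
                       css = vapply(grid, function(g) f(g) + target_css, numeric(1)))
    cond <- simpleError("target Css not bracketed by the CYP3A4 CLint search interval")
    cond$diagnostic <- diag
    stop(cond)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  clint_3a4 <- 10^root
  p <- rebalanced_parent(parent, clint_3a4, phys)
  by <- scaled_clint_by_pathway(p, phys)
  fm_map <- by / sum(by)
  out <- list(clint_3a4 = clint_3a4,
              clint_3a5 = p$pathways[["CYP3A5"]]$clint,
              clint_3a7 = p$pathways[["CYP3A7"]]$clint,
              clint_hlm = p$pathways[["HLM"]]$clint,
              fm_map = fm_map,
              achieved_css = css_at(clint_3a4),
              parent = p)
  if (!is.null(check_fold)) {
    base <- analytic_steady_state(p, metabolite, phys, rate)$css_metabolite
    ind <- analytic_steady_state(p, metabolite, phys, rate,
                                 cyp3a_fold = check_fold)$css_metabolite
    out$ddi_ratio_at_fold <- ind / base
  }
  out
}

resolve_path <- function(obj, path) {
  for (p in path) {
    idx <- suppressWarnings(as.integer(p))
    key <- if (!is.na(idx)) idx else p
    if (is.na(idx) && (!is.list(obj) && !is.numeric(obj) || !(p %in% names(obj)))) {
      stop(sprintf("cannot resolve parameter path element '%s'", p), call. = FALSE)
    }
    obj <- obj[[key]]
  }
  obj
}

assign_path <- function(obj, path, value) {
  p <- path[1]
  idx <- suppressWarnings(as.integer(p))
  key <- if (!is.na(idx)) idx else p
  if (is.na(idx) && (!(p %in% names(obj)))) {
    stop(sprintf("cannot resolve parameter path element '%s'", p), call. = FALSE)
  }
  if (length(path) == 1L) obj[[key]] <- value
  else obj[[key]] <- assign_path(obj[[key]], path[-1], value)
  obj
}

#' Deterministic local sensitivity scan
#'
#' Evaluates the mean-individual steady state over a list of values for one
#' configuration parameter, addressed by a dotted path into the
#' `model_config` (e.g. `"physiology.abundances.CYP27A1"`,
#' `"regimens.1.dose"`, `"compounds.cholesterol.fu_plasma"`).
#'
#' @param config A `model_config`.
#' @param parameter Dotted parameter path.
#' @param values Numeric values to scan (an empty vector yields an empty
#'   table).
#' @return data.frame with `value`, `css_parent` (mg/mL),
#'   `css_metabolite` (ng/mL).
#' @export
sensitivity_scan <- function(config, parameter, values) {
  stopifnot(inherits(config, "model_config"))
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  resolve_path(config, path)   # errors early if unresolvable
  rows <- lapply(values, function(v) {
    cfg <- assign_path(config, path, v)
    phys <- cfg$physiology
    iv <- Filter(function(r) r$route == "iv_infusion", cfg$regimens)[[1]]
    rate <- iv$dose * phys$body_weight / 24
    ss <- analytic_steady_state(cfg$compounds[[1]], cfg$compounds[[2]], phys, rate)
    data.frame(value = v, css_parent = ss$css_parent,
               css_metabolite = ss$css_metabolite)
  })
  if (!length(rows)) {
    return(data.frame(value = numeric(), css_parent = numeric(),
                      css_metabolite = numeric()))
  }
  do.call(rbind, rows)
}
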