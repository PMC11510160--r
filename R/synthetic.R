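# Synthetic-data generators: literature-style study tables for the
# meta-analysis stage, noisy observed concentration profiles for the
# verification stage, and parameter-recovery fixtures for calibration.
# All generators are pure functions of (spec, seed); noise is multiplicative
# lognormal (concentrations are strictly positive and reported as mean/CV).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic study table
#'
#' Describes the generative model for a set of literature-style studies of
#' baseline plasma 4beta-OHC: per-study means scatter lognormally around a
#' true population mean with a between-study SD, and per-study SDs follow a
#' within-study CV. Optional strata apply multiplicative shifts (e.g. the
#' higher female baseline).
#'
#' @param n_studies Number of studies (default 38, the size of a typical
#'   literature meta-analysis of this biomarker).
#' @param n_range Per-study sample-size range (inclusive).
#' @param true_mean True population mean, ng/mL (default 29.85).
#' @param between_study_sd SD of study means, ng/mL.
#' @param within_study_cv Within-study CV (fraction, 0.5 = 50%).
#' @param strata Optional data.frame with columns `sex` (and/or
#'   `ethnicity`), `weight` (sampling probability) and `shift`
#'   (multiplicative mean shift).
#' @param seed Mandatory integer seed.
#' @return A `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_studies = 38, n_range = c(20, 200),
                                 true_mean = 29.85, between_study_sd = 4.5,
                                 within_study_cv = 0.5, strata = NULL,
                                 seed) {
  stopifnot(n_studies >= 1, !missing(seed))
  check_positive(true_mean, "true_mean")
  check_positive(between_study_sd, "between_study_sd", strict = FALSE)
  check_positive(within_study_cv, "within_study_cv", strict = FALSE)
  structure(list(n_studies = n_studies, n_range = n_range,
                 true_mean = true_mean, between_study_sd = between_study_sd,
                 within_study_cv = within_study_cv, strata = strata,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a literature-style study table
#'
#' @param spec A [synthetic_study_spec()].
#' @return data.frame of study records (`study_id`, `n`, `mean`, `sd`,
#'   `ethnicity`, `sex`) that validates against [study_record()] with no
#'   post-processing.
#' @export
gen_study_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_studies), function(i) {
      sex <- NA_character_; ethnicity <- NA_character_; shift <- 1
      if (!is.null(spec$strata)) {
        k <- sample(nrow(spec$strata), 1, prob = spec$strata$weight)
        shift <- spec$strata$shift[k]
        if ("sex" %in% names(spec$strata)) sex <- spec$strata$sex[k]
        if ("ethnicity" %in% names(spec$strata)) ethnicity <- spec$strata$ethnicity[k]
      }
      m <- spec$true_mean * shift
      cv_b <- spec$between_study_sd / spec$true_mean
      study_mean <- rlnorm_mean_cv(1, m, cv_b)
      sizes <- seq(spec$n_range[1], spec$n_range[2])
      n <- sizes[sample.int(length(sizes), 1)]
      study_record(sprintf("synthetic-%02d", i), n = n, mean = study_mean,
                   sd = study_mean * spec$within_study_cv,
                   ethnicity = ethnicity, sex = sex)
    })
    do.call(rbind, rows)
  })
}

#' Overlay observation noise on a simulated profile
#'
#' Samples the simulated metabolite profile at the requested times and
#' applies multiplicative lognormal noise with the given CV, emulating an
#' observed concentration-time table.
#'
#' @param simulation A `simulation_output` from [simulate_subject()].
#' @param noise_cv Observation CV, percent.
#' @param sampling_times Times, h; must lie within the simulated range.
#' @param seed Integer seed.
#' @return data.frame with `time_h`, `true_value`, `observed` (ng/mL).
#' @export
gen_observed_profiles <- function(simulation, noise_cv, sampling_times, seed) {
  stopifnot(inherits(simulation, "simulation_output"))
  check_positive(noise_cv, "noise_cv", strict = FALSE)
  if (!length(sampling_times)) {
    return(data.frame(time_h = numeric(), true_value = numeric(),
                      observed = numeric()))
  }
  if (min(sampling_times) < min(simulation$time) ||
      max(sampling_times) > max(simulation$time)) {
    stop("sampling times outside the simulated range", call. = FALSE)
  }
  truth <- stats::approx(simulation$time, simulation$plasma_metabolite,
                         xout = sampling_times)$y
  obs <- with_seed(seed, truth * rlnorm_mean_cv(length(truth), 1, noise_cv / 100))
  data.frame(time_h = sampling_times, true_value = truth, observed = obs)
}

#' Parameter-recovery fixture for the fm calibration
#'
#' Generates a synthetic "observed" baseline (and induced) metabolite Css
#' from a hidden true CYP3A4 CLint, for round-trip testing of
#' [calibrate_fm_cyp3a()].
#'
#' @param true_clint_3a4 Hidden truth, uL/min/pmol.
#' @param design A [trial_design()].
#' @param seed Integer seed for the observation noise.
#' @param noise_cv Observation CV, percent (0 for a noise-free fixture).
#' @param check_fold CYP3A activity fold used for the induced observation.
#' @param phys Reference physiology.
#' @return List with `observed` (`css_baseline`, `ddi_ratio`, both noisy)
#'   and `truth` (the generating parameters).
#' @export
recovery_fixture <- function(true_clint_3a4, design, seed, noise_cv = 10,
                             check_fold = 10, phys = default_physiology()) {
  check_positive(true_clint_3a4, "true_clint_3a4")
  cfg <- default_model_config()
  parent <- rebalanced_parent(cfg$compounds[["cholesterol"]], true_clint_3a4, phys)
  metabolite <- cfg$compounds[["4b-hydroxycholesterol"]]
  rate <- subject_infusion_rate(design, phys)
  base <- analytic_steady_state(parent, metabolite, phys, rate)$css_metabolite
  ind <- analytic_steady_state(parent, metabolite, phys, rate,
                               cyp3a_fold = check_fold)$css_metabolite
  noisy <- with_seed(seed, c(base, ind) * rlnorm_mean_cv(2, 1, noise_cv / 100))
  list(observed = list(css_baseline = noisy[1], ddi_ratio = noisy[2] / noisy[1],
                       check_fold = check_fold),
       truth = list(clint_3a4 = true_clint_3a4, css_baseline = base,
                    ddi_ratio = ind / base))
}
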