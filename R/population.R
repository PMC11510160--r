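# Virtual population templates and individual sampling. Templates are thin
# data records (means, CVs, frequencies); abundances and size scalars are
# sampled lognormally (strictly positive, conventional for enzyme
# abundances), parameterized by arithmetic mean and CV.

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

dist_spec <- function(mean, cv) {
  check_positive(mean, "mean")
  check_positive(cv, "cv", strict = FALSE)
  list(mean = mean, cv = cv)
}

#' Build a population template
#'
#' Distributions and frequencies from which virtual individuals are drawn.
#' Defaults describe a healthy Caucasian-like adult population: CYP3A4
#' abundance 137 pmol/mg with 41% CV, CYP27A1 41.93 pmol/mg, a 24% higher
#' female CYP3A4 mean, and a CYP3A5 poor-metabolizer-dominated phenotype mix
#' (extensive-metabolizer fraction 0.17).
#'
#' @param name Template label.
#' @param age_range Length-2 years.
#' @param prop_female Fraction of females in \[0, 1\].
#' @param weight,liver_weight,mppgl,q_h `list(mean =, cv =)` lognormal
#'   specifications (kg, g, mg/g, L/h).
#' @param abundances Named list of `list(mean =, cv =)` per enzyme,
#'   pmol/mg; CV in fractional units (0.41 = 41%).
#' @param female_cyp3a4_multiplier Multiplicative shift of the female CYP3A4
#'   abundance mean (1.24 = +24%), applied before sampling.
#' @param cyp3a5_phenotype_freqs Named frequencies for `EM`, `IM`, `PM`
#'   (must sum to 1). PM individuals get ~zero CYP3A5, IM half the EM mean.
#' @param cardiac_output_multiplier,hematocrit_multiplier Disease modifiers
#'   applied to hepatic blood flow and hematocrit.
#' @param hematocrit Baseline hematocrit.
#' @return A `population_template`.
#' @export
population_template <- function(name = "healthy-caucasian",
                                age_range = c(20, 50), prop_female = 0.5,
                                weight = dist_spec(67.5, 0.15),
                                liver_weight = dist_spec(1737.11, 0.15),
                                mppgl = dist_spec(39.79, 0.30),
                                q_h = dist_spec(90, 0.15),
                                abundances = list(
                                  CYP3A4 = dist_spec(137, 0.41),
                                  CYP3A5 = dist_spec(102, 0.60),
                                  CYP3A7 = dist_spec(2, 0.41),
                                  CYP27A1 = dist_spec(41.93, 0)),
                                female_cyp3a4_multiplier = 1.24,
                                cyp3a5_phenotype_freqs = c(EM = 0.17, IM = 0, PM = 0.83),
                                cardiac_output_multiplier = 1,
                                hematocrit_multiplier = 1,
                                hematocrit = 0.45) {
  if (prop_female < 0 || prop_female > 1) stop_field("prop_female", "must be in [0, 1]")
  if (abs(sum(cyp3a5_phenotype_freqs) - 1) > 1e-9) {
    stop_field("cyp3a5_phenotype_freqs", "must sum to 1")
  }
  if (any(cyp3a5_phenotype_freqs < 0)) {
    stop_field("cyp3a5_phenotype_freqs", "must be >= 0")
  }
  freqs <- c(EM = 0, IM = 0, PM = 0)
  freqs[names(cyp3a5_phenotype_freqs)] <- cyp3a5_phenotype_freqs
  structure(list(name = name, age_range = age_range, prop_female = prop_female,
                 weight = weight, liver_weight = liver_weight, mppgl = mppgl,
                 q_h = q_h, abundances = abundances,
                 female_cyp3a4_multiplier = female_cyp3a4_multiplier,
                 cyp3a5_phenotype_freqs = freqs,
                 cardiac_output_multiplier = cardiac_output_multiplier,
                 hematocrit_multiplier = hematocrit_multiplier,
                 hematocrit = hematocrit),
            class = "population_template")
}

template_registry <- function() {
  list(
    "healthy-caucasian" = population_template(),
    "healthy-asian" = population_template(
      name = "healthy-asian",
      abundances = list(CYP3A4 = dist_spec(137 * 0.84, 0.41),
                        CYP3A5 = dist_spec(102, 0.60),
                        CYP3A7 = dist_spec(2, 0.41),
                        CYP27A1 = dist_spec(41.93, 0)),
      cyp3a5_phenotype_freqs = c(EM = 0.48, IM = 0, PM = 0.52)))
}

#' Derive a genotype-, disease- or sex-specific template
#'
#' Starting from a registered base template, applies documented overrides:
#' `genotype = "cyp3a4_1_22"` sets the CYP3A4 abundance mean to 100.86
#' pmol/mg and `"cyp3a4_22_22"` to 51.27 pmol/mg (CV 41% retained);
#' `disease = "ra"` (rheumatoid arthritis) sets the CYP3A4 mean to 82.07
#' pmol/mg, cardiac output x1.05 and hematocrit x0.83.
#'
#' @param base Base template name (`"healthy-caucasian"`, `"healthy-asian"`)
#'   or a `population_template`.
#' @param genotype Optional `"cyp3a4_1_22"` or `"cyp3a4_22_22"`.
#' @param disease Optional `"ra"`.
#' @param prop_female Optional override of the female proportion.
#' @param cyp3a4_mean Optional direct override of the CYP3A4 abundance mean.
#' @return A derived `population_template`.
#' @export
make_template <- function(base = "healthy-caucasian", genotype = NULL,
                          disease = NULL, prop_female = NULL,
                          cyp3a4_mean = NULL) {
  tpl <- if (inherits(base, "population_template")) base else {
    reg <- template_registry()
    if (!base %in% names(reg)) {
      stop(sprintf("unknown base template '%s'", base), call. = FALSE)
    }
    reg[[base]]
  }
  if (!is.null(genotype) && !is.null(disease)) {
    stop("conflicting overrides: give either a genotype or a disease", call. = FALSE)
  }
  if (!is.null(genotype)) {
    genotype <- match.arg(genotype, c("cyp3a4_1_22", "cyp3a4_22_22"))
    tpl$abundances$CYP3A4$mean <- switch(genotype, cyp3a4_1_22 = 100.86,
                                         cyp3a4_22_22 = 51.27)
    tpl$name <- paste(tpl$name, genotype, sep = "/")
  }
  if (!is.null(disease)) {
    disease <- match.arg(disease, "ra")
    tpl$abundances$CYP3A4$mean <- 82.07
    tpl$cardiac_output_multiplier <- 1.05
    tpl$hematocrit_multiplier <- 0.83
    tpl$name <- paste(tpl$name, disease, sep = "/")
  }
  if (!is.null(cyp3a4_mean)) {
    check_positive(cyp3a4_mean, "cyp3a4_mean")
    tpl$abundances$CYP3A4$mean <- cyp3a4_mean
  }
  if (!is.null(prop_female)) {
    if (prop_female < 0 || prop_female > 1) stop_field("prop_female", "must be in [0, 1]")
    tpl$prop_female <- prop_female
  }
  tpl
}

#' Sample one virtual individual
#'
#' Draws sex, age, body size, liver scalars and enzyme abundances from the
#' template distributions using the current RNG state (seed the stream with
#' `set.seed()` or sample via [sample_population()] for reproducibility).
#' Females get the template's CYP3A4 mean multiplier; the CYP3A5 phenotype
#' is drawn from the template frequencies (PM -> ~0 abundance, IM -> half
#' the EM mean).
#'
#' @param template A [population_template()].
#' @return A [system_physiology()].
#' @export
sample_individual <- function(template) {
  stopifnot(inherits(template, "population_template"))
  sex <- if (stats::runif(1) < template$prop_female) "female" else "male"
  age <- stats::runif(1, template$age_range[1], template$age_range[2])
  w <- rlnorm_mean_cv(1, template$weight$mean, template$weight$cv)
  lw <- rlnorm_mean_cv(1, template$liver_weight$mean, template$liver_weight$cv)
  mp <- rlnorm_mean_cv(1, template$mppgl$mean, template$mppgl$cv)
  qh <- rlnorm_mean_cv(1, template$q_h$mean, template$q_h$cv) *
    template$cardiac_output_multiplier
  ab <- vapply(names(template$abundances), function(enz) {
    spec <- template$abundances[[enz]]
    m <- spec$mean
    if (enz == "CYP3A4" && sex == "female") m <- m * template$female_cyp3a4_multiplier
    if (enz == "CYP3A5") {
      ph <- sample(names(template$cyp3a5_phenotype_freqs), 1,
                   prob = template$cyp3a5_phenotype_freqs)
      m <- switch(ph, EM = m, IM = m / 2, PM = 0)
      if (m == 0) return(0)
    }
    rlnorm_mean_cv(1, m, spec$cv)
  }, numeric(1))
  system_physiology(body_weight = w, liver_weight = lw, mppgl = mp,
                    hepatic_blood_flow = qh,
                    hematocrit = min(0.99, template$hematocrit * template$hematocrit_multiplier),
                    sex = sex, age = age, abundances = ab)
}

#' Sample a reproducible roster of individuals
#'
#' @param template A [population_template()].
#' @param n Number of individuals.
#' @param seed Integer seed; the draw is a pure function of
#'   `(template, n, seed)`.
#' @return List of [system_physiology()] objects.
#' @export
sample_population <- function(template, n, seed) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) sample_individual(template))
}
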