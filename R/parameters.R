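# Domain types: compounds, pathways, physiology, regimens, interactions.
# Internal unit convention: time h, volume L, amount mg, enzyme amount pmol;
# intrinsic clearances are stored as given in vitro (uL/min/pmol or uL/min/mg)
# and scaled to whole-liver L/h with the 60/1e6 factor.

ENZYME_LABELS <- c("CYP3A4", "CYP3A5", "CYP3A7", "CYP27A1", "HLM")
CYP3A_ENZYMES <- c("CYP3A4", "CYP3A5", "CYP3A7")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict && x <= 0) stop_field(field, "must be > 0")
  if (!strict && x < 0) stop_field(field, "must be >= 0")
  x
}

#' One metabolic pathway of a compound
#'
#' A single elimination pathway: either a per-pmol intrinsic clearance
#' assigned to a named CYP enzyme, or a residual per-mg microsomal ("HLM")
#' clearance that absorbs pathways without abundance data (here CYP7A1).
#'
#' @param enzyme One of `"CYP3A4"`, `"CYP3A5"`, `"CYP3A7"`, `"CYP27A1"`,
#'   `"HLM"`.
#' @param clint Intrinsic clearance, uL/min/pmol for enzyme pathways or
#'   uL/min/mg microsomal protein for `"HLM"`. Non-negative.
#' @param basis `"per_pmol"` or `"per_mg"`; defaults from `enzyme` and must
#'   be `"per_mg"` exactly when `enzyme == "HLM"`.
#' @return A `pathway_clearance` object.
#' @export
pathway_clearance <- function(enzyme, clint,
                              basis = if (enzyme == "HLM") "per_mg" else "per_pmol") {
  enzyme <- match.arg(enzyme, ENZYME_LABELS)
  basis <- match.arg(basis, c("per_pmol", "per_mg"))
  check_positive(clint, "clint", strict = FALSE)
  if ((basis == "per_mg") != (enzyme == "HLM")) {
    stop_field("basis", "'per_mg' is allowed for, and required by, the HLM pathway only")
  }
  structure(list(enzyme = enzyme, clint = clint, basis = basis),
            class = "pathway_clearance")
}

#' Compound parameters for one analyte
#'
#' Physicochemical, binding, distribution and per-pathway elimination
#' parameters of one analyte (cholesterol, 4beta-OHC, a probe or a
#' perpetrator).
#'
#' @param name Compound label.
#' @param molecular_weight g/mol.
#' @param logP Octanol-water log partition coefficient (record-keeping only).
#' @param blood_to_plasma Blood-to-plasma concentration ratio (B/P), > 0.
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param vss Steady-state volume of distribution, L/kg.
#' @param kp_liver Liver-to-plasma partition coefficient.
#' @param binding_protein Text label of the reference binding protein.
#' @param pathways List of [pathway_clearance()] objects; enzyme labels must
#'   be unique.
#' @return A `compound_params` object.
#' @export
compound_params <- function(name, molecular_weight, logP = NA_real_,
                            blood_to_plasma, fu_plasma, vss, kp_liver = 1,
                            binding_protein = "", pathways = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive(molecular_weight, "molecular_weight")
  check_positive(blood_to_plasma, "blood_to_plasma")
  check_positive(fu_plasma, "fu_plasma")
  if (fu_plasma > 1) stop_field("fu_plasma", "must be <= 1")
  check_positive(vss, "vss")
  check_positive(kp_liver, "kp_liver")
  if (!is.list(pathways)) stop_field("pathways", "must be a list")
  pathways <- lapply(pathways, function(p) {
    if (inherits(p, "pathway_clearance")) p else do.call(pathway_clearance, p)
  })
  enz <- vapply(pathways, `[[`, "", "enzyme")
  if (anyDuplicated(enz)) {
    stop_field("pathways", "pathway enzyme labels must be unique within a compound")
  }
  names(pathways) <- enz
  structure(list(name = name, molecular_weight = molecular_weight, logP = logP,
                 blood_to_plasma = blood_to_plasma, fu_plasma = fu_plasma,
                 vss = vss, kp_liver = kp_liver,
                 binding_protein = binding_protein, pathways = pathways),
            class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> %s (MW %.2f g/mol)\n", x$name, x$molecular_weight))
  cat(sprintf("  B/P %.3g, fu_p %.3g, Vss %.3g L/kg, liver Kp %.3g\n",
              x$blood_to_plasma, x$fu_plasma, x$vss, x$kp_liver))
  for (p in x$pathways) {
    cat(sprintf("  %-8s CLint %.4g %s\n", p$enzyme, p$clint,
                if (p$basis == "per_mg") "uL/min/mg" else "uL/min/pmol"))
  }
  invisible(x)
}

#' One virtual individual's physiology
#'
#' System parameters of a single virtual subject used for in vitro-to-in vivo
#' scaling and the well-stirred liver model.
#'
#' @param body_weight kg.
#' @param liver_weight g.
#' @param mppgl mg microsomal protein per g liver (MPPGL).
#' @param hepatic_blood_flow L/h (Q_H).
#' @param hematocrit Fraction in (0, 1).
#' @param sex `"female"` or `"male"`.
#' @param age Years.
#' @param abundances Named numeric vector, enzyme -> pmol/mg microsomal
#'   protein (e.g. `c(CYP3A4 = 137, CYP27A1 = 41.93)`); all >= 0.
#' @return A `system_physiology` object.
#' @export
system_physiology <- function(body_weight, liver_weight, mppgl,
                              hepatic_blood_flow = 90, hematocrit = 0.45,
                              sex = "male", age = 35, abundances = numeric()) {
  check_positive(body_weight, "body_weight")
  check_positive(liver_weight, "liver_weight")
  check_positive(mppgl, "mppgl")
  check_positive(hepatic_blood_flow, "hepatic_blood_flow")
  check_positive(hematocrit, "hematocrit")
  if (hematocrit >= 1) stop_field("hematocrit", "must be in (0, 1)")
  sex <- match.arg(sex, c("male", "female"))
  check_positive(age, "age", strict = FALSE)
  if (length(abundances)) {
    if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
      stop_field("abundances", "must be a named numeric vector")
    }
    unknown <- setdiff(names(abundances), ENZYME_LABELS)
    if (length(unknown)) {
      stop_field("abundances", paste("unknown enzyme label:", paste(unknown, collapse = ", ")))
    }
    if (any(abundances < 0)) stop_field("abundances", "must be >= 0")
  }
  structure(list(body_weight = body_weight, liver_weight = liver_weight,
                 mppgl = mppgl, hepatic_blood_flow = hepatic_blood_flow,
                 hematocrit = hematocrit, sex = sex, age = age,
                 abundances = abundances),
            class = "system_physiology")
}

#' Reference healthy physiology
#'
#' Mean healthy-adult system parameters: liver weight 1737.11 g, MPPGL
#' 39.79 mg/g, hepatic blood flow 90 L/h, CYP3A4 abundance 137 and CYP27A1
#' abundance 41.93 pmol/mg microsomal protein. Body weight defaults to
#' 67.5 kg, the back-derived average subject weight of the half-life studies
#' behind the cholesterol clearance chain (use 63.5 kg for the 4beta-OHC
#' side); both are documented, overridable conventions.
#'
#' @param body_weight kg; default 67.5.
#' @param cyp3a5 CYP3A5 abundance pmol/mg; default 102 (extensive-metabolizer
#'   reference, a documented placeholder).
#' @param ... Passed on to [system_physiology()].
#' @return A `system_physiology` object.
#' @export
default_physiology <- function(body_weight = 67.5, cyp3a5 = 102, ...) {
  system_physiology(
    body_weight = body_weight, liver_weight = 1737.11, mppgl = 39.79,
    hepatic_blood_flow = 90,
    abundances = c(CYP3A4 = 137, CYP3A5 = cyp3a5, CYP3A7 = 2, CYP27A1 = 41.93),
    ...)
}

#' Dosing regimen
#'
#' @param compound Compound name the regimen applies to.
#' @param route `"iv_infusion"` (continuous, dose in mg/kg/day) or `"oral"`
#'   (dose in mg per administration).
#' @param dose Dose (> 0); units depend on `route`.
#' @param interval Dosing interval, h (oral route).
#' @param start_day Day the regimen starts (>= 0).
#' @param duration_days Days the regimen lasts (> 0).
#' @return A `dose_regimen` object.
#' @export
dose_regimen <- function(compound, route = c("iv_infusion", "oral"), dose,
                         interval = 24, start_day = 0, duration_days) {
  route <- match.arg(route)
  check_positive(dose, "dose")
  check_positive(interval, "interval")
  check_positive(start_day, "start_day", strict = FALSE)
  check_positive(duration_days, "duration_days")
  structure(list(compound = compound, route = route, dose = dose,
                 interval = interval, start_day = start_day,
                 duration_days = duration_days),
            class = "dose_regimen")
}

#' Perpetrator interaction mechanism
#'
#' Emax-type induction (`ind_max`, `ind_c50`) or competitive inhibition
#' (`ki`) acting on the listed enzymes. The rifampicin-like defaults carry
#' Ind_max = 16 and IndC50 = 0.32 uM.
#'
#' @param mechanism `"induction"` or `"competitive_inhibition"`.
#' @param ind_max Maximal fold induction (>= 1), induction only.
#' @param ind_c50 Unbound liver concentration at half-maximal induction, uM.
#' @param ki Competitive inhibition constant, uM; inhibition only.
#' @param target_enzymes Enzymes affected; defaults to the CYP3A family.
#' @return An `interaction_spec` object.
#' @export
interaction_spec <- function(mechanism = c("induction", "competitive_inhibition"),
                             ind_max = NULL, ind_c50 = NULL, ki = NULL,
                             target_enzymes = CYP3A_ENZYMES) {
  mechanism <- match.arg(mechanism)
  target_enzymes <- match.arg(target_enzymes, ENZYME_LABELS, several.ok = TRUE)
  if (mechanism == "induction") {
    check_positive(ind_max %||% NA_real_, "ind_max")
    if (ind_max < 1) stop_field("ind_max", "must be >= 1 for induction")
    check_positive(ind_c50 %||% NA_real_, "ind_c50")
    ki <- NULL
  } else {
    check_positive(ki %||% NA_real_, "ki")
    ind_max <- NULL; ind_c50 <- NULL
  }
  structure(list(mechanism = mechanism, ind_max = ind_max, ind_c50 = ind_c50,
                 ki = ki, target_enzymes = target_enzymes),
            class = "interaction_spec")
}

#' Scale an in vitro pathway clearance to whole-liver unbound clearance
#'
#' Converts a per-pmol (or per-mg) intrinsic clearance to the whole-liver
#' unbound intrinsic clearance in L/h:
#' `clint x liver_weight x MPPGL x abundance x 60/1e6` for per-pmol
#' pathways, dropping the abundance factor for the per-mg HLM pathway.
#'
#' @param pathway A [pathway_clearance()].
#' @param phys A [system_physiology()]; for per-pmol pathways its
#'   `abundances` must contain the pathway enzyme.
#' @param fold Optional activity multiplier (induction/inhibition), default 1.
#' @return Whole-liver unbound intrinsic clearance, L/h.
#' @export
scaled_liver_clint <- function(pathway, phys, fold = 1) {
  stopifnot(inherits(pathway, "pathway_clearance"),
            inherits(phys, "system_physiology"))
  protein_mg <- phys$liver_weight * phys$mppgl
  if (pathway$basis == "per_pmol") {
    ab <- phys$abundances[pathway$enzyme]
    if (is.na(ab)) {
      stop(sprintf("physiology has no abundance for enzyme '%s'", pathway$enzyme),
           call. = FALSE)
    }
    unname(pathway$clint * fold * protein_mg * ab * 60 / 1e6)
  } else {
    pathway$clint * fold * protein_mg * 60 / 1e6
  }
}

# Per-pathway whole-liver unbound CLint (named, L/h), with optional activity
# folds (named enzyme -> fold multiplier).
scaled_clint_by_pathway <- function(compound, phys, enzyme_fold = NULL) {
  vapply(compound$pathways, function(p) {
    f <- 1
    if (!is.null(enzyme_fold) && !is.na(enzyme_fold[p$enzyme])) {
      f <- unname(enzyme_fold[p$enzyme])
    }
    scaled_liver_clint(p, phys, fold = f)
  }, numeric(1))
}
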