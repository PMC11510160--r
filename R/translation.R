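# Reverse translation of in vivo clearances to per-enzyme intrinsic
# clearances through the well-stirred liver model, and the genotype
# retrograde abundance calculation.

#' Intravenous clearance from elimination half-life
#'
#' `CLiv = 0.693 x Vss x W / t_half`, the one-compartment relation between
#' terminal half-life and systemic clearance.
#'
#' @param t_half Elimination half-life, h.
#' @param vss Steady-state volume of distribution, L/kg.
#' @param weight Body weight, kg.
#' @return CLiv, L/h.
#' @export
cliv_from_halflife <- function(t_half, vss, weight) {
  check_positive(t_half, "t_half")
  check_positive(vss, "vss")
  check_positive(weight, "weight")
  0.693 * vss * weight / t_half
}

#' Invert the well-stirred liver model
#'
#' Recovers the total unbound hepatic metabolic intrinsic clearance CLmet,H
#' from an in vivo (plasma) clearance:
#' `CLmet,H = Q_H x CLiv / (fu_p x (Q_H - CLiv / (B/P)))`.
#' The inversion is physical only while the blood clearance `CLiv/(B/P)` is
#' below the hepatic blood flow.
#'
#' @param cliv In vivo clearance, L/h (plasma basis).
#' @param q_h Hepatic blood flow, L/h.
#' @param fu_plasma Fraction unbound in plasma.
#' @param blood_to_plasma Blood-to-plasma ratio.
#' @return CLmet,H, L/h.
#' @export
whole_liver_intrinsic_from_iv <- function(cliv, q_h, fu_plasma, blood_to_plasma) {
  check_positive(cliv, "cliv", strict = FALSE)
  check_positive(q_h, "q_h")
  check_positive(fu_plasma, "fu_plasma")
  check_positive(blood_to_plasma, "blood_to_plasma")
  if (cliv / blood_to_plasma >= q_h) {
    stop("blood clearance >= hepatic blood flow: well-stirred model not invertible",
         call. = FALSE)
  }
  q_h * cliv / (fu_plasma * (q_h - cliv / blood_to_plasma))
}

#' Forward well-stirred hepatic clearance
#'
#' `CL_H = Q_H x fu_p x CLint / (Q_H + fu_p x CLint / (B/P))` (plasma basis);
#' the exact inverse of [whole_liver_intrinsic_from_iv()].
#'
#' @param cl_uint_total Total unbound whole-liver intrinsic clearance, L/h.
#' @inheritParams whole_liver_intrinsic_from_iv
#' @return Hepatic plasma clearance, L/h.
#' @export
forward_wellstirred <- function(cl_uint_total, q_h, fu_plasma, blood_to_plasma) {
  check_positive(cl_uint_total, "cl_uint_total", strict = FALSE)
  check_positive(q_h, "q_h")
  check_positive(fu_plasma, "fu_plasma")
  check_positive(blood_to_plasma, "blood_to_plasma")
  q_h * fu_plasma * cl_uint_total /
    (q_h + fu_plasma * cl_uint_total / blood_to_plasma)
}

#' Pathway share of the hepatic metabolic clearance
#'
#' @param clmet_h Total hepatic metabolic intrinsic clearance, L/h.
#' @param fm Fraction metabolized by the pathway, in \[0, 1\].
#' @return Pathway clearance `fm x clmet_h`, L/h.
#' @export
split_pathway <- function(clmet_h, fm) {
  check_positive(clmet_h, "clmet_h", strict = FALSE)
  if (!is.numeric(fm) || is.na(fm) || fm < 0 || fm > 1) {
    stop_field("fm", "must be in [0, 1]")
  }
  fm * clmet_h
}

#' Per-pmol intrinsic clearance from a pathway clearance
#'
#' `CLint = CLmet,H,pathway / (liver_weight x MPPGL x abundance) x 1e6/60`.
#'
#' @param clmet_pathway Pathway whole-liver clearance, L/h.
#' @param phys A [system_physiology()] holding the enzyme abundance.
#' @param enzyme Enzyme label.
#' @return Intrinsic clearance, uL/min/pmol.
#' @export
per_enzyme_intrinsic <- function(clmet_pathway, phys, enzyme) {
  check_positive(clmet_pathway, "clmet_pathway", strict = FALSE)
  ab <- phys$abundances[enzyme]
  if (is.na(ab) || ab <= 0) {
    stop(sprintf("abundance for '%s' missing or zero", enzyme), call. = FALSE)
  }
  unname(clmet_pathway / (phys$liver_weight * phys$mppgl * ab) * 1e6 / 60)
}

#' Per-mg microsomal (HLM) intrinsic clearance
#'
#' `CLint = CL_HLM / (liver_weight x MPPGL) x 1e6/60`; the residual pathway
#' absorbing the fraction `1 - (fm_CYP27A1 + fm_CYP3A)`.
#'
#' @param cl_hlm Residual whole-liver clearance, L/h (>= 0).
#' @param phys A [system_physiology()].
#' @return Intrinsic clearance, uL/min/mg microsomal protein.
#' @export
per_mg_intrinsic <- function(cl_hlm, phys) {
  check_positive(cl_hlm, "cl_hlm", strict = FALSE)
  cl_hlm / (phys$liver_weight * phys$mppgl) * 1e6 / 60
}

#' Apportion a CYP3A-family clearance to CYP3A5 and CYP3A7
#'
#' Treats an optimized CYP3A4 intrinsic clearance as the CYP3A-family total
#' net of the sibling contributions: the family CLint is
#' `clint_3a4 / (1 - (pct_3a5 + pct_3a7)/100)` and each sibling receives its
#' percentage of that total (in vitro contributions 5.6% and 2.8%).
#'
#' @param clint_3a4 CYP3A4 intrinsic clearance, uL/min/pmol.
#' @param pct_3a5,pct_3a7 Percent contributions of CYP3A5 and CYP3A7;
#'   their sum must be < 100.
#' @return Named list `clint_3a_total`, `clint_3a5`, `clint_3a7`.
#' @export
sibling_isoform_clint <- function(clint_3a4, pct_3a5 = 5.6, pct_3a7 = 2.8) {
  check_positive(clint_3a4, "clint_3a4", strict = FALSE)
  check_positive(pct_3a5, "pct_3a5", strict = FALSE)
  check_positive(pct_3a7, "pct_3a7", strict = FALSE)
  if (pct_3a5 + pct_3a7 >= 100) {
    stop_field("pct_3a5 + pct_3a7", "must be < 100")
  }
  total <- clint_3a4 / (1 - (pct_3a5 + pct_3a7) / 100)
  list(clint_3a_total = total,
       clint_3a5 = total * pct_3a5 / 100,
       clint_3a7 = total * pct_3a7 / 100)
}

#' Back-calculate a fraction metabolized from an intrinsic clearance
#'
#' `fm = scaled whole-liver clearance / CLmet,H`.
#'
#' @param clint Intrinsic clearance, uL/min/pmol.
#' @param phys A [system_physiology()].
#' @param enzyme Enzyme label (abundance looked up in `phys`).
#' @param clmet_h Total hepatic metabolic intrinsic clearance, L/h.
#' @return Fraction metabolized, in \[0, 1\].
#' @export
fm_from_clint <- function(clint, phys, enzyme, clmet_h) {
  check_positive(clmet_h, "clmet_h")
  pw <- pathway_clearance(enzyme, clint)
  fm <- scaled_liver_clint(pw, phys) / clmet_h
  if (fm > 1 + 1e-9) {
    stop("back-calculated fm > 1: intrinsic clearance inconsistent with CLmet,H",
         call. = FALSE)
  }
  fm
}

#' Full reverse-translation chain for one compound
#'
#' Runs half-life -> CLiv -> CLmet,H -> per-pathway clearances -> in vitro
#' intrinsic clearances, attributing the residual fraction
#' `1 - sum(fm)` to the per-mg HLM pathway.
#'
#' @param t_half Elimination half-life, h.
#' @param vss L/kg.
#' @param weight Body weight, kg.
#' @param fu_plasma,blood_to_plasma Binding parameters.
#' @param fm_map Named fractions metabolized, e.g.
#'   `c(CYP27A1 = 0.27, CYP3A4 = 2.1e-5)`; must sum to <= 1.
#' @param phys A [system_physiology()]; also supplies `q_h`.
#' @return A `translation_result` list: `cliv`, `clmet_h`,
#'   `per_pathway_clmet` (L/h, incl. HLM) and `per_pathway_clint`
#'   (uL/min/pmol, HLM uL/min/mg).
#' @export
translate_compound <- function(t_half, vss, weight, fu_plasma, blood_to_plasma,
                               fm_map, phys = default_physiology()) {
  if (any(fm_map < 0) || any(fm_map > 1) || sum(fm_map) > 1 + 1e-9) {
    stop_field("fm_map", "fractions must lie in [0, 1] and sum to <= 1")
  }
  cliv <- cliv_from_halflife(t_half, vss, weight)
  clmet_h <- whole_liver_intrinsic_from_iv(cliv, phys$hepatic_blood_flow,
                                           fu_plasma, blood_to_plasma)
  fm_hlm <- 1 - sum(fm_map)
  clmet <- c(vapply(fm_map, split_pathway, numeric(1), clmet_h = clmet_h),
             HLM = split_pathway(clmet_h, fm_hlm))
  clint <- clmet
  for (enz in names(fm_map)) {
    clint[enz] <- per_enzyme_intrinsic(clmet[[enz]], phys, enz)
  }
  clint["HLM"] <- per_mg_intrinsic(clmet[["HLM"]], phys)
  structure(list(cliv = cliv, clmet_h = clmet_h,
                 per_pathway_clmet = clmet, per_pathway_clint = clint),
            class = "translation_result")
}

#' @export
print.translation_result <- function(x, ...) {
  cat(sprintf("<translation_result> CLiv %.4g L/h, CLmet,H %.4g L/h\n",
              x$cliv, x$clmet_h))
  for (enz in names(x$per_pathway_clint)) {
    unit <- if (enz == "HLM") "uL/min/mg" else "uL/min/pmol"
    cat(sprintf("  %-8s CLmet %.4g L/h   CLint %.4g %s\n",
                enz, x$per_pathway_clmet[[enz]], x$per_pathway_clint[[enz]], unit))
  }
  invisible(x)
}

#' Synthetic CYP3A probe substrate for retrograde calculations
#'
#' A midazolam-like probe (labelled synthetic: its parameters are not
#' literature values but were solved so the retrograde chain reproduces the
#' reference heterozygous/homozygous CYP3A4*22 abundances at 20%/50% hepatic
#' clearance reductions for the [default_physiology()] reference subject).
#' CYP3A5 carries 13.3% of the probe CLint and the baseline hepatic blood
#' extraction ratio is ~0.16.
#'
#' @return A `compound_params` probe with CYP3A4 and CYP3A5 pathways.
#' @export
synthetic_cyp3a_probe <- function() {
  compound_params(
    name = "synthetic-cyp3a-probe", molecular_weight = 325.8, logP = 3.9,
    blood_to_plasma = 0.66, fu_plasma = 0.032, vss = 1.0, kp_liver = 1,
    pathways = list(pathway_clearance("CYP3A4", 0.5278596),
                    pathway_clearance("CYP3A5", 0.1086512)))
}

#' Retrograde CYP3A4 abundance for a reduced-clearance genotype
#'
#' Given a probe substrate metabolized by CYP3A4 and CYP3A5, finds the CYP3A4
#' abundance at which the probe's well-stirred hepatic clearance drops by
#' `fractional_cl_reduction`, holding CYP3A5 abundance and all other scalars
#' fixed. Used to derive CYP3A4*1/*22 and *22/*22 population abundances from
#' clinical probe-clearance reductions.
#'
#' @param baseline_abundance Wild-type CYP3A4 abundance, pmol/mg.
#' @param fractional_cl_reduction Fractional reduction of the probe's hepatic
#'   clearance, in (0, 1).
#' @param probe A [compound_params()] with a CYP3A4 pathway (CYP3A5
#'   optional); defaults to [synthetic_cyp3a_probe()].
#' @param phys A [system_physiology()].
#' @return Reduced CYP3A4 abundance, pmol/mg (< `baseline_abundance`).
#' @export
genotype_retrograde_abundance <- function(baseline_abundance,
                                          fractional_cl_reduction,
                                          probe = synthetic_cyp3a_probe(),
                                          phys = default_physiology()) {
  check_positive(baseline_abundance, "baseline_abundance")
  r <- fractional_cl_reduction
  if (!is.numeric(r) || is.na(r) || r <= 0 || r >= 1) {
    stop_field("fractional_cl_reduction", "must be in (0, 1)")
  }
  if (!("CYP3A4" %in% names(probe$pathways))) {
    stop("probe must carry a CYP3A4 pathway", call. = FALSE)
  }
  phys$abundances["CYP3A4"] <- baseline_abundance
  by_path <- scaled_clint_by_pathway(probe, phys)
  cl0 <- forward_wellstirred(sum(by_path), phys$hepatic_blood_flow,
                             probe$fu_plasma, probe$blood_to_plasma)
  x1 <- whole_liver_intrinsic_from_iv((1 - r) * cl0, phys$hepatic_blood_flow,
                                      probe$fu_plasma, probe$blood_to_plasma)
  other <- sum(by_path[names(by_path) != "CYP3A4"])
  if (x1 <= other) {
    stop("CYP3A4's share of probe clearance is smaller than the requested reduction",
         call. = FALSE)
  }
  # scaled CYP3A4 CLint is linear in abundance
  baseline_abundance * (x1 - other) / by_path[["CYP3A4"]]
}
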