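# Reverse-translation chain: half-life -> CLiv -> CLmet,H -> per-pathway
# intrinsic clearances, the CYP3A sibling split, fm back-calculation, and
# the genotype retrograde abundance.

test_that("CLiv follows the half-life relation", {
  expect_equal(cliv_from_halflife(46.05 * 24, 0.1, 67.5),
               0.693 * 0.1 * 67.5 / (46.05 * 24), tolerance = 1e-12)
  expect_equal(cliv_from_halflife(46.05 * 24, 0.1, 67.5), 4.23e-3, tolerance = 1e-3)
  expect_equal(cliv_from_halflife(62, 0.05, 63.5), 3.55e-2, tolerance = 1e-3)
  expect_lt(cliv_from_halflife(1e9, 0.1, 67.5), 1e-8)
  expect_error(cliv_from_halflife(-1, 0.1, 67.5), "t_half")
})

test_that("well-stirred inversion recovers CLmet,H and respects flow limits", {
  cliv <- cliv_from_halflife(46.05 * 24, 0.1, 67.5)
  clmet <- whole_liver_intrinsic_from_iv(cliv, 90, 0.0021, 0.55)
  expect_equal(clmet, 2.016, tolerance = 1e-3)
  expect_identical(whole_liver_intrinsic_from_iv(0, 90, 0.0021, 0.55), 0)
  expect_error(whole_liver_intrinsic_from_iv(60, 90, 0.0021, 0.55),
               "not invertible")
  # low-extraction limit: CLmet,H ~ CLiv / fu
  expect_equal(clmet, cliv / 0.0021, tolerance = 1e-4)
})

test_that("forward well-stirred model is the exact inverse and is flow-limited", {
  cliv <- 4.23e-3
  clmet <- whole_liver_intrinsic_from_iv(cliv, 90, 0.0021, 0.55)
  expect_equal(forward_wellstirred(clmet, 90, 0.0021, 0.55), cliv,
               tolerance = 1e-12)
  expect_equal(forward_wellstirred(1e12, 90, 0.0021, 0.55), 90 * 0.55,
               tolerance = 1e-4)
  # property: round-trip holds across the physical input space
  set.seed(42)
  for (i in 1:50) {
    q <- runif(1, 60, 120); fu <- runif(1, 1e-4, 1); bp <- runif(1, 0.3, 2)
    x <- 10^runif(1, -3, 4)
    cl <- forward_wellstirred(x, q, fu, bp)
    expect_equal(whole_liver_intrinsic_from_iv(cl, q, fu, bp), x,
                 tolerance = 1e-9)
  }
})

test_that("pathway split and per-enzyme scaling reproduce the printed clearances", {
  clmet <- whole_liver_intrinsic_from_iv(cliv_from_halflife(46.05 * 24, 0.1, 67.5),
                                         90, 0.0021, 0.55)
  expect_equal(split_pathway(clmet, 0), 0)
  expect_equal(split_pathway(clmet, 1), clmet)
  expect_error(split_pathway(clmet, 1.1), "fm")
  cl27 <- split_pathway(clmet, 0.27)
  expect_equal(cl27, 0.544, tolerance = 1e-3)
  expect_equal(per_enzyme_intrinsic(cl27, phys_ref, "CYP27A1"), 3.13e-3,
               tolerance = 2e-3)
  cl3a4 <- split_pathway(clmet, 2.1e-5)
  expect_equal(per_enzyme_intrinsic(cl3a4, phys_ref, "CYP3A4"), 7.46e-8,
               tolerance = 2e-3)
  expect_equal(per_enzyme_intrinsic(0, phys_ref, "CYP27A1"), 0)
  expect_error(per_enzyme_intrinsic(1, system_physiology(70, 1700, 40), "CYP3A4"),
               "missing")
  # residual HLM pathway
  expect_equal(per_mg_intrinsic(split_pathway(clmet, 1 - 0.27 - 2.1e-5), phys_ref),
               0.355, tolerance = 2e-3)
  expect_equal(per_mg_intrinsic(0, phys_ref), 0)
})

test_that("4b-OHC chain reproduces its printed CYP27A1 and HLM clearances", {
  res <- translate_compound(62, 0.05, 63.5, 0.0051, 0.55, c(CYP27A1 = 0.5),
                            phys = default_physiology(body_weight = 63.5))
  expect_equal(res$per_pathway_clint[["CYP27A1"]], 0.02, tolerance = 2e-3)
  expect_equal(res$per_pathway_clint[["HLM"]], 0.84, tolerance = 1e-3)
})

test_that("sibling isoform split treats the optimized CLint as the family total", {
  sib <- sibling_isoform_clint(4.17e-7, 5.6, 2.8)
  expect_equal(sib$clint_3a5, 2.55e-8, tolerance = 5e-3)
  expect_equal(sib$clint_3a7, 1.27e-8, tolerance = 5e-3)
  expect_equal(sib$clint_3a_total, 4.17e-7 / 0.916, tolerance = 1e-12)
  zero <- sibling_isoform_clint(1e-7, 0, 0)
  expect_equal(zero$clint_3a_total, 1e-7)
  expect_equal(zero$clint_3a5, 0)
  expect_error(sibling_isoform_clint(1e-7, 60, 40), "< 100")
})

test_that("fm back-calculation inverts the pathway decomposition", {
  clmet <- whole_liver_intrinsic_from_iv(cliv_from_halflife(46.05 * 24, 0.1, 67.5),
                                         90, 0.0021, 0.55)
  expect_equal(fm_from_clint(4.17e-7, phys_ref, "CYP3A4", clmet), 1.17e-4,
               tolerance = 1e-2)
  expect_equal(fm_from_clint(0, phys_ref, "CYP3A4", clmet), 0)
  f <- 0.27
  clint <- per_enzyme_intrinsic(split_pathway(clmet, f), phys_ref, "CYP27A1")
  expect_equal(fm_from_clint(clint, phys_ref, "CYP27A1", clmet), f,
               tolerance = 1e-12)
  expect_error(fm_from_clint(1, phys_ref, "CYP27A1", clmet), "fm > 1")
})

test_that("translate_compound conserves mass and scales linearly with weight", {
  res <- translate_compound(46.05 * 24, 0.1, 67.5, 0.0021, 0.55,
                            c(CYP27A1 = 0.27, CYP3A4 = 2.1e-5))
  expect_equal(sum(res$per_pathway_clmet), res$clmet_h, tolerance = 1e-9)
  res2 <- translate_compound(46.05 * 24, 0.1, 2 * 67.5, 0.0021, 0.55,
                             c(CYP27A1 = 0.27, CYP3A4 = 2.1e-5))
  expect_equal(res2$cliv, 2 * res$cliv, tolerance = 1e-12)
  # low-extraction regime: translated clearances within 0.1% of weight-linear
  expect_equal(res2$per_pathway_clint[["CYP27A1"]],
               2 * res$per_pathway_clint[["CYP27A1"]], tolerance = 1e-3)
  expect_error(translate_compound(62, 0.05, 63.5, 0.0051, 0.55,
                                  c(CYP27A1 = 0.7, CYP3A4 = 0.4)),
               "fm_map")
})

test_that("genotype retrograde abundance recovers the reference genotype values", {
  expect_equal(genotype_retrograde_abundance(137, 0.20), 100.86, tolerance = 0.05)
  expect_equal(genotype_retrograde_abundance(137, 0.50), 51.27, tolerance = 0.05)
  # continuity: vanishing reduction returns the baseline
  expect_equal(genotype_retrograde_abundance(137, 1e-9), 137, tolerance = 1e-6)
  expect_error(genotype_retrograde_abundance(137, 0), "fractional_cl_reduction")
  # a probe out-metabolized by CYP3A5 cannot absorb a large reduction
  lopsided <- compound_params("probe", 300, blood_to_plasma = 0.66,
                              fu_plasma = 0.03, vss = 1,
                              pathways = list(pathway_clearance("CYP3A4", 1e-4),
                                              pathway_clearance("CYP3A5", 1)))
  expect_error(genotype_retrograde_abundance(137, 0.5, probe = lopsided),
               "smaller than the requested reduction")
})

test_that("retrograde reduces to the linear closed form for a pure-CYP3A4 probe", {
  # tiny clint => extraction << 1 => abundance scales as (1 - reduction)
  probe <- compound_params("probe", 300, blood_to_plasma = 0.66,
                           fu_plasma = 0.03, vss = 1,
                           pathways = list(pathway_clearance("CYP3A4", 1e-6)))
  expect_equal(genotype_retrograde_abundance(137, 0.3, probe = probe),
               137 * 0.7, tolerance = 1e-5)
})
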