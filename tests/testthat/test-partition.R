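test_that("binding strength <-> unbound fraction conversion", {
  expect_equal(binding_strength_from_unbound(0.5), 1)
  expect_equal(binding_strength_from_unbound(1), 0)
  expect_equal(binding_strength_from_unbound(0.015), 0.985 / 0.015,
               tolerance = 1e-12)
  expect_error(binding_strength_from_unbound(0), "infinite binding")
})

test_that("unbound fraction in a fluid scales binding by protein content", {
  cmp <- tcpy()
  pl <- plasma_fluid(7.8)
  sal <- saliva_fluid(8.9)
  # identity contract: evaluating in plasma returns the measured value
  expect_identical(unbound_fraction_in_fluid(cmp, pl, pl), 0.015)
  # protein-free fluid frees everything
  free <- fluid("water", 7, fraction_water = 1, fraction_protein = 0)
  expect_equal(unbound_fraction_in_fluid(cmp, free, pl), 1)
  # rat saliva: beta = 65.667 * 0.003/0.073 -> f_u ~ 0.270
  expect_equal(unbound_fraction_in_fluid(cmp, sal, pl),
               1 / (1 + (0.985 / 0.015) * 0.003 / 0.073),
               tolerance = 1e-12)
  # zero plasma protein with nonzero binding is a contradiction
  pl0 <- fluid("plasma0", 7.4, fraction_water = 1, fraction_protein = 0)
  expect_error(unbound_fraction_in_fluid(cmp, sal, pl0),
               "plasma fraction_protein is 0")
})

test_that("ion trapping: magnitude, direction, limits and reciprocity", {
  # equal pH on both sides -> no trapping
  expect_equal(unbound_trapping_ratio(generic_base(), saliva_fluid(7.4),
                                      plasma_fluid(7.4)), 1)
  # generic base accumulates in the more acidic human saliva
  expect_equal(unbound_trapping_ratio(generic_base(), saliva_fluid(6.7),
                                      plasma_fluid(7.4)),
               2.138955, tolerance = 1e-6)
  # weak acid, alkaline rat saliva: mild accumulation, damped by alpha
  expect_equal(unbound_trapping_ratio(tcpy(), saliva_fluid(8.9),
                                      plasma_fluid(7.8)),
               1.039147, tolerance = 1e-6)
  # alpha -> 1: ions as permeant as neutrals, no trapping at any pH pair
  perm <- compound("p", "acid", pKa = 5, logKow_neutral = 1, alpha = 1,
                   fraction_unbound_plasma = 0.5)
  expect_equal(unbound_trapping_ratio(perm, saliva_fluid(8.9),
                                      plasma_fluid(7.4)), 1)
  # alpha -> 0: classical pH-partition (Rasmussen) ratio within 1%
  for (pKa in c(4.55, 7)) {
    imp <- compound("i", "acid", pKa = pKa, logKow_neutral = 1,
                    alpha = 1e-9, fraction_unbound_plasma = 0.5)
    Rs <- 10^(8.9 - pKa); Rp <- 10^(7.4 - pKa)
    expect_equal(unbound_trapping_ratio(imp, saliva_fluid(8.9),
                                        plasma_fluid(7.4)),
                 (1 + Rs) / (1 + Rp), tolerance = 0.01)
  }
  # swapping the fluids inverts the ratio exactly
  for (cmp in list(tcpy(), generic_base())) {
    fwd <- unbound_trapping_ratio(cmp, saliva_fluid(8.9), plasma_fluid(7.4))
    rev <- unbound_trapping_ratio(cmp, plasma_fluid(7.4), saliva_fluid(8.9))
    expect_equal(fwd * rev, 1, tolerance = 1e-12)
  }
})

test_that("saliva:blood partition: identity, neutral reduction, TCPy", {
  # identical compositions and pH partition to exactly 1
  same <- species_physiology("same", plasma = plasma_fluid(7.4),
                             saliva = plasma_fluid(7.4))
  res <- saliva_blood_partition(generic_base(), same)
  expect_equal(res$p_sal_bl, 1, tolerance = 1e-12)
  # neutral compound into protein-free saliva reduces to f_u^p
  ntl <- compound("n", "neutral", logKow_neutral = 1,
                  fraction_unbound_plasma = 0.5)
  pf <- species_physiology(
    "pf", plasma = plasma_fluid(7.4),
    saliva = fluid("water", 6.7, fraction_water = 1, fraction_protein = 0))
  expect_equal(saliva_blood_partition(ntl, pf)$p_sal_bl, 0.5,
               tolerance = 1e-12)
  # TCPy under measured rat physiology: ~0.058, within the 0.04-0.06
  # in vivo ratio band
  res <- saliva_blood_partition(tcpy(), phys(7.8, 8.9, "rat"))
  expect_equal(res$p_sal_bl, 0.0576513, tolerance = 1e-5)
  expect_gte(res$p_sal_bl, 0.04)
  expect_lte(res$p_sal_bl, 0.06)
  expect_equal(res$f_u_saliva, 0.2703704, tolerance = 1e-6)
  expect_equal(res$trapping_ratio, 1.039147, tolerance = 1e-6)
})

test_that("partition matches the independent oracle over a property grid", {
  for (fu in c(0.1, 0.5, 0.9)) {
    for (pKa in c(4, 7, 10)) {
      for (cls in c("acid", "base", "neutral")) {
        cmp <- compound("g", cls, pKa = if (cls == "neutral") NULL else pKa,
                        logKow_neutral = 2, alpha = 0.001,
                        fraction_unbound_plasma = fu)
        got <- saliva_blood_partition(cmp, phys(7.4, 6.7))$p_sal_bl
        want <- oracle_partition(cls, pKa, 0.001, fu, 7.4, 6.7)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("partition rises with unbound fraction and with trapping pH", {
  # strictly increasing in fraction_unbound_plasma, all else fixed
  fu <- seq(0.05, 1, by = 0.05)
  p <- vapply(fu, function(f)
    saliva_blood_partition(generic_base(fu = f), phys(7.4, 6.7))$p_sal_bl,
    numeric(1))
  expect_true(all(diff(p) > 0))
  # weak acid: raising saliva pH above plasma pH never decreases P
  pHs <- seq(7.4, 9.4, by = 0.25)
  pa <- vapply(pHs, function(s)
    saliva_blood_partition(tcpy(), phys(7.4, s))$p_sal_bl, numeric(1))
  expect_true(all(diff(pa) >= 0))
  # weak base: lowering saliva pH below plasma pH never decreases P
  pHs <- seq(7.4, 5.4, by = -0.25)
  pb <- vapply(pHs, function(s)
    saliva_blood_partition(generic_base(), phys(7.4, s))$p_sal_bl,
    numeric(1))
  expect_true(all(diff(pb) >= 0))
})

test_that("species partition ratio: ~3x for pKa 7 base, ~1 off-range", {
  ratio <- species_partition_ratio(generic_base(), phys(7.4, 6.7, "human"),
                                   phys(7.4, 8.9, "rat"))
  expect_equal(ratio, 2.95217, tolerance = 1e-5)
  expect_gte(ratio, 2.7)
  expect_lte(ratio, 3.3)
  # identical physiologies -> 1
  expect_equal(species_partition_ratio(generic_base(), phys(7.4, 6.7),
                                       phys(7.4, 6.7)), 1)
  # pKa far below every fluid pH: species comparable (trapping -> 1)
  low <- generic_base(pKa = 4)
  expect_equal(species_partition_ratio(low, phys(7.4, 6.7, "human"),
                                       phys(7.4, 8.9, "rat")),
               1, tolerance = 0.01)
})

test_that("cellular term and option flags behave", {
  # fraction_cells > 0 adds a cellular contribution
  cmp <- generic_base()
  sal_cells <- fluid("saliva", 6.7, fraction_water = 0.9,
                     fraction_protein = 0.003, fraction_cells = 0.2)
  ph <- species_physiology("x", plasma = plasma_fluid(7.4),
                           saliva = sal_cells)
  res <- saliva_blood_partition(cmp, ph)
  expect_gt(res$diagnostics$cellular_term, 0)
  expect_equal(res$diagnostics$cellular_term /
                 res$diagnostics$interstitial_term, 0.2 / 0.8,
               tolerance = 1e-12)
  # water normalization multiplies by the water-fraction ratio
  base <- saliva_blood_partition(cmp, phys(7.4, 6.7))
  wn <- saliva_blood_partition(cmp, phys(7.4, 6.7),
                               water_normalization = TRUE)
  expect_equal(wn$p_sal_bl / base$p_sal_bl, 0.98 / 0.915,
               tolerance = 1e-12)
  # pH-reweighted binding changes the saliva unbound fraction only when on
  ib <- saliva_blood_partition(cmp, phys(7.4, 6.7),
                               ionization_binding = TRUE)
  expect_false(isTRUE(all.equal(ib$f_u_saliva, base$f_u_saliva)))
})
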