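test_that("electron counts follow the nuclear-charge and valence conventions", {
  expect_identical(electron_counts(c(C = 2, H = 2)), list(total = 14L, valence = 10L))
  expect_identical(electron_counts(c(H = 1)), list(total = 1L, valence = 1L))
  expect_identical(electron_counts(c(C = 8, H = 8)), list(total = 56L, valence = 40L))
  expect_error(electron_counts(c(C = 1, Xx = 2)), "Xx")
  expect_error(electron_counts(c(1, 2)), "named")
  expect_error(electron_counts(c(C = 1.5)), "integer")
})

test_that("all six built-in polymers reproduce the reference electron pairs", {
  expected <- list(
    PE = c(16, 12), PS = c(56, 40), P2VP = c(56, 40),
    PA = c(14, 10), PMMA = c(54, 40), PI = c(196, 138)
  )
  rs_expected <- c(PE = 1.75, PS = 1.66, P2VP = 1.66, PA = 1.62,
                   PMMA = 1.74, PI = 1.61)
  rho_expected <- c(PE = 0.93, PS = 1.06, P2VP = 1.15, PA = 1.36,
                    PMMA = 1.19, PI = 1.42)
  mats <- builtin_materials()
  expect_named(mats, names(expected))
  for (nm in names(expected)) {
    m <- mats[[nm]]
    expect_identical(c(m$total_electrons, m$valence_electrons),
                     as.integer(expected[[nm]]), label = nm)
    expect_identical(m$unique_rs, rs_expected[[nm]])
    expect_identical(m$density, rho_expected[[nm]])
  }
  # PMMA: corrected repeat unit, printed formula retained
  pmma <- builtin_materials("PMMA")
  expect_identical(pmma$composition, c(C = 5L, H = 8L, O = 2L))
  expect_match(pmma$formula_printed, "C8H8O2")
  expect_output(print(pmma), "54/40")
  expect_error(builtin_materials("teflon"), "unknown")
})

test_that("material() validates and derives bulk quantities", {
  expect_error(material("x", c(C = 1), density = 0), "positive")
  expect_error(material("x", c(C = 1), density = 1, total_electrons = 7),
               "expected 7")
  pe <- builtin_materials("PE")
  expect_equal(pe$molar_mass, 2 * 12.011 + 4 * 1.008, tolerance = 1e-12)
  # hand value for PE atomic density: 0.93 * 6.022e23 * 6 / 28.054 cm^-3
  n_atoms <- pe$density * pennstop_constants$avogadro *
    pe$atoms_per_monomer / pe$molar_mass
  expect_equal(n_atoms, 1.198e23, tolerance = 0.001)
})

test_that("Bragg-rule combination is the stoichiometric weighted mean", {
  E <- exp(seq(log(30), log(3000), length.out = 25))
  # single element: identity
  h <- elemental_scs("H", E, 5 * log(1 + E / 25) / (E / 25))
  one <- bragg_combine(list(h), c(H = 1))
  expect_equal(one$scs_per_atom, h$scs, tolerance = 1e-12)

  # constant tables 2 and 3, counts 1:1 -> per-atom 2.5 everywhere
  a <- elemental_scs("H", E, rep(2, length(E)))
  b <- elemental_scs("C", E, rep(3, length(E)))
  mix <- bragg_combine(list(a, b), c(H = 1, C = 1))
  expect_true(all(abs(mix$scs_per_atom - 2.5) < 1e-12))
  expect_equal(mix$scs_per_monomer, mix$scs_per_atom * 2, tolerance = 1e-12)

  # Bethe-like toy tables for C2H4 against direct closed-form evaluation
  f <- function(Z, E) Z * 15 * log(1 + E / (25 * Z)) / (E / (25 * Z))
  hT <- toy_elemental_scs("H"); cT <- toy_elemental_scs("C")
  comb <- bragg_combine(list(hT, cT), c(C = 2, H = 4),
                        energies_keV = exp(seq(log(25), log(4000), length.out = 30)))
  direct <- (2 * f(6, comb$energies_keV) + 4 * f(1, comb$energies_keV)) / 6
  expect_equal(comb$scs_per_atom, direct, tolerance = 0.005)

  # permutation invariance and linearity in one elemental table
  comb2 <- bragg_combine(list(cT, hT), c(H = 4, C = 2),
                         energies_keV = comb$energies_keV)
  expect_equal(comb2$scs_per_atom, comb$scs_per_atom, tolerance = 1e-12)
  c2 <- elemental_scs("C", cT$energies_keV, 2 * cT$scs)
  comb3 <- bragg_combine(list(hT, c2), c(C = 2, H = 4),
                         energies_keV = comb$energies_keV)
  expect_equal(comb3$scs_per_monomer - comb$scs_per_monomer,
               2 * stats::approx(log(cT$energies_keV), cT$scs,
                                 log(comb$energies_keV))$y,
               tolerance = 1e-9)

  expect_error(bragg_combine(list(hT), c(C = 2, H = 4)), "missing.*C")
  expect_error(bragg_combine(list(hT, cT), c(C = 1, H = 1),
                             energies_keV = c(1, 10)), "outside")
})

test_that("Bragg-rule mean excitation energy is the electron-weighted log mean", {
  expect_equal(bragg_mean_excitation(c(O = 3), c(O = 95)), 95, tolerance = 1e-12)
  # water with conventional elemental values lands near 75 eV
  expect_equal(bragg_mean_excitation(c(H = 2, O = 1), c(H = 19.2, O = 105.0)),
               exp((2 * log(19.2) + 8 * log(105)) / 10), tolerance = 1e-12)
  expect_equal(bragg_mean_excitation(c(H = 2, O = 1), c(H = 19.2, O = 105.0)),
               74.8, tolerance = 0.001)
  # equal elemental I -> that I, any stoichiometry
  expect_equal(bragg_mean_excitation(c(C = 7, N = 2), c(C = 70, N = 70)), 70,
               tolerance = 1e-12)
  # invariant under repeat-unit doubling
  I1 <- bragg_mean_excitation(c(C = 5, H = 8, O = 2),
                              c(C = 78, H = 19.2, O = 95))
  I2 <- bragg_mean_excitation(c(C = 10, H = 16, O = 4),
                              c(C = 78, H = 19.2, O = 95))
  expect_equal(I1, I2, tolerance = 1e-12)
  expect_gt(I1, 19.2); expect_lt(I1, 95)
  expect_error(bragg_mean_excitation(c(C = 1, H = 1), c(C = 78)), "missing.*H")
})

test_that("registry and elemental-table files round-trip", {
  mats <- builtin_materials()[c("PE", "PMMA")]
  p <- withr::local_tempfile(fileext = ".yaml")
  write_materials(mats, p)
  back <- read_materials(p)
  expect_identical(back$PMMA$composition, mats$PMMA$composition)
  expect_equal(back$PE$density, 0.93)
  expect_equal(back$PMMA$unique_rs, 1.74)

  t <- toy_elemental_scs("O")
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_elemental_scs(t, pt)
  back_t <- read_elemental_scs(pt, "O")
  expect_equal(back_t$scs, t$scs, tolerance = 1e-5)
})
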