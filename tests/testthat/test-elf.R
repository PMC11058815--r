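make_grid_elf <- function(values, energies = seq(5, 50, length.out = length(values))) {
  elf(energies, values)
}

test_that("elf constructor enforces grid and value invariants", {
  expect_s3_class(elf(1:10, rep(0.5, 10)), "elf")
  expect_error(elf(1:5, rep(1, 5)), "at least 8")
  expect_error(elf(c(1:9, 9), rep(1, 10)), "strictly increasing")
  expect_error(elf(0:9, rep(1, 10)), "positive")
  expect_error(elf(1:10, c(rep(1, 9), -0.1)), "non-negative")
  expect_error(elf(1:10, c(rep(1, 9), NaN)), "non-negative|finite")
})

test_that("ELF file I/O round-trips and rejects malformed rows", {
  x <- synth_elf(drude_set(0.5, 0.7, 0.1), 1, 100, n = 10)
  p <- withr::local_tempfile(fileext = ".txt")
  write_elf(x, p)
  y <- read_elf(p)
  expect_length(y$energies_eV, 10)
  expect_equal(y$values, x$values, tolerance = 1e-9)
  expect_equal(y$energies_eV, x$energies_eV, tolerance = 1e-9)

  # negative ELF cited with its line
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# hdr", sprintf("%g %g", 1:9, 0.1), "5.5 -0.1"), bad)
  expect_error(read_elf(bad), "negative ELF")
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(sprintf("%g %g", 1:9, 0.1), "8.5 oops"), bad2)
  expect_error(read_elf(bad2), "line 10")
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g %g", c(1:9, 9), 0.1), dup)
  expect_error(read_elf(dup), "duplicate")
  expect_error(read_elf("no/such/file.txt"), "not found")
  # unsorted input is sorted on read
  shuf <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g %g", c(5:9, 1:4), 0.1 * c(5:9, 1:4)), shuf)
  z <- read_elf(shuf)
  expect_equal(z$energies_eV, as.numeric(1:9))
})

test_that("synthetic Drude ELF peaks at the oscillator and decays in the tail", {
  w0 <- 0.8
  x <- synth_elf(drude_set(w0^2, w0, 0.01), 5, 80, n = 400)
  peak_ha <- ev_to_hartree(x$energies_eV[which.max(x$values)])
  step <- diff(ev_to_hartree(x$energies_eV))[which.max(x$values)]
  expect_lt(abs(peak_ha - w0), step)
  tail_vals <- x$values[x$energies_eV > hartree_to_ev(10 * w0)]
  expect_true(all(tail_vals < 1e-6))
  expect_error(synth_elf(drude_set(1, 1, 0.1), -1, 10), "omega_min")
})

test_that("numeric sum rules of Drude sets match closed forms within 1%", {
  sets <- list(
    drude_set(0.54, 0.735, 0.29),
    drude_set(c(0.3, 8), c(0.6, 9), c(0.2, 4)),
    drude_set(c(0.1, 0.4, 2), c(0.3, 1.1, 5), c(0.1, 0.5, 2))
  )
  for (osc in sets) {
    x <- synth_elf(osc, 0.005, 2e5, n = 6000)
    w <- ev_to_hartree(x$energies_eV)
    f_num <- pracma::trapz(w, w * x$values)
    s_num <- pracma::trapz(w, x$values / w)
    cf <- drude_sum_rules(osc)
    expect_equal(f_num, cf$f_sum, tolerance = 0.01)
    expect_equal(s_num, cf$screening_sum, tolerance = 0.01)
  }
  # unit-screening single oscillator: screening sum exactly pi/2
  expect_equal(drude_sum_rules(drude_set(0.64, 0.8, 0.05))$screening_sum,
               pi / 2, tolerance = 1e-12)
})

test_that("f-sum effective electron count recovers the constructed count", {
  ps <- builtin_materials("PS")
  # choose A so (pi/2) A / Omega_m^2 = 40 electrons per monomer
  n_mono_au <- ps$density * pennstop_constants$avogadro / ps$molar_mass *
    pennstop_constants$bohr_cm^3
  A <- 40 * (4 * pi * n_mono_au)   # f-sum: Z_eff = A / Omega_m^2
  x <- synth_elf(drude_set(A, 0.735, 0.3), 0.05, 5e4, n = 4000)
  z_top <- f_sum_effective_electrons(x, ps)
  expect_equal(z_top, 40, tolerance = 0.02)
  # ~0 at the grid bottom, monotone in omega_max
  expect_lt(f_sum_effective_electrons(x, ps, omega_max_eV = x$energies_eV[1]), 0.1)
  zs <- vapply(c(5, 20, 100, 1000), function(wm)
    f_sum_effective_electrons(x, ps, omega_max_eV = wm), numeric(1))
  expect_true(all(diff(zs) >= 0))
  expect_error(f_sum_effective_electrons(x, ps, omega_max_eV = 1e6), "outside")
})

test_that("mean excitation energy: delta limit, log-average and oracle", {
  w66 <- ev_to_hartree(66)
  narrow <- synth_elf(drude_set(w66^2, w66, 0.002 * w66), 30, 140,
                      n = 4000, spacing = "linear")
  expect_equal(mean_excitation_energy(narrow), 66, tolerance = 0.01)

  # two equal-f-sum narrow lines -> geometric mean of the centres
  wa <- ev_to_hartree(20); wb <- ev_to_hartree(200)
  two <- synth_elf(drude_set(c(1, 1), c(wa, wb), 0.002 * c(wa, wb)),
                   5, 1000, n = 40000)
  expect_equal(mean_excitation_energy(two), sqrt(20 * 200), tolerance = 0.01)

  # broad oscillator vs brute-force dense quadrature
  A <- ev_to_hartree(20)^2; w0 <- ev_to_hartree(20); g0 <- ev_to_hartree(10)
  broad <- synth_elf(drude_set(A, w0, g0), 0.01, 1e5, n = 8000)
  expect_equal(mean_excitation_energy(broad),
               oracle_drude_I_eV(A, w0, g0), tolerance = 0.005)

  # scale invariance and bounds
  x <- polymer_like_elf()
  xs <- elf(x$energies_eV, 0.37 * x$values)
  expect_equal(mean_excitation_energy(xs), mean_excitation_energy(x),
               tolerance = 1e-9)
  I <- mean_excitation_energy(x)
  expect_gt(I, min(x$energies_eV)); expect_lt(I, max(x$energies_eV))
  expect_error(mean_excitation_energy(elf(1:10, rep(0, 10))), "degenerate")
})

test_that("Penn weight is 2 ELF/(pi omega_p) with near-unit screening mass", {
  # exact pointwise value: ELF = pi at omega_p = 2 Hartree gives g = 1
  e_ha <- seq(0.5, 4, length.out = 15)
  vals <- rep(0, 15); vals[7] <- pi
  stopifnot(abs(e_ha[7] - 2) < 1e-12)
  pw <- penn_weight(elf(hartree_to_ev(e_ha), vals))
  expect_equal(pw$g[7], 1, tolerance = 1e-9)
  expect_true(all(pw$g[vals == 0] == 0))
  expect_true(all(pw$g >= 0))

  # unit-screening Drude ELF integrates to ~1
  x <- synth_elf(drude_set(0.64, 0.8, 0.04), 0.05, 5e4, n = 4000)
  expect_equal(penn_weight(x)$integral_mass, 1, tolerance = 0.01)

  # grid refinement changes the mass by < 0.5%
  x1 <- polymer_like_elf(n = 700)
  x2 <- polymer_like_elf(n = 1400)
  m1 <- penn_weight(x1)$integral_mass
  m2 <- penn_weight(x2)$integral_mass
  expect_lt(abs(m2 / m1 - 1), 0.005)
})
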