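test_that("decomposition reproduces hand-evaluated terms on a worked ledger", {
  led <- energy_ledger(
    e_complex = -100, e_surface_relaxed = -40, e_molecule_relaxed = -30,
    e_surface_deformed = -38, e_molecule_deformed_periodic = -27,
    e_molecule_deformed_isolated = -28, e_surface_ghosted = -41,
    e_molecule_ghosted = -29, unit = "kJ/mol")
  d <- decompose_ledger(led)
  expect_equal(d$dE, -30)
  expect_equal(d$delta_S, 2)
  expect_equal(d$delta_N, 3)
  expect_equal(d$dE_N, 2)
  expect_equal(d$dE_L, 1)
  expect_equal(d$dE_star, -35)
  expect_equal(d$dE_star_C, -30)
  expect_equal(d$dE_C, -25)
  expect_equal(d$bsse, 5)
})

test_that("degenerate ledgers decompose to the expected zeros", {
  zero <- energy_ledger(0, 0, 0, 0, 0, 0, 0, 0, unit = "kJ/mol")
  d0 <- decompose_ledger(zero)
  for (f in c("dE", "dE_star", "delta_S", "delta_N", "dE_N", "dE_L",
              "dE_star_C", "dE_C", "bsse")) {
    expect_identical(d0[[f]], 0)
  }
  # no surface deformation -> delta_S = 0
  led <- energy_ledger(-90, -40, -30, -40, -27, -28, unit = "kJ/mol")
  expect_equal(decompose_ledger(led)$delta_S, 0)
})

test_that("missing ghost energies degrade to NA BSSE terms, not errors", {
  led <- energy_ledger(-100, -40, -30, -38, -27, -28, unit = "kJ/mol")
  d <- decompose_ledger(led)
  expect_true(is.na(d$bsse))
  expect_true(is.na(d$dE_C))
  expect_false(is.na(d$dE))
})

test_that("ledger construction validates inputs", {
  expect_error(energy_ledger(NA, -40, -30, -38, -27, -28, unit = "kJ/mol"),
               "E\\(SN//SN\\)")
  expect_error(energy_ledger(Inf, -40, -30, -38, -27, -28,
                             unit = "kJ/mol"), "finite")
  expect_error(energy_ledger(-100, -40, -30, -38, -27, -28,
                             unit = "furlong"), "unknown energy unit")
  # ghost energy above the deformed fragment violates variational lowering
  expect_warning(energy_ledger(-100, -40, -30, -38, -27, -28,
                               e_surface_ghosted = -37,
                               e_molecule_ghosted = -29, unit = "kJ/mol"),
                 "ghost")
})

test_that("identity invariants close on 1000 random synthetic ledgers", {
  set.seed(101)
  for (rep in 1:1000) {
    led <- generate_energy_ledger(
      dE_star = runif(1, -200, -1), delta_S = runif(1, 0, 50),
      dE_N = runif(1, 0, 30), dE_L = runif(1, -10, 10),
      bsse = runif(1, 0, 40), seed = rep)
    d <- decompose_ledger(led)
    expect_lt(abs(d$dE - (d$dE_star + d$delta_S + d$delta_N)),
              1e-9 * max(abs(d$dE), 1))
    expect_lt(abs(d$delta_N - (d$dE_N + d$dE_L)),
              1e-9 * max(abs(d$delta_N), 1))
    expect_lt(abs(d$dE_C - (d$dE_star_C + d$delta_S + d$dE_N + d$dE_L)),
              1e-9 * max(abs(d$dE_C), 1))
    expect_gte(d$bsse, -1e-9)
  }
})

test_that("decomposition is unit independent", {
  led <- generate_energy_ledger(-80, 5, 3, -2, 12, seed = 3)
  d_kj <- decompose_ledger(led)
  d_ha <- decompose_ledger(convert_ledger(led, "hartree"))
  d_ev <- decompose_ledger(convert_ledger(led, "eV"))
  for (f in c("dE", "dE_star", "delta_S", "dE_N", "dE_L", "bsse")) {
    expect_equal(d_ha[[f]], d_kj[[f]], tolerance = 1e-9)
    expect_equal(d_ev[[f]], d_kj[[f]], tolerance = 1e-9)
  }
})

test_that("unit conversion uses the CODATA factor and round-trips", {
  expect_equal(convert_energy(1, "hartree", "kJ/mol"), 2625.4996394799)
  expect_identical(convert_energy(0, "eV", "hartree"), 0)
  x <- c(-3.2, 0.7, 151.1)
  for (a in c("hartree", "kJ/mol", "eV")) for (b in c("hartree", "eV")) {
    expect_equal(convert_energy(convert_energy(x, a, b), b, a), x,
                 tolerance = 1e-12)
  }
  expect_error(convert_energy(1, "kcal", "eV"), "unknown energy unit")
})

test_that("dispersion contribution and fraction match the published table", {
  expect_equal(dispersion_contribution(-10.1, -104.9), -94.8)
  expect_equal(dispersion_contribution(-28.2, -131.9), -103.7)
  expect_identical(dispersion_contribution(-5.5, -5.5), 0)

  philic <- dispersion_split(-10.1, -104.9)
  phobic <- dispersion_split(-28.2, -131.9)
  expect_gt(dispersion_fraction(philic), 0.90)
  expect_equal(round(100 * dispersion_fraction(phobic)), 79)
  expect_equal(dispersion_fraction(dispersion_split(0, -50)), 1.0)
  expect_error(dispersion_fraction(dispersion_split(-10, 5)), "unbound|bound")
})

test_that("ledger JSON round-trips through the literal E(X//Y) symbols", {
  led <- generate_energy_ledger(-60, 4, 2, 1, 8, seed = 11)
  path <- tempfile(fileext = ".json")
  write_energy_ledger(led, path)
  raw <- jsonlite::read_json(path)
  expect_true(all(c("E(SN//SN)", "E(S//S)", "E_M(N//N)", "E(S[N]//SN)",
                    "E([S]N//SN)", "unit") %in% names(raw)))
  led2 <- read_energy_ledger(path)
  # decimal serialization of ~1e5 kJ/mol base energies limits the
  # round-trip of their small differences to ~1e-10 absolute
  d1 <- decompose_ledger(led)
  d2 <- decompose_ledger(led2)
  for (f in c("dE", "dE_star", "delta_S", "dE_N", "dE_L", "bsse")) {
    expect_lt(abs(d1[[f]] - d2[[f]]), 1e-8)
  }
})

test_that("energy table formatting mirrors the dE / dE^D / Disp. columns", {
  tab <- format_energy_table(c("4.5 OH/nm2 PBE-D2", "1.5 OH/nm2 PBE-D2"),
                             dE = c(-10.1, -28.2),
                             dE_disp = c(-104.9, -131.9))
  expect_match(tab[1], "dE\\^D")
  expect_match(tab[2], "-94.8")
  expect_match(tab[3], "-103.7")
})
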