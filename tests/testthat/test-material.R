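test_that("identity state gives identity invariants, zero strain, zero energy, zero stress", {
  inv <- isochoric_invariants(1, 1, 55)
  expect_equal(inv$I1bar, 3)
  expect_equal(inv$I4bar, 1)
  expect_equal(inv$I6bar, 1)
  Es <- fiber_strain_measures(3, 1, 1, 0.315)
  expect_equal(Es$E1bar, 0)
  expect_equal(Es$E2bar, 0)
  for (p in list(hgo_young(), hgo_params(C10 = 10, k1 = 50, k2 = 3,
                                         kappa = 0.1, alpha = 30))) {
    e <- strain_energy(p, 1, 1)
    expect_equal(e$U_total, 0)
    expect_equal(e$U_vol, 0)
    s <- membrane_stress(p, 1, 1)
    expect_equal(s$sigma_theta, 0, tolerance = 1e-12)
    expect_equal(s$sigma_z, 0, tolerance = 1e-12)
  }
})

test_that("equibiaxial stretch collapses the fiber-angle dependence", {
  for (lam in c(0.9, 1.1, 1.3)) {
    for (al in c(0, 30, 55, 90)) {
      inv <- isochoric_invariants(lam, lam, al)
      expect_equal(inv$I4bar, lam^2)
    }
  }
})

test_that("invariants, strain measures, energy and stress match the high-precision symbolic oracle at (1.2, 1.1)", {
  # frozen from a 30-digit mpmath evaluation of the closed-form expressions
  inv <- isochoric_invariants(1.2, 1.1, 55)
  expect_equal(inv$I1bar, 3.2239210284664830, tolerance = 1e-12)
  expect_equal(inv$I4bar, 1.2856676835175481, tolerance = 1e-12)
  Es <- fiber_strain_measures(inv$I1bar, inv$I4bar, inv$I6bar, 0.315)
  expect_equal(Es$E1bar, 0.086246846560407294, tolerance = 1e-12)
  expect_equal(Es$E2bar, Es$E1bar)
  e <- strain_energy(hgo_young(), 1.2, 1.1)
  expect_equal(e$U_iso, 9.4046831955922865, tolerance = 1e-11)
  expect_equal(e$U_aniso, 2.2614947999321718, tolerance = 1e-11)
  expect_equal(e$U_total, 11.666177995524458, tolerance = 1e-11)
  s <- membrane_stress(hgo_young(), 1.2, 1.1)
  expect_equal(s$sigma_theta, 105.58957959180972, tolerance = 1e-11)
  expect_equal(s$sigma_z, 80.352688279758425, tolerance = 1e-11)
})

test_that("matrix-only limit (k1 = 0) reduces the energy to the neo-Hookean term", {
  p <- hgo_params(k1 = 0)
  for (lt in c(0.9, 1.1, 1.4)) {
    e <- strain_energy(p, lt, 1.05)
    inv <- isochoric_invariants(lt, 1.05, p$alpha)
    expect_equal(e$U_total, p$C10 * (inv$I1bar - 3))
  }
})

test_that("kappa = 1/3 is fully isotropic: strain measure loses I4 and equibiaxial stresses are equal for any alpha", {
  Es <- fiber_strain_measures(3.4, 1.9, 1.9, 1 / 3)
  expect_equal(Es$E1bar, 0.4 / 3)
  Es2 <- fiber_strain_measures(3.4, 1.1, 1.1, 1 / 3)
  expect_equal(Es$E1bar, Es2$E1bar)
  for (al in c(0, 40, 55, 90)) {
    p <- hgo_params(kappa = 1 / 3, alpha = al)
    s <- membrane_stress(p, 1.25, 1.25)
    expect_equal(s$sigma_theta, s$sigma_z, tolerance = 1e-12)
  }
})

test_that("membrane stresses are consistent with finite differences of the strain energy", {
  p <- hgo_young()
  for (lt in c(0.85, 1.0, 1.25, 1.5)) {
    for (lz in c(0.9, 1.0, 1.2)) {
      # the tension-only switch puts a curvature kink exactly at the
      # identity (E = 0), where symmetric differences are not valid; the
      # identity stress is checked exactly elsewhere
      if (lt == 1 && lz == 1) next
      s <- membrane_stress(p, lt, lz)
      fd_t <- lt * num_deriv(function(x) strain_energy(p, x, lz)$U_total, lt)
      fd_z <- lz * num_deriv(function(x) strain_energy(p, lt, x)$U_total, lz)
      # relative to the overall stress magnitude at the state, so that a
      # single near-zero component does not blow up the comparison
      scale <- max(1, abs(fd_t), abs(fd_z))
      expect_lt(abs(s$sigma_theta - fd_t) / scale, 1e-6)
      expect_lt(abs(s$sigma_z - fd_z) / scale, 1e-6)
    }
  }
})

test_that("energy vanishes only at the identity on the physical domain", {
  p <- hgo_young()
  grid <- expand.grid(lt = seq(0.7, 1.6, by = 0.15),
                      lz = seq(0.7, 1.6, by = 0.15))
  for (i in seq_len(nrow(grid))) {
    U <- strain_energy(p, grid$lt[i], grid$lz[i])$U_total
    if (abs(grid$lt[i] - 1) < 1e-12 && abs(grid$lz[i] - 1) < 1e-12) {
      expect_equal(U, 0)
    } else {
      expect_gt(U, 0)
    }
  }
})

test_that("energy and hoop stress increase monotonically in lambda_theta at fixed lambda_z >= 1", {
  p <- hgo_young()
  for (lz in c(1, 1.1, 1.3)) {
    lts <- seq(1.0, 1.6, by = 0.05)
    U <- vapply(lts, function(x) strain_energy(p, x, lz)$U_total, numeric(1))
    S <- vapply(lts, function(x) membrane_stress(p, x, lz)$sigma_theta,
                numeric(1))
    expect_true(all(diff(U) > 0))
    expect_true(all(diff(S) > 0))
  }
})

test_that("tension-only switch is inert on tensile states and matters on compressed ones", {
  on <- hgo_params(tension_only = TRUE)
  off <- hgo_params(tension_only = FALSE)
  # tensile states: identical output
  for (lt in c(1.1, 1.3)) {
    expect_equal(strain_energy(on, lt, 1.05)$U_total,
                 strain_energy(off, lt, 1.05)$U_total)
    expect_equal(membrane_stress(on, lt, 1.05)$sigma_theta,
                 membrane_stress(off, lt, 1.05)$sigma_theta)
  }
  # with the high default dispersion the strain measure stays positive even
  # in compression (the kappa*(I1-3) term dominates), so a low-dispersion,
  # circumferential-fiber material is needed to reach E < 0
  al_on <- hgo_params(kappa = 0, alpha = 0, tension_only = TRUE)
  al_off <- hgo_params(kappa = 0, alpha = 0, tension_only = FALSE)
  inv <- isochoric_invariants(0.8, 1.0, 0)
  E <- fiber_strain_measures(inv$I1bar, inv$I4bar, inv$I6bar, 0)$E1bar
  expect_lt(E, 0)
  expect_lt(strain_energy(al_on, 0.8, 1.0)$U_aniso,
            strain_energy(al_off, 0.8, 1.0)$U_aniso)
})

test_that("overflow guard raises a material-instability error naming the state", {
  p <- hgo_params(k2 = 5000, exp_cap = 50)
  expect_error(strain_energy(p, 1.5, 1.2, context = "station 3"),
               "material instability.*station 3")
  expect_error(membrane_stress(p, 1.5, 1.2), "material instability")
})

test_that("parameter validation rejects out-of-range values and bad stretches", {
  expect_error(hgo_params(C10 = 0), "C10")
  expect_error(hgo_params(k2 = 0), "k2")
  expect_error(hgo_params(kappa = 0.4), "kappa")
  expect_error(hgo_params(alpha = 95), "alpha")
  expect_error(isochoric_invariants(-1, 1, 55), "positive")
  expect_error(membrane_stress(hgo_young(), 0, 1), "positive")
  expect_error(fiber_strain_measures(2.5, 1, 1, 0.3), "I1bar")
})

test_that("HGO presets round-trip through the JSON config interface", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(C10_kPa = 60, k1_kPa = 100, k2 = 8,
                            kappa = 0.2, alpha_deg = 45, D_per_kPa = 1e-6),
                       path, auto_unbox = TRUE)
  p <- read_hgo_params(path)
  expect_equal(p$C10, 60)
  expect_equal(p$k1, 100)
  expect_equal(p$alpha, 45)
  # missing keys fall back to the young preset
  jsonlite::write_json(list(C10_kPa = 50), path, auto_unbox = TRUE)
  p2 <- read_hgo_params(path)
  expect_equal(p2$C10, 50)
  expect_equal(p2$k1, hgo_young()$k1)
})
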