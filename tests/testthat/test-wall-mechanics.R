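test_that("axial stretch field is unity in diastole and for zero motion", {
  geo <- small_geometry()
  lz <- axial_stretch_field(geo, root_motion(9.5, 0.03), "diastole")
  expect_equal(lz$station, rep(1, nrow(geo)))
  lz0 <- axial_stretch_field(geo, root_motion(0, 0), "systole")
  expect_equal(lz0$station, rep(1, nrow(geo)))
  expect_equal(lz0$segment, rep(1, nrow(geo) - 1))
})

test_that("linear decay spreads the root displacement as uniform strain over its span", {
  # contact region starts at 150 mm; stations every 10 mm land exactly on it
  cfg <- aorta_config(n_stations = 36, length_mm = 350,
                      free_frac = 150 / 350, vicinity_frac = 0)
  geo <- make_geometry(cfg, seed = 0)
  lz <- axial_stretch_field(geo, root_motion(9.5, 0), "systole")
  span <- geo$s_mm[-1] <= 150
  expect_equal(mean(lz$segment[span]), 1 + 9.5 / 150, tolerance = 1e-12)
  expect_equal(lz$segment[!span], rep(1, sum(!span)))
})

test_that("segment elongations always sum to the imposed elongation", {
  set.seed(1)
  for (i in 1:8) {
    geo <- small_geometry(n = sample(8:30, 1))
    yb <- runif(1, 0, 20)
    ep <- runif(1, 0, 0.08)
    lz <- axial_stretch_field(geo, root_motion(yb, ep), "systole")
    ds <- diff(geo$s_mm)
    elong <- sum(lz$segment * ds) - sum(ds)
    expect_equal(elong, ep * attr(geo, "length_mm") + yb, tolerance = 1e-9)
  }
})

test_that("unloaded state is the equilibrium at zero pressure and solved roots satisfy the residual", {
  expect_equal(equilibrium_radius(12, 2.4, 12, 0, 1, 0, hgo_young()), 1,
               tolerance = 1e-9)
  # plugging a solved root back gives a residual far below the load scale
  for (P in c(40, 70, 110)) {
    for (lz in c(1, 1.05)) {
      lt <- equilibrium_radius(10, 2, 10, P, lz, 0.5, hgo_young())
      st <- membrane_stress(hgo_young(), lt, lz)$sigma_theta
      resid <- st * (2 / (lt * lz)) / (lt * 10) -
        (P * 0.133322 - 0.5 * (lt * 10 - 10))
      expect_lt(abs(resid), 1e-9 * P * 0.133322)
    }
  }
})

test_that("equilibrium root matches an independent dense-grid scan of the residual", {
  R0 <- 11; H0 <- 2.2; P <- 70
  lt <- equilibrium_radius(R0, H0, R0, P, 1, 0, hgo_young())
  grid <- seq(0.5, 2.5, by = 1e-6)
  st <- membrane_stress(hgo_young(), grid, 1)$sigma_theta
  resid <- st * (H0 / grid) / (grid * R0) - P * 0.133322
  i <- which(diff(sign(resid)) != 0)[1]
  # linear interpolation of the sign change on the fine grid
  root <- grid[i] - resid[i] * (grid[i + 1] - grid[i]) /
    (resid[i + 1] - resid[i])
  expect_equal(lt, root, tolerance = 1e-6)
})

test_that("unsolvable equilibria raise informative errors", {
  soft <- hgo_params(C10 = 0.5, k1 = 0, k2 = 1)
  expect_error(
    equilibrium_radius(12, 2.4, 12, 500, 1, 0, soft, context = "station 9"),
    "equilibrium not found.*station 9")
})

test_that("diastolic solve reproduces the in-vivo geometry within the restoration residual", {
  geo <- small_geometry()
  for (sup in list(support_none(), support_params())) {
    un <- restore_zero_pressure(geo, hgo_young(), sup, 70, tol = 0.001)
    dia <- solve_phase(geo, un, hgo_young(), sup, 70, phase = "diastole")
    expect_lt(max(abs(dia$r_mm - geo$diameter_mm / 2) / geo$diameter_mm),
              0.001)
  }
})

test_that("volume grows with pressure and shrinks with wall stiffness and support", {
  geo <- small_geometry()
  un <- restore_zero_pressure(geo, hgo_young(), support_none(), 70)
  dia <- solve_phase(geo, un, hgo_young(), support_none(), 70,
                     phase = "diastole")
  sys <- solve_phase(geo, un, hgo_young(), support_none(), 110,
                     phase = "systole", motion = root_motion(0))
  dV <- attr(sys, "volume_mm3") - attr(dia, "volume_mm3")
  expect_gt(dV, 0)

  stiffer <- hgo_params(C10 = 42 * 3, k1 = 290 * 3)
  un2 <- restore_zero_pressure(geo, stiffer, support_none(), 70)
  sys2 <- solve_phase(geo, un2, stiffer, support_none(), 110,
                      phase = "systole", motion = root_motion(0))
  dia2 <- solve_phase(geo, un2, stiffer, support_none(), 70,
                      phase = "diastole")
  expect_lt(attr(sys2, "volume_mm3") - attr(dia2, "volume_mm3"), dV)

  # support never increases radial expansion
  un3 <- restore_zero_pressure(geo, hgo_young(), support_params(), 70)
  sys3 <- solve_phase(geo, un3, hgo_young(), support_params(), 110,
                      phase = "systole", motion = root_motion(0))
  expect_true(all(sys3$r_mm <= sys$r_mm + 1e-6))
})

test_that("a rigid-limit wall shows essentially no volume change over the pulse", {
  geo <- small_geometry()
  rigid <- hgo_params(C10 = 42e6, k1 = 290e6)
  un <- restore_zero_pressure(geo, rigid, support_none(), 70, tol = 1e-5)
  dia <- solve_phase(geo, un, rigid, support_none(), 70, phase = "diastole")
  sys <- solve_phase(geo, un, rigid, support_none(), 110,
                     phase = "systole", motion = root_motion(0))
  rel <- (attr(sys, "volume_mm3") - attr(dia, "volume_mm3")) /
    attr(dia, "volume_mm3")
  expect_lt(abs(rel), 0.001)
})

test_that("straight-tube chain distensibility matches the single-ring closed form", {
  geo <- make_geometry(cylinder_config(), seed = 0)
  un <- restore_zero_pressure(geo, hgo_young(), support_none(), 70,
                              tol = 1e-6)
  dia <- solve_phase(geo, un, hgo_young(), support_none(), 70,
                     phase = "diastole")
  sys <- solve_phase(geo, un, hgo_young(), support_none(), 110,
                     phase = "systole", motion = root_motion(0))
  D_chain <- distensibility_from_volumes(attr(sys, "volume_mm3"),
                                         attr(dia, "volume_mm3"), 40)
  # single ring: V scales with r^2 at fixed length
  lt_d <- dia$lambda_theta[1]; lt_s <- sys$lambda_theta[1]
  D_ring <- ((lt_s / lt_d)^2 - 1) / 40 * 1000
  expect_equal(D_chain, D_ring, tolerance = 1e-6)
})

test_that("calibrated tube area distensibility inverts Bramwell-Hill at the achieved PWV", {
  mat <- suppressWarnings(
    calibrate_material_to_pwv(hgo_young(), 6, 12.5, 2.5))
  DA <- tube_area_distensibility(mat, 12.5, 2.5, 70)
  expect_equal(DA, distensibility_from_pwv(attr(mat, "achieved_pwv")),
               tolerance = 0.02)
})

test_that("phase states export to CSV with the documented columns", {
  geo <- small_geometry()
  un <- restore_zero_pressure(geo, hgo_young(), support_none(), 70)
  dia <- solve_phase(geo, un, hgo_young(), support_none(), 70,
                     phase = "diastole")
  path <- withr::local_tempfile(fileext = ".csv")
  write_phase_csv(dia, path)
  tab <- utils::read.csv(path)
  expect_named(tab, c("s_mm", "lambda_theta", "lambda_z", "r_mm",
                      "sigma_theta_kPa", "sigma_z_kPa"))
})
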