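# shared fixtures and small numeric oracles

# central-difference derivative with one Richardson step
num_deriv <- function(f, x, h = 1e-5) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# small geometry for fast property loops
small_geometry <- function(n = 12, ...) {
  make_geometry(aorta_config(n_stations = n, ...), seed = 0)
}

# straight uniform cylinder config (zero taper); the centerline shape is
# irrelevant to the ring mechanics, only diameters and lengths matter
cylinder_config <- function(d = 24, n = 15, L = 300) {
  aorta_config(n_stations = n, length_mm = L, d_proximal_mm = d,
               d_distal_mm = d)
}

# a solved generic scenario, computed once per test run
generic_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mat <- suppressWarnings(
        calibrate_material_to_pwv(hgo_young(), 4.8, 12.5, 2.5))
      cfg <- scenario_config(material = mat, displacement = 9.5,
                             eps_p = 0.027)
      cache <<- run_scenario(cfg)
    }
    cache
  }
})
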