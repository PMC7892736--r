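#' Holzapfel-Gasser-Ogden material parameters
#'
#' Constructs the parameter set of the Holzapfel-Gasser-Ogden (HGO)
#' hyperelastic model for an arterial wall: an isotropic neo-Hookean matrix
#' reinforced by two symmetric families of collagen fibers dispersed around
#' mean directions at +/-`alpha` from the circumferential direction.
#'
#' The defaults are the physiological values for a compliant young-adult
#' proximal aorta: `C10 = 42` kPa, `k1 = 290` kPa, `k2 = 12.6`,
#' `kappa = 0.315`, `alpha = 55` degrees, `D = 1e-6` kPa^-1.
#' The wall is treated as incompressible (the radial stretch is eliminated
#' analytically, so the volumetric term of the energy is identically zero);
#' `D` is retained for completeness but inert.
#'
#' @param C10 Isotropic matrix stiffness \[kPa\], > 0.
#' @param k1 Fiber stiffness \[kPa\], >= 0.
#' @param k2 Fiber exponential coefficient \[dimensionless\], > 0.
#' @param kappa Fiber dispersion coefficient, in \[0, 1/3\]; 1/3 is fully
#'   isotropic, 0 perfectly aligned.
#' @param alpha Mean fiber angle from the circumferential direction
#'   \[degrees\], in \[0, 90\].
#' @param D Compressibility coefficient \[kPa^-1\] (inert, see Details).
#' @param tension_only If `TRUE` (default) a fiber family contributes only
#'   when its strain measure is positive; the printed energy is ambiguous for
#'   compressed fibers and tension-only is the standard solver convention.
#' @param exp_cap Overflow guard: maximum allowed value of `k2 * E^2` in the
#'   fiber exponential before a material-instability error is raised.
#'
#' @return An object of class `hgo_params`.
#' @seealso [hgo_young()], [strain_energy()], [membrane_stress()]
#' @export
#' @examples
#' p <- hgo_params()
#' strain_energy(p, lambda_theta = 1.2, lambda_z = 1.1)
hgo_params <- function(C10 = 42, k1 = 290, k2 = 12.6, kappa = 0.315,
                       alpha = 55, D = 1e-6, tension_only = TRUE,
                       exp_cap = 50) {
  stopifnot(is.numeric(C10), is.numeric(k1), is.numeric(k2),
            is.numeric(kappa), is.numeric(alpha), is.numeric(D))
  if (C10 <= 0) stop("C10 must be > 0")
  if (k1 < 0) stop("k1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  if (kappa < 0 || kappa > 1 / 3) stop("kappa must be in [0, 1/3]")
  if (alpha < 0 || alpha > 90) stop("alpha must be in [0, 90] degrees")
  structure(list(C10 = C10, k1 = k1, k2 = k2, kappa = kappa,
                 alpha = alpha, D = D, n_families = 2L,
                 tension_only = isTRUE(tension_only), exp_cap = exp_cap),
            class = "hgo_params")
}

#' Young-adult HGO parameter preset
#'
#' The compliant young-aorta preset (`C10` 42 kPa, `k1` 290 kPa, `k2` 12.6,
#' `kappa` 0.315, `alpha` 55 degrees, `D` 1e-6 kPa^-1).
#'
#' @return An `hgo_params` object.
#' @export
hgo_young <- function() hgo_params()

#' Read HGO parameters from a JSON config file
#'
#' Keys: `C10_kPa`, `k1_kPa`, `k2`, `kappa`, `alpha_deg`, `D_per_kPa`.
#' Missing keys fall back to the young preset values.
#'
#' @param path Path to a JSON file.
#' @return An `hgo_params` object.
#' @export
read_hgo_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- hgo_young()
  pick <- function(key, fallback) if (!is.null(cfg[[key]])) cfg[[key]] else fallback
  hgo_params(C10 = pick("C10_kPa", def$C10), k1 = pick("k1_kPa", def$k1),
             k2 = pick("k2", def$k2), kappa = pick("kappa", def$kappa),
             alpha = pick("alpha_deg", def$alpha), D = pick("D_per_kPa", def$D))
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("HGO material parameters (2 symmetric dispersed fiber families)\n")
  cat(sprintf("  C10 = %g kPa, k1 = %g kPa, k2 = %g\n", x$C10, x$k1, x$k2))
  cat(sprintf("  kappa = %g, alpha = %g deg, D = %g kPa^-1 (inert)\n",
              x$kappa, x$alpha, x$D))
  cat(sprintf("  tension-only fibers: %s\n", x$tension_only))
  invisible(x)
}

#' Isochoric invariants of an incompressible membrane state
#'
#' Kinematics of a thin incompressible wall element under circumferential
#' stretch `lambda_theta` and axial stretch `lambda_z`; the radial stretch is
#' `1/(lambda_theta * lambda_z)`. The two fiber families at +/-`alpha` from
#' the circumferential direction share the same squared-stretch invariant,
#' so `I4bar == I6bar` for all membrane states.
#'
#' @param lambda_theta,lambda_z Circumferential and axial stretches, > 0.
#' @param alpha Mean fiber angle \[degrees\].
#' @return A list with `I1bar`, `I4bar`, `I6bar`.
#' @export
#' @examples
#' isochoric_invariants(1, 1, 55)  # identity: (3, 1, 1)
isochoric_invariants <- function(lambda_theta, lambda_z, alpha) {
  if (any(lambda_theta <= 0) || any(lambda_z <= 0))
    stop("stretches must be positive")
  lr2 <- (lambda_theta * lambda_z)^-2
  a <- alpha * pi / 180
  I4 <- lambda_theta^2 * cos(a)^2 + lambda_z^2 * sin(a)^2
  list(I1bar = lambda_theta^2 + lambda_z^2 + lr2, I4bar = I4, I6bar = I4)
}

#' Dispersed-fiber strain measures
#'
#' `Ea = kappa * (I1bar - 3) + (1 - 3*kappa) * (I4bar - 1)` for family 1, and
#' the same with `I6bar` for family 2. At `kappa = 1/3` the fiber response
#' degenerates to the isotropic measure `(I1bar - 3)/3`.
#'
#' @param I1bar,I4bar,I6bar Isochoric invariants.
#' @param kappa Dispersion coefficient.
#' @return A list with `E1bar`, `E2bar`.
#' @export
fiber_strain_measures <- function(I1bar, I4bar, I6bar, kappa) {
  if (any(I1bar < 3 - 1e-9)) stop("I1bar must be >= 3")
  list(E1bar = kappa * (I1bar - 3) + (1 - 3 * kappa) * (I4bar - 1),
       E2bar = kappa * (I1bar - 3) + (1 - 3 * kappa) * (I6bar - 1))
}

# Fiber-family energy/stress inclusion with the tension-only switch and the
# exponential overflow guard. Returns exp(k2*E^2) factor or stops.
.fiber_exp <- function(params, E, context = NULL) {
  arg <- params$k2 * E^2
  if (any(arg > params$exp_cap)) {
    where <- if (is.null(context)) "" else paste0(" at ", context)
    stop(sprintf(
      "material instability: k2*E^2 = %.3g exceeds cap %.3g%s",
      max(arg), params$exp_cap, where))
  }
  exp(arg)
}

#' Strain-energy density of a membrane state
#'
#' Evaluates the HGO strain-energy density for an incompressible membrane
#' state, decomposed into volumetric (identically zero here), isochoric
#' isotropic `C10 * (I1bar - 3)`, and isochoric anisotropic
#' `k1/(2*k2) * sum_a (exp(k2 * Ea^2) - 1)` parts. With the default
#' tension-only convention a family contributes only when `Ea > 0`.
#'
#' @param params An [hgo_params()] object.
#' @param lambda_theta,lambda_z Membrane stretches.
#' @param context Optional label (e.g., a station id) used in the overflow
#'   error message.
#' @return A list of class `energy_breakdown` with `U_vol`, `U_iso`,
#'   `U_aniso`, `U_total`, all in kPa.
#' @export
strain_energy <- function(params, lambda_theta, lambda_z, context = NULL) {
  stopifnot(inherits(params, "hgo_params"))
  inv <- isochoric_invariants(lambda_theta, lambda_z, params$alpha)
  Es <- fiber_strain_measures(inv$I1bar, inv$I4bar, inv$I6bar, params$kappa)
  U_iso <- params$C10 * (inv$I1bar - 3)
  U_aniso <- 0 * U_iso
  for (E in list(Es$E1bar, Es$E2bar)) {
    active <- if (params$tension_only) E > 0 else rep(TRUE, length(E))
    Ee <- ifelse(active, E, 0)
    U_aniso <- U_aniso +
      params$k1 / (2 * params$k2) * (.fiber_exp(params, Ee, context) - 1)
  }
  structure(list(U_vol = 0 * U_iso, U_iso = U_iso, U_aniso = U_aniso,
                 U_total = U_iso + U_aniso),
            class = "energy_breakdown")
}

#' In-plane Cauchy membrane stresses
#'
#' Plane-stress reduction of the HGO law for an incompressible wall: with the
#' radial stretch eliminated (`lambda_r = 1/(lambda_theta*lambda_z)`) and the
#' radial Cauchy stress taken as zero, the in-plane stresses follow from
#' `sigma_i = lambda_i * dU/dlambda_i` with analytic derivatives.
#'
#' @inheritParams strain_energy
#' @return A list of class `membrane_stress` with `sigma_theta`, `sigma_z`
#'   in kPa.
#' @export
#' @examples
#' membrane_stress(hgo_young(), 1.2, 1.1)
membrane_stress <- function(params, lambda_theta, lambda_z, context = NULL) {
  stopifnot(inherits(params, "hgo_params"))
  if (any(lambda_theta <= 0) || any(lambda_z <= 0))
    stop("stretches must be positive")
  a <- params$alpha * pi / 180
  lt <- lambda_theta; lz <- lambda_z
  dI1_dlt <- 2 * lt - 2 * lt^-3 * lz^-2
  dI1_dlz <- 2 * lz - 2 * lt^-2 * lz^-3
  inv <- isochoric_invariants(lt, lz, params$alpha)
  Es <- fiber_strain_measures(inv$I1bar, inv$I4bar, inv$I6bar, params$kappa)
  s_th <- lt * params$C10 * dI1_dlt
  s_z <- lz * params$C10 * dI1_dlz
  kp <- params$kappa
  fam <- list(list(E = Es$E1bar), list(E = Es$E2bar))
  for (f in fam) {
    E <- f$E
    active <- if (params$tension_only) E > 0 else rep(TRUE, length(E))
    Ee <- ifelse(active, E, 0)
    w <- params$k1 * Ee * .fiber_exp(params, Ee, context)  # dU/dE per family
    dE_dlt <- kp * dI1_dlt + (1 - 3 * kp) * 2 * lt * cos(a)^2
    dE_dlz <- kp * dI1_dlz + (1 - 3 * kp) * 2 * lz * sin(a)^2
    s_th <- s_th + lt * w * dE_dlt
    s_z <- s_z + lz * w * dE_dlz
  }
  structure(list(sigma_theta = s_th, sigma_z = s_z), class = "membrane_stress")
}
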