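#' External tissue support parameters
#'
#' Elastic (Robin-type) radial support of the wall by the surrounding
#' tissue, per unit outer area, by region: the descending aorta in
#' `contact` with the spine is tethered most stiffly, a `vicinity`
#' transition band less so, and the `free` ascending/arch wall least. The
#' dashpot coefficients are stored for completeness but inert: the analysis
#' is quasi-static between the diastolic and peak-systolic endpoints, where
#' wall velocity vanishes.
#'
#' Spring stiffnesses are reduced-model defaults (contact 10, vicinity 1,
#' free 0.1 kPa/mm), exposed in config.
#'
#' @param contact,vicinity,free Radial spring stiffness per unit area
#'   \[kPa/mm\] per region, with `contact >= vicinity >= free >= 0`.
#' @param c_contact,c_vicinity,c_free Dashpot coefficients \[kPa s/mm\]
#'   (stored, inert).
#' @return A list of class `support_params`.
#' @export
support_params <- function(contact = 10, vicinity = 1, free = 0.1,
                           c_contact = 0, c_vicinity = 0, c_free = 0) {
  k <- c(contact = contact, vicinity = vicinity, free = free)
  if (any(k < 0)) stop("spring stiffnesses must be >= 0")
  if (!(contact >= vicinity && vicinity >= free))
    stop("require k(contact) >= k(vicinity) >= k(free)")
  structure(list(k = k,
                 c = c(contact = c_contact, vicinity = c_vicinity,
                       free = c_free)),
            class = "support_params")
}

#' No external support
#'
#' @return A `support_params` object with all stiffnesses zero.
#' @export
support_none <- function() support_params(0, 0, 0)

.station_k <- function(geometry, support) {
  unname(support$k[geometry$region])
}

#' Per-station axial stretch field for a cardiac phase
#'
#' In diastole the centerline is at its reference length (`lambda_z = 1`
#' everywhere). At peak systole each inter-station segment carries a uniform
#' passive strain `eps_p` plus its share of the root displacement `y_b`,
#' distributed by the axial decay profile (linear from the root to the first
#' `contact` station). Summed over segments, the elongation equals
#' `eps_p * L + y_b`.
#'
#' @param geometry An `aorta_geometry`.
#' @param motion A [root_motion()] object.
#' @param phase `"diastole"` or `"systole"`.
#' @return A list with `station` (per-station `lambda_z`, endpoints carry
#'   their single adjacent segment value, interior stations the mean of the
#'   two) and `segment` (per-segment `lambda_z`, length `n - 1`).
#' @export
axial_stretch_field <- function(geometry, motion,
                                phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  n <- nrow(geometry)
  if (phase == "diastole")
    return(list(station = rep(1, n), segment = rep(1, n - 1)))
  w <- decay_weights(geometry)
  ds <- diff(geometry$s_mm)
  seg <- 1 + motion$eps_p + motion$peak_displacement * (-diff(w)) / ds
  station <- c(seg[1], (seg[-1] + seg[-(n - 1)]) / 2, seg[n - 1])
  list(station = station, segment = seg)
}

#' Solve thin-wall equilibrium for the circumferential stretch
#'
#' Laplace (membrane) equilibrium of one wall ring: finds `lambda_theta` in
#' \[0.5, 2.5\] such that
#' `sigma_theta(lambda_theta, lambda_z) * h / r = P - k * (r - r_ref)`,
#' with loaded radius `r = lambda_theta * R0` and loaded thickness
#' `h = H0 / (lambda_theta * lambda_z)`. The elastic support resists radial
#' displacement from the in-vivo diastolic radius `r_ref`. The residual is
#' monotone on the bracket, so the root is unique; it is resolved to a
#' relative tolerance of 1e-9.
#'
#' @param R0,H0 Unloaded mid-surface radius and thickness \[mm\].
#' @param r_ref In-vivo diastolic radius the support reacts against \[mm\].
#' @param P Internal pressure \[mmHg\], >= 0.
#' @param lambda_z Axial stretch of the ring.
#' @param k Support stiffness \[kPa/mm\].
#' @param material An [hgo_params()] object.
#' @param context Optional label for error messages.
#' @return The equilibrium `lambda_theta`.
#' @export
equilibrium_radius <- function(R0, H0, r_ref, P, lambda_z = 1, k = 0,
                               material = hgo_young(), context = NULL) {
  if (P < 0) stop("pressure must be >= 0")
  P_kPa <- mmHg_to_kPa(P)
  resid <- function(lt) {
    st <- membrane_stress(material, lt, lambda_z, context)$sigma_theta
    r <- lt * R0
    h <- H0 / (lt * lambda_z)
    st * h / r - (P_kPa - k * (r - r_ref))
  }
  lo <- 0.5; hi <- 2.5
  flo <- resid(lo); fhi <- resid(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    where <- if (is.null(context)) "" else paste0(" [", context, "]")
    stop(sprintf(
      paste0("equilibrium not found%s: no sign change on lambda_theta ",
             "bracket [%.2f, %.2f] at P = %.3g mmHg, lambda_z = %.4g ",
             "(material/pressure mismatch)"),
      where, lo, hi, P, lambda_z))
  }
  sol <- stats::uniroot(resid, c(lo, hi), f.lower = flo, f.upper = fhi,
                        tol = 1e-12, maxiter = 200)
  sol$root
}

#' Solve a quasi-static phase of the tube chain
#'
#' Per-station membrane equilibrium of the whole aorta at one pressure with
#' the phase's axial-stretch field: the loaded state of every station, the
#' total loaded centerline length, and the lumen volume integrated as the
#' frustum (conical-cylinder) chain over loaded radii and segment lengths.
#'
#' @param geometry In-vivo diastolic `aorta_geometry`.
#' @param unloaded An `unloaded_geometry` from [restore_zero_pressure()].
#' @param material An [hgo_params()] object.
#' @param support A [support_params()] object.
#' @param P Internal pressure \[mmHg\].
#' @param motion A [root_motion()] (ignored in diastole).
#' @param phase `"diastole"` or `"systole"`.
#' @return A data.frame of class `phase_state` (columns `s_mm`,
#'   `lambda_theta`, `lambda_z`, `r_mm`, `sigma_theta_kPa`, `sigma_z_kPa`)
#'   with attributes `pressure_mmHg`, `segment_length_mm`,
#'   `total_length_mm`, `volume_mm3`.
#' @export
solve_phase <- function(geometry, unloaded, material, support, P,
                        motion = root_motion(0),
                        phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  stopifnot(inherits(unloaded, "unloaded_geometry"))
  lz <- axial_stretch_field(geometry, motion, phase)
  kvec <- .station_k(geometry, support)
  r_ref <- geometry$diameter_mm / 2
  n <- nrow(geometry)
  lt <- numeric(n)
  for (i in seq_len(n)) {
    lt[i] <- equilibrium_radius(unloaded$R0_mm[i], unloaded$H0_mm[i],
                                r_ref[i], P, lz$station[i], kvec[i],
                                material,
                                context = sprintf("station %d (%s)", i, phase))
  }
  r <- lt * unloaded$R0_mm
  st <- membrane_stress(material, lt, lz$station)
  seg_len <- diff(geometry$s_mm) * lz$segment  # unloaded seg length = diastolic
  vol <- sum(conical_volume(seg_len, 2 * r[-n], 2 * r[-1]))
  structure(data.frame(s_mm = geometry$s_mm, lambda_theta = lt,
                       lambda_z = lz$station, r_mm = r,
                       sigma_theta_kPa = st$sigma_theta,
                       sigma_z_kPa = st$sigma_z),
            class = c("phase_state", "data.frame"),
            pressure_mmHg = P, segment_length_mm = seg_len,
            total_length_mm = sum(seg_len), volume_mm3 = vol)
}

#' Write a phase state as CSV
#'
#' Columns: `s_mm, lambda_theta, lambda_z, r_mm, sigma_theta_kPa,
#' sigma_z_kPa`.
#'
#' @param state A `phase_state`.
#' @param path File path.
#' @export
write_phase_csv <- function(state, path) {
  utils::write.csv(as.data.frame(state), path, row.names = FALSE)
  invisible(path)
}
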