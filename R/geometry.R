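#' Configuration for the synthetic proximal-aorta geometry
#'
#' Geometry parameters of the synthetic tapered, curved proximal aorta
#' (ascending limb, ~180-degree planar arch, descending limb down to the
#' celiac-trunk level). Defaults are typical young-adult dimensions:
#' 30 mm proximal lumen diameter tapering linearly to 20 mm over a 350 mm
#' centerline, wall thickness 10% of the local lumen diameter.
#'
#' @param n_stations Number of centerline stations.
#' @param length_mm Total diastolic centerline length \[mm\].
#' @param d_proximal_mm,d_distal_mm Proximal/distal lumen diameters \[mm\].
#' @param thickness_ratio Wall thickness as a fraction of local diameter.
#' @param ascending_mm Length of the straight ascending limb \[mm\].
#' @param arch_radius_mm Radius of the planar arch \[mm\].
#' @param free_frac,vicinity_frac Fractions of the centerline (from the
#'   root) tagged `free` and `vicinity`; the remainder (the descending
#'   aorta against the spine) is tagged `contact`.
#' @param jitter_sd_mm Standard deviation of optional seeded diameter
#'   jitter \[mm\] (0 = smooth taper); monotone non-increase is enforced.
#' @return A list of class `aorta_config`.
#' @export
aorta_config <- function(n_stations = 40, length_mm = 350,
                         d_proximal_mm = 30, d_distal_mm = 20,
                         thickness_ratio = 0.10,
                         ascending_mm = 60, arch_radius_mm = 40,
                         free_frac = 0.40, vicinity_frac = 0.10,
                         jitter_sd_mm = 0) {
  if (n_stations < 2) stop("config error: need at least 2 stations")
  if (length_mm <= 0 || d_proximal_mm <= 0 || d_distal_mm <= 0)
    stop("config error: dimensions must be positive")
  if (d_distal_mm > d_proximal_mm)
    stop("config error: taper must be non-increasing (d_distal <= d_proximal)")
  if (arch_radius_mm <= 0) stop("config error: arch radius must be > 0")
  if (ascending_mm + pi * arch_radius_mm >= length_mm)
    stop("config error: ascending limb + arch exceed total length")
  if (free_frac < 0 || vicinity_frac < 0 || free_frac + vicinity_frac >= 1)
    stop("config error: invalid region fractions")
  structure(as.list(environment()), class = "aorta_config")
}

#' Generate the synthetic proximal-aorta geometry
#'
#' Builds an ordered chain of centerline stations emulating the proximal
#' aorta from the aortic root down to the celiac-trunk level: a straight
#' ascending limb, a planar semicircular arch, and a straight descending
#' limb. Lumen diameter tapers linearly with arc length; wall thickness is
#' `thickness_ratio` (default 10%) of the local lumen diameter at every
#' station. Stations are tagged `free` (ascending/arch), `vicinity`
#' (transition band) or `contact` (descending aorta tethered by the spine).
#' Generation is pure: the same config and seed give identical geometries.
#'
#' @param config An [aorta_config()].
#' @param seed Integer seed for the (optional) diameter jitter.
#' @return A data.frame of class `aorta_geometry` with columns `s_mm`,
#'   `x_mm`, `y_mm`, `z_mm`, `diameter_mm`, `thickness_mm`, `region`, and
#'   attribute `length_mm`.
#' @export
#' @examples
#' geo <- make_geometry(aorta_config(), seed = 0)
#' head(geo)
make_geometry <- function(config = aorta_config(), seed = 0) {
  stopifnot(inherits(config, "aorta_config"))
  n <- config$n_stations
  L <- config$length_mm
  s <- seq(0, L, length.out = n)

  # centerline in the x-z plane: up, over the arch, down
  La <- config$ascending_mm
  Ra <- config$arch_radius_mm
  Larc <- pi * Ra
  x <- z <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]
    if (si <= La) {
      x[i] <- 0; z[i] <- si
    } else if (si <= La + Larc) {
      th <- (si - La) / Ra  # 0..pi
      x[i] <- Ra * (1 - cos(th)); z[i] <- La + Ra * sin(th)
    } else {
      x[i] <- 2 * Ra; z[i] <- La - (si - La - Larc)
    }
  }

  d <- config$d_proximal_mm +
    (config$d_distal_mm - config$d_proximal_mm) * s / L
  if (config$jitter_sd_mm > 0) {
    rng <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      stats::rnorm(n, 0, config$jitter_sd_mm)
    })
    d <- cummin(pmax(d + rng, 0.25 * config$d_distal_mm))  # keep tapered
  }

  region <- ifelse(s / L < config$free_frac, "free",
                   ifelse(s / L < config$free_frac + config$vicinity_frac,
                          "vicinity", "contact"))
  geo <- data.frame(s_mm = s, x_mm = x, y_mm = 0, z_mm = z,
                    diameter_mm = d,
                    thickness_mm = config$thickness_ratio * d,
                    region = region, stringsAsFactors = FALSE)
  structure(geo, class = c("aorta_geometry", "data.frame"),
            length_mm = L, config = config, seed = seed)
}

#' Write/read an aorta geometry as CSV
#'
#' Columns: `s_mm, x_mm, y_mm, z_mm, diameter_mm, thickness_mm, region`.
#'
#' @param geometry An `aorta_geometry`.
#' @param path File path.
#' @return `read_geometry_csv` returns an `aorta_geometry`.
#' @export
write_geometry_csv <- function(geometry, path) {
  utils::write.csv(as.data.frame(geometry), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("s_mm", "x_mm", "y_mm", "z_mm", "diameter_mm", "thickness_mm",
            "region")
  if (!all(need %in% names(geo)))
    stop("geometry CSV missing columns: ",
         paste(setdiff(need, names(geo)), collapse = ", "))
  structure(geo, class = c("aorta_geometry", "data.frame"),
            length_mm = max(geo$s_mm))
}

#' Generate a pressure load
#'
#' A smooth single-peak intraluminal pressure waveform over one normalized
#' cardiac cycle, attaining exactly the diastolic pressure at the cycle ends
#' and the systolic pressure at mid-cycle. Defaults emulate a carotid
#' tonometry trace calibrated to 110/70 mmHg.
#'
#' @param DBP,SBP Diastolic and systolic pressure \[mmHg\], `SBP > DBP > 0`.
#' @param n_samples Number of waveform samples (>= 3).
#' @return A list of class `pressure_load` with `DBP`, `SBP`,
#'   `pulse_pressure`, `p_o` (intrathoracic pressure, 0) and a `waveform`
#'   data.frame (`t`, `p_mmHg`).
#' @export
make_pressure <- function(DBP = 70, SBP = 110, n_samples = 100) {
  if (!(SBP > DBP) || DBP <= 0) stop("require SBP > DBP > 0")
  if (n_samples < 3) stop("n_samples must be >= 3")
  t <- seq(0, 1, length.out = n_samples)
  p <- sin(pi * t)^2
  p <- DBP + (SBP - DBP) * (p - min(p)) / (max(p) - min(p))
  structure(list(DBP = DBP, SBP = SBP, pulse_pressure = SBP - DBP, p_o = 0,
                 waveform = data.frame(t = t, p_mmHg = p)),
            class = "pressure_load")
}

#' Project the coronal aortic-annulus displacement onto the motion vector
#'
#' The root displacement measured in the coronal plane (`AAD_C`) is
#' projected through the plane-rotation angle `phi` onto the true motion
#' vector: `AAD_C * cos(phi)`.
#'
#' @param AAD_C Coronal-plane annulus displacement \[mm\], >= 0.
#' @param phi Rotation angle between planes \[degrees\].
#' @return Projected displacement \[mm\].
#' @export
project_root_displacement <- function(AAD_C, phi) {
  if (any(AAD_C < 0)) stop("AAD_C must be >= 0")
  AAD_C * cos(phi * pi / 180)
}

#' Average repeated displacement measurements
#'
#' Arithmetic mean of repeated measurements, reported to one decimal with
#' round-half-up (e.g., 9.8 and 9.1 mm average to 9.5 mm).
#'
#' @param values Non-empty numeric vector \[mm\].
#' @return Mean rounded half-up to one decimal \[mm\].
#' @export
summarize_repeated_measurements <- function(values) {
  if (length(values) == 0) stop("need at least one measurement")
  floor(mean(values) * 10 + 0.5) / 10
}

#' Aortic-root motion scenario
#'
#' Peak systolic root displacement plus a smooth 0 -> 1 -> 0 temporal
#' profile (cosmetic in the quasi-static analysis: only the diastolic and
#' peak-systolic endpoints enter the mechanics). The displacement is
#' absorbed axially by the aorta following a linear decay from the root
#' station to the first `contact` station (the spine-tethered descending
#' aorta does not elongate); `eps_p` is the uniform passive centerline
#' strain produced by pressurization alone.
#'
#' @param peak_displacement Peak systolic root displacement y_b \[mm\], >= 0.
#' @param eps_p Passive pressure-induced centerline strain (>= 0),
#'   calibrated once against the no-motion scenario (see
#'   [calibrate_passive_elongation()]).
#' @param n_samples Samples of the temporal profile.
#' @return A list of class `root_motion`.
#' @export
root_motion <- function(peak_displacement = 9.5, eps_p = 0, n_samples = 50) {
  if (peak_displacement < 0) stop("peak displacement must be >= 0")
  if (eps_p < 0) stop("eps_p must be >= 0")
  t <- seq(0, 1, length.out = n_samples)
  f <- sin(pi * t)^2
  f <- f / max(f)  # peak exactly 1 for any sample count
  structure(list(peak_displacement = peak_displacement, eps_p = eps_p,
                 profile = data.frame(t = t, f = f)),
            class = "root_motion")
}

#' Axial decay weights of the root displacement
#'
#' Fraction of the root displacement still carried at each station: 1 at
#' the root, decaying linearly in arc length to 0 at the first `contact`
#' station and 0 beyond it.
#'
#' @param geometry An `aorta_geometry`.
#' @return Numeric vector of per-station weights in \[0, 1\].
#' @export
decay_weights <- function(geometry) {
  s <- geometry$s_mm
  ic <- which(geometry$region == "contact")
  s_c <- if (length(ic)) s[min(ic)] else max(s)
  if (s_c <= 0) return(rep(0, length(s)))
  pmax(0, 1 - s / s_c)
}

#' Sample two-phase cross sections from solved phase states
#'
#' Tags `tag_count` cross sections evenly spaced in diastolic arc length
#' (7 for the in-silico style analysis, 8 for the two-phase in-vivo style
#' analysis) and samples the solved diastolic and systolic states for lumen
#' areas and inter-tag centerline lengths in both phases. This is the bridge
#' between the truth model and the cross-section-based estimators.
#'
#' @param dia_state,sys_state `phase_state` objects from [solve_phase()],
#'   sharing the same geometry.
#' @param tag_count Number of tagged sections (>= 2).
#' @return A data.frame of class `two_phase_sections` with columns `tag`,
#'   `s_mm`, `area_dia_mm2`, `area_sys_mm2`, `seg_len_dia_mm`,
#'   `seg_len_sys_mm` (segment lengths lead up to each tag; first row `NA`).
#' @export
make_two_phase_sections <- function(dia_state, sys_state, tag_count = 7) {
  stopifnot(inherits(dia_state, "phase_state"),
            inherits(sys_state, "phase_state"))
  if (tag_count < 2) stop("tag_count must be >= 2")
  s <- dia_state$s_mm
  tags <- seq(min(s), max(s), length.out = tag_count)

  r_dia <- stats::approx(s, dia_state$r_mm, xout = tags)$y
  r_sys <- stats::approx(s, sys_state$r_mm, xout = tags)$y

  # cumulative loaded centerline length per phase, interpolated at the tags
  cum_len <- function(state) {
    seg <- attr(state, "segment_length_mm")
    c(0, cumsum(seg))
  }
  Ld <- stats::approx(s, cum_len(dia_state), xout = tags)$y
  Ls <- stats::approx(s, cum_len(sys_state), xout = tags)$y

  structure(data.frame(
    tag = seq_len(tag_count), s_mm = tags,
    area_dia_mm2 = pi * r_dia^2, area_sys_mm2 = pi * r_sys^2,
    seg_len_dia_mm = c(NA, diff(Ld)), seg_len_sys_mm = c(NA, diff(Ls))),
    class = c("two_phase_sections", "data.frame"))
}

#' Write/read two-phase section tables as CSV
#'
#' The CSV layout (`tag, s_mm, area_dia_mm2, area_sys_mm2, seg_len_dia_mm,
#' seg_len_sys_mm`) is also the real-data entry point: tables of measured
#' cross-sectional areas along a centerline at two cardiac phases can be
#' fed directly to [run_two_phase_estimation()].
#'
#' @param sections A `two_phase_sections` data.frame.
#' @param path File path.
#' @return `read_sections_csv` returns a `two_phase_sections` object.
#' @export
write_sections_csv <- function(sections, path) {
  utils::write.csv(as.data.frame(sections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sections_csv
#' @export
read_sections_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag", "s_mm", "area_dia_mm2", "area_sys_mm2",
            "seg_len_dia_mm", "seg_len_sys_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("section CSV parse error: missing columns ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$area_dia_mm2) | tab$area_dia_mm2 <= 0 |
                 !is.finite(tab$area_sys_mm2) | tab$area_sys_mm2 <= 0)
  if (length(bad))
    stop("section CSV parse error: non-positive area at line ", bad[1] + 1)
  structure(tab, class = c("two_phase_sections", "data.frame"))
}
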