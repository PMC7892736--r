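#' Volume of a conical cylinder (frustum)
#'
#' `pi * L / 12 * (D1^2 + D1*D2 + D2^2)`: the exact volume of a circular
#' frustum of length `L` whose diameter tapers linearly from `D1` to `D2`.
#' Vectorized.
#'
#' @param L Segment length(s) \[mm\], >= 0.
#' @param D1,D2 End diameters \[mm\], >= 0.
#' @return Volume(s) \[mm^3\].
#' @export
#' @examples
#' conical_volume(3, 2, 2)  # cylinder limit: 3 * pi
conical_volume <- function(L, D1, D2) {
  if (any(L < 0) || any(D1 < 0) || any(D2 < 0))
    stop("conical_volume: inputs must be >= 0")
  pi * L / 12 * (D1^2 + D1 * D2 + D2^2)
}

#' Integrate tagged cross sections into a lumen volume
#'
#' Chains [conical_volume()] over consecutive tagged sections. Diameters are
#' derived from areas assuming circular cross sections
#' (`d = 2 * sqrt(A / pi)`). In `fixed` length mode the diastolic inter-tag
#' lengths are used for both phases (the elongation-neglecting estimator);
#' in `variable` mode each phase uses its own lengths.
#'
#' @param sections A `two_phase_sections` data.frame.
#' @param phase `"diastole"` or `"systole"`.
#' @param length_mode `"fixed"` or `"variable"`.
#' @return Volume \[mm^3\].
#' @export
chain_volume <- function(sections, phase = c("diastole", "systole"),
                         length_mode = c("fixed", "variable")) {
  phase <- match.arg(phase)
  length_mode <- match.arg(length_mode)
  if (nrow(sections) < 2) stop("need at least 2 tagged sections")
  if (any(diff(sections$s_mm) <= 0))
    stop("tag coordinates must be strictly increasing")
  A <- if (phase == "diastole") sections$area_dia_mm2 else sections$area_sys_mm2
  d <- 2 * sqrt(A / pi)
  len <- if (length_mode == "fixed" || phase == "diastole")
    sections$seg_len_dia_mm else sections$seg_len_sys_mm
  len <- len[-1]  # segment lengths lead up to each tag; first row is NA
  n <- nrow(sections)
  sum(conical_volume(len, d[-n], d[-1]))
}

#' Volumetric distensibility from endpoint volumes
#'
#' `(V_max - V_min) / V_min / PP`, reported on the 1e-3 mmHg^-1 scale.
#'
#' @param V_max,V_min Peak-systolic and diastolic lumen volumes \[mm^3\],
#'   `V_min > 0`.
#' @param PP Pulse pressure \[mmHg\], > 0.
#' @return Distensibility \[1e-3 mmHg^-1\].
#' @export
#' @examples
#' distensibility_from_volumes(1.04 * 100, 100, 40)  # 1.0
distensibility_from_volumes <- function(V_max, V_min, PP) {
  if (V_min <= 0) stop("V_min must be > 0")
  if (PP <= 0) stop("pulse pressure must be > 0")
  (V_max - V_min) / V_min / PP * 1000
}

#' Cross-sectional area compliance
#'
#' `C_A = dA/dP`, approximated by the secant `(A_sys - A_dia) / PP`.
#'
#' @param A_dia,A_sys Diastolic and systolic areas \[mm^2\].
#' @param PP Pulse pressure \[mmHg\], > 0.
#' @return Area compliance \[mm^2/mmHg\].
#' @export
area_compliance <- function(A_dia, A_sys, PP) {
  if (any(PP <= 0)) stop("pulse pressure must be > 0")
  (A_sys - A_dia) / PP
}

#' Relative distensibility estimation error
#'
#' `(D_est - D_ref) / D_ref * 100`; negative values mean underestimation.
#' Always computed from unrounded internals (rounded table entries do not
#' reproduce the error of the unrounded pipeline).
#'
#' @param D_ref Reference distensibility, > 0.
#' @param D_est Estimated distensibility.
#' @return Error \[%\].
#' @export
estimation_error <- function(D_ref, D_est) {
  if (any(D_ref <= 0)) stop("D_ref must be > 0")
  (D_est - D_ref) / D_ref * 100
}

#' Bramwell-Hill pulse wave velocity from area distensibility
#'
#' `PWV = 1 / sqrt(rho * D_A)` with the area distensibility converted from
#' mmHg^-1 to Pa^-1. [distensibility_from_pwv()] is the exact inverse.
#'
#' @param area_distensibility Local area distensibility \[mmHg^-1\], > 0.
#' @param rho Blood density \[kg/m^3\], > 0 (default 1060).
#' @return Pulse wave velocity \[m/s\].
#' @export
#' @examples
#' bramwell_hill_pwv(distensibility_from_pwv(4.8))  # 4.8
bramwell_hill_pwv <- function(area_distensibility, rho = 1060) {
  if (any(area_distensibility <= 0) || any(rho <= 0))
    stop("inputs must be > 0")
  1 / sqrt(rho * area_distensibility / 133.322)
}

#' @rdname bramwell_hill_pwv
#' @param pwv Pulse wave velocity \[m/s\], > 0.
#' @return `distensibility_from_pwv`: area distensibility \[mmHg^-1\].
#' @export
distensibility_from_pwv <- function(pwv, rho = 1060) {
  if (any(pwv <= 0) || any(rho <= 0)) stop("inputs must be > 0")
  133.322 / (rho * pwv^2)
}

#' Assemble a distensibility report
#'
#' Collects the reference (volumetric) distensibility, the fixed-length and
#' variable-length cross-section estimates, their percent errors, and the
#' improvement ratio `(|err_fixed| - |err_variable|) / |err_fixed| * 100`.
#' If the reference is degenerate (non-positive, or below 1e-4 on the
#' 1e-3 mmHg^-1 scale, i.e. three orders of magnitude under physiological
#' values, as for a rigid-limit wall), the errors and improvement are
#' reported as `NA` rather than as ratios of numerical noise.
#'
#' @param D_ref,D_fixed,D_variable Distensibilities \[1e-3 mmHg^-1\].
#' @param V_min,V_max Truth-model volumes \[mm^3\].
#' @param PP Pulse pressure \[mmHg\].
#' @param scenario Optional scenario label.
#' @return A list of class `distensibility_report`.
#' @export
distensibility_report <- function(D_ref, D_fixed, D_variable, V_min = NA,
                                  V_max = NA, PP = NA, scenario = NA) {
  degenerate <- !is.finite(D_ref) || D_ref <= 1e-4
  err_fixed <- if (degenerate) NA_real_ else estimation_error(D_ref, D_fixed)
  err_variable <- if (degenerate) NA_real_ else
    estimation_error(D_ref, D_variable)
  improvement <- if (degenerate || abs(err_fixed) < 1e-12) NA_real_ else
    (abs(err_fixed) - abs(err_variable)) / abs(err_fixed) * 100
  structure(list(scenario = scenario, D_ref = D_ref, D_fixed_length = D_fixed,
                 D_variable_length = D_variable, err_fixed = err_fixed,
                 err_variable = err_variable, improvement = improvement,
                 V_min = V_min, V_max = V_max, pulse_pressure = PP,
                 degenerate = degenerate),
            class = "distensibility_report")
}

#' @export
print.distensibility_report <- function(x, ...) {
  cat("Distensibility report",
      if (!is.na(x$scenario)) paste0("[", x$scenario, "]"), "\n")
  cat(sprintf("  reference D:        %.2f x 1e-3 mmHg^-1\n", x$D_ref))
  cat(sprintf("  fixed-length D:     %.2f x 1e-3 mmHg^-1 (err %.1f%%)\n",
              x$D_fixed_length, x$err_fixed))
  cat(sprintf("  variable-length D:  %.2f x 1e-3 mmHg^-1 (err %.1f%%)\n",
              x$D_variable_length, x$err_variable))
  cat(sprintf("  improvement:        %.1f%%\n", x$improvement))
  invisible(x)
}

#' Serialize a distensibility report
#'
#' `report_as_row` returns a one-row data.frame mirroring the sensitivity
#' table columns (scenario, reference distensibility, estimate without
#' considering elongation, error); `write_report_json` writes the full
#' report as JSON.
#'
#' @param report A `distensibility_report`.
#' @return A one-row data.frame.
#' @export
report_as_row <- function(report) {
  data.frame(
    scenario = report$scenario,
    reference_distensibility_1e3_mmHg = report$D_ref,
    estimate_without_elongation_1e3_mmHg = report$D_fixed_length,
    error_without_elongation_pct = report$err_fixed,
    estimate_variable_length_1e3_mmHg = report$D_variable_length,
    error_variable_length_pct = report$err_variable,
    improvement_pct = report$improvement,
    stringsAsFactors = FALSE)
}

#' @rdname report_as_row
#' @param path File path for the JSON output.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
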