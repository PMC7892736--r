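# Exact pressure conversion used at every I/O boundary.
# Internally the package works in kPa and mm (kPa * mm / mm = kPa, so the
# thin-wall equilibrium needs no further scale factors).
KPA_PER_MMHG <- 0.133322

#' Convert pressure between mmHg and kPa
#'
#' Exact conversion with 1 mmHg = 133.322 Pa.
#'
#' @param p Pressure value(s).
#' @return Converted pressure value(s).
#' @keywords internal
mmHg_to_kPa <- function(p) p * KPA_PER_MMHG

#' @rdname mmHg_to_kPa
#' @keywords internal
kPa_to_mmHg <- function(p) p / KPA_PER_MMHG
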