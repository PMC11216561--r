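# 1 mmHg = 1.35951 cm water at 4 degrees C; conversions are always explicit.
CMH2O_PER_MMHG <- 1.35951

#' Convert pressures between mmHg and cm water
#'
#' Intracranial pressure is reported in cm water throughout this package
#' (the unit of lumbar-puncture manometry); much of the ICP literature uses
#' mmHg. These helpers convert explicitly -- no function in the package ever
#' converts units implicitly.
#'
#' @param x Numeric vector of pressures.
#' @return Numeric vector of converted pressures.
#' @examples
#' mmhg_to_cmh2o(15)   # upper normal ICP approx 20.4 cm water
#' cmh2o_to_mmhg(22)
#' @export
mmhg_to_cmh2o <- function(x) x * CMH2O_PER_MMHG

#' @rdname mmhg_to_cmh2o
#' @export
cmh2o_to_mmhg <- function(x) x / CMH2O_PER_MMHG
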