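#' Physical constants used throughout the package
#'
#' Fixed defaults for the handful of physical constants the calculators rely
#' on. Every function taking a constant accepts an override, so these are
#' conventions, not hard-wired assumptions.
#'
#' @return Named list with elements:
#' \describe{
#'   \item{faraday}{Faraday constant, 96485 C mol^-1.}
#'   \item{avogadro}{Avogadro constant, 6.022e23 mol^-1.}
#'   \item{water_density}{Density of water near room temperature, 998 kg m^-3.}
#'   \item{water_heat_capacity}{Specific heat of water, 4180 J kg^-1 K^-1.}
#' }
#' @export
#' @examples
#' pef_constants()$faraday
pef_constants <- function() {
  list(
    faraday = 96485,
    avogadro = 6.022e23,
    water_density = 998,
    water_heat_capacity = 4180
  )
}
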