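#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values. All photon-energy arithmetic in the package
#' goes through this table so that every module uses identical constants.
#'
#' @format Named list with elements
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{c_light}{speed of light in vacuum, m s^-1}
#'   \item{N_A}{Avogadro constant, mol^-1}
#' }
#' @export
physical_constants <- list(
  h       = 6.62607015e-34,
  c_light = 2.99792458e8,
  N_A     = 6.02214076e23
)

# photon energy in J at a wavelength given in nm
.photon_energy <- function(wavelength_nm) {
  physical_constants$h * physical_constants$c_light / (wavelength_nm * 1e-9)
}

# trapezoid rule on an irregular grid; kept local so the quadrature used
# for emission integration is one auditable definition
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

.stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "photokin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  )
  stop(cond)
}
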