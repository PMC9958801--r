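#' Physical constants used throughout the model
#'
#' CODATA 2018 values, SI units. The elementary charge, Boltzmann and Planck
#' constants and the Avogadro number are exact by definition since the 2019
#' SI redefinition; the electron mass and vacuum permittivity are quoted to
#' nine significant digits.
#'
#' @return A named list with components
#'   \describe{
#'     \item{q}{elementary charge, C}
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{hbar}{reduced Planck constant, J s}
#'     \item{m0}{free electron rest mass, kg}
#'     \item{eps0}{vacuum permittivity, F/m}
#'     \item{N_A}{Avogadro constant, 1/mol}
#'   }
#' @examples
#' physical_constants()$q
#' @export
physical_constants <- function() {
  list(
    q    = 1.602176634e-19,
    kB   = 1.380649e-23,
    hbar = 1.054571817e-34,
    m0   = 9.10938370e-31,
    eps0 = 8.85418781e-12,
    N_A  = 6.02214076e23
  )
}

# internal shorthand; a plain list keeps hot paths free of function calls
.const <- list(
  q    = 1.602176634e-19,
  kB   = 1.380649e-23,
  hbar = 1.054571817e-34,
  m0   = 9.10938370e-31,
  eps0 = 8.85418781e-12,
  N_A  = 6.02214076e23
)
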