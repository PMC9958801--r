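#' Areal density of states of a two-valley 2D band
#'
#' Effective-mass density of states of the lowest (highest) two conduction
#' (valence) valleys. The second valley is thermally weighted by its energy
#' separation from the first:
#' `D0 = g1*m1/(2*pi*hbar^2) + g2*m2/(2*pi*hbar^2) * exp(-dE12/(kB*T))`.
#'
#' @param band A [band_structure()].
#' @param thermal A [thermal_state()].
#' @return Areal density of states, 1/(J m^2).
#' @examples
#' density_of_states(band_structure("n", 0.54, 0.58, 2, 6, 0.07))
#' @export
density_of_states <- function(band, thermal = thermal_state()) {
  .assert(inherits(band, "band_structure"), "`band` must be a band_structure")
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  pref <- .const$m0 / (2 * pi * .const$hbar^2)
  kT <- .const$kB * thermal$temperature
  band$g1 * band$m1_rel * pref +
    band$g2 * band$m2_rel * pref * exp(-band$dE12 * .const$q / kT)
}

# overflow-safe log(1 + exp(x)); exact softplus for |x| up to ~2000
.softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

#' Sheet charge density of the 2D channel
#'
#' Fermi-Dirac sheet charge as a function of the chemical potential
#' `phi_ch` (band edge minus quasi-Fermi level, in volts). For an n-type
#' channel `sigma_2D = -phi_th * Cdq * log(1 + exp(-phi_ch/phi_th)) <= 0`;
#' the p-type branch is the mirror image. Evaluated with a softplus so it
#' neither overflows nor underflows for `|phi_ch/phi_th|` up to ~2000.
#'
#' @param phi_ch Chemical potential, V. Vectorised.
#' @param model A [sheet_charge_model()].
#' @return Sheet charge density, C/m^2 (same length as `phi_ch`).
#' @examples
#' m <- sheet_charge_model(band_structure("n", 0.54, 0.58, 2, 6, 0.07))
#' sheet_charge(0, m) # -phi_th * Cdq * log(2)
#' @export
sheet_charge <- function(phi_ch, model) {
  .assert(inherits(model, "sheet_charge_model"),
          "`model` must be a sheet_charge_model")
  phith <- model$thermal$phi_th
  if (model$band$carrier_type == "n") {
    -phith * model$Cdq * .softplus(-phi_ch / phith)
  } else {
    phith * model$Cdq * .softplus(phi_ch / phith)
  }
}

#' Dimensionless occupation function u(phi_ch)
#'
#' `u = log(1 + exp(-phi_ch/phi_th))` for n-type (sign flipped for p-type),
#' so that `|sigma_2D| = phi_th * Cdq * u` holds exactly. `u` is the state
#' variable of the closed-form drain-current expression.
#'
#' @inheritParams sheet_charge
#' @return Non-negative dimensionless values, same length as `phi_ch`.
#' @examples
#' m <- sheet_charge_model(band_structure("n", 0.54, 0.58, 2, 6, 0.07))
#' u_value(0, m) # log(2)
#' @export
u_value <- function(phi_ch, model) {
  .assert(inherits(model, "sheet_charge_model"),
          "`model` must be a sheet_charge_model")
  phith <- model$thermal$phi_th
  if (model$band$carrier_type == "n") {
    .softplus(-phi_ch / phith)
  } else {
    .softplus(phi_ch / phith)
  }
}
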