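#' Bulk ion number concentration
#'
#' Converts an ionic molar concentration (mol/L) into a per-species number
#' concentration: `n0 = N_A * i0 * 1000` (1/m^3). A symmetric 1:1
#' electrolyte is assumed throughout, so `n0` is the concentration of each
#' ionic species far from any charged interface.
#'
#' @param i0 Ionic molar concentration, mol/L. Vectorised.
#' @return Number concentration, 1/m^3.
#' @examples
#' bulk_ion_concentration(1e-3) # 1 mM -> 6.022e23 m^-3
#' @export
bulk_ion_concentration <- function(i0) {
  .assert(all(i0 >= 0), "`i0` must be >= 0 (mol/L)")
  .const$N_A * i0 * 1000
}

#' Membrane charge concentration from Langmuir binding
#'
#' Equilibrium Langmuir occupancy of surface receptors converted into a
#' volumetric fixed-charge concentration spread over the membrane thickness:
#' `Nm = (kq / hm) * Nr * Kc*Nt / (1 + Kc*Nt)`.
#' The sign of `Nm` is the sign of the per-molecule charge `kq`.
#'
#' @param m A [membrane_spec()] in Langmuir mode.
#' @return Signed membrane charge concentration, 1/m^3.
#' @examples
#' m <- membrane_spec(Nr = 2.3e17, Nt = 100e-15, Kc = 1e13, hm = 5e-9, kq = 22.3)
#' langmuir_membrane_charge(m) # half occupancy
#' @export
langmuir_membrane_charge <- function(m) {
  .assert(inherits(m, "membrane_spec"), "`m` must be a membrane_spec")
  .assert(identical(m$mode, "langmuir"),
          "`m` must be a Langmuir-mode membrane_spec (receptor/target binding)")
  occupancy <- m$Kc * m$Nt / (1 + m$Kc * m$Nt)
  (m$kq / m$hm) * m$Nr * occupancy
}

#' Membrane charge concentration for either membrane mode
#'
#' Returns the fixed `Nm` directly, or evaluates the Langmuir isotherm.
#'
#' @param m A [membrane_spec()].
#' @return Signed membrane charge concentration, 1/m^3.
#' @export
membrane_charge_concentration <- function(m) {
  .assert(inherits(m, "membrane_spec"), "`m` must be a membrane_spec")
  if (m$mode == "fixed_Nm") m$Nm else langmuir_membrane_charge(m)
}

#' Donnan potential of the ion-permeable membrane
#'
#' Potential plateau reached inside a charge-neutral ion-permeable membrane
#' of fixed charge `Nm` bathed in a 1:1 electrolyte of per-species
#' concentration `n0`:
#' `psi_DP = phi_th * asinh(Nm / (2*n0))`,
#' evaluated through the logarithmic form
#' `log(x + sqrt(1 + x^2))`. Odd in `Nm`.
#'
#' @param Nm Signed membrane charge concentration, 1/m^3. Vectorised.
#' @param n0 Bulk per-species ion concentration, 1/m^3 (positive).
#' @param thermal A [thermal_state()].
#' @return Donnan potential, V.
#' @examples
#' donnan_potential(0, bulk_ion_concentration(1e-3)) # 0
#' @export
donnan_potential <- function(Nm, n0, thermal = thermal_state()) {
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  .assert(.is_num1(n0) && n0 >= 0, "`n0` must be a single non-negative number")
  if (n0 == 0) {
    if (all(Nm == 0)) return(rep(0, length(Nm)))
    abort("`n0` = 0 with non-zero membrane charge: the Donnan limit is undefined (unscreened membrane)")
  }
  x <- Nm / (2 * n0)
  thermal$phi_th * log(x + sqrt(1 + x^2))
}

#' Net charge in the membrane plus diffuse layer
#'
#' First integral of the Poisson-Boltzmann equation across the membrane and
#' the adjacent diffuse layer, taken from the Donnan plateau (zero field) to
#' the outer Helmholtz plane at potential `psi_m`:
#' \deqn{\sigma_{md} = -\mathrm{sgn}(\psi_m-\psi_{DP})
#'   \sqrt{4 q n_0 \phi_{th} \varepsilon_m f},\quad
#'   f = \cosh\frac{\psi_m}{\phi_{th}} - \cosh\frac{\psi_{DP}}{\phi_{th}}
#'     - \frac{\psi_m-\psi_{DP}}{\phi_{th}}\sinh\frac{\psi_{DP}}{\phi_{th}}}
#' The radicand `f` is non-negative by convexity of `cosh`; tiny negative
#' floating-point values are clamped to zero. At `psi_DP = 0` the expression
#' reduces exactly to the Gouy-Chapman (Grahame) form
#' `-sqrt(8 * eps_m * kB*T * n0) * sinh(psi_m / (2*phi_th))`.
#'
#' All potentials are surface-minus-bulk, so countercharge opposes the
#' excursion of `psi_m` away from the Donnan plateau:
#' `psi_m > psi_DP` gives `sigma_md < 0` and vice versa.
#'
#' @param psi_m Potential at the outer Helmholtz plane, V. Vectorised.
#' @param psi_DP Donnan potential, V (scalar or same length as `psi_m`).
#' @param n0 Bulk per-species ion concentration, 1/m^3.
#' @param eps_m Membrane permittivity, F/m.
#' @param thermal A [thermal_state()].
#' @return Charge density, C/m^2.
#' @examples
#' n0 <- bulk_ion_concentration(1e-3)
#' membrane_diffuse_charge(0.1, 0, n0, 80 * physical_constants()$eps0)
#' @export
membrane_diffuse_charge <- function(psi_m, psi_DP, n0, eps_m,
                                    thermal = thermal_state()) {
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  phith <- thermal$phi_th
  xm <- psi_m / phith
  xd <- psi_DP / phith
  f <- cosh(xm) - cosh(xd) - (xm - xd) * sinh(xd)
  f <- pmax(f, 0) # analytic f >= 0; clamp rounding noise near psi_m = psi_DP
  -sign(psi_m - psi_DP) * sqrt(4 * .const$q * n0 * phith * eps_m * f)
}
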