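#' Proton activity at the oxide surface
#'
#' Boltzmann relation between the bulk proton activity `10^-pH` and the
#' activity at the charged surface: `aHs = 10^-pH * exp(-psi0/phi_th)`.
#' A positively charged surface (`psi0 > 0`, potentials measured surface
#' minus bulk) repels protons and lowers `aHs`.
#'
#' @param pH Bulk pH.
#' @param psi0 Oxide-surface potential relative to the electrolyte bulk, V.
#'   Vectorised.
#' @param thermal A [thermal_state()].
#' @return Dimensionless surface proton activity (strictly positive).
#' @examples
#' surface_proton_activity(3, 0) # 1e-3
#' @export
surface_proton_activity <- function(pH, psi0, thermal = thermal_state()) {
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  10^(-pH) * exp(-psi0 / thermal$phi_th)
}

#' Site-binding surface charge of an amphoteric oxide
#'
#' Closed form of the two-reaction site-binding model:
#' `sigma0 = q*Ns*(aHs^2 - Ka*Kb) / (aHs^2 + Kb*aHs + Ka*Kb)`.
#' Bounded in `(-q*Ns, +q*Ns)`, monotone increasing in the surface proton
#' activity, and zero at `aHs = sqrt(Ka*Kb)` (the point of zero charge).
#'
#' @param aHs Surface proton activity (dimensionless, positive). Vectorised.
#' @param site A [site_binding_spec()].
#' @return Surface charge density, C/m^2.
#' @examples
#' s <- site_binding_spec(Ns = 4e18, pKa = 7, pKb = 7, pH = 3)
#' oxide_surface_charge(sqrt(s$Ka * s$Kb), s) # exactly 0
#' @export
oxide_surface_charge <- function(aHs, site) {
  .assert(inherits(site, "site_binding_spec"),
          "`site` must be a site_binding_spec")
  .assert(all(aHs > 0), "`aHs` must be positive")
  .const$q * site$Ns * (aHs^2 - site$Ka * site$Kb) /
    (aHs^2 + site$Kb * aHs + site$Ka * site$Kb)
}

#' Point of zero charge of the oxide surface
#'
#' The pH at which the amphoteric surface carries no net charge (at zero
#' surface potential): `pH_pzc = (pKa + pKb) / 2`.
#'
#' @param site A [site_binding_spec()].
#' @return The pH of the point of zero charge.
#' @examples
#' point_of_zero_charge(site_binding_spec(4e18, 7, 7, 5)) # 7
#' @export
point_of_zero_charge <- function(site) {
  .assert(inherits(site, "site_binding_spec"),
          "`site` must be a site_binding_spec")
  (site$pKa + site$pKb) / 2
}

#' Diagnostic: fractional occupation of the three surface species
#'
#' Fractions of neutral (-MOH), deprotonated (-MO-) and protonated (-MOH2+)
#' hydroxyl sites at a given surface proton activity. The fractions sum to
#' one; the net charge is `q*Ns*(f_MOH2 - f_MO)` and coincides with
#' [oxide_surface_charge()].
#'
#' @inheritParams oxide_surface_charge
#' @return A tibble with columns `aHs`, `f_MOH`, `f_MO`, `f_MOH2`.
#' @export
site_fractions <- function(aHs, site) {
  .assert(inherits(site, "site_binding_spec"),
          "`site` must be a site_binding_spec")
  .assert(all(aHs > 0), "`aHs` must be positive")
  den <- aHs^2 + site$Kb * aHs + site$Ka * site$Kb
  tibble(
    aHs = aHs,
    f_MOH  = site$Kb * aHs / den,
    f_MO   = site$Ka * site$Kb / den,
    f_MOH2 = aHs^2 / den
  )
}
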