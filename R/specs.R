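#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

.assert <- function(ok, msg) if (!isTRUE(ok)) abort(msg)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Thermal state of the system
#'
#' Bundles the absolute temperature with the derived thermal voltage
#' `phi_th = kB * T / q`, the natural voltage scale of every Boltzmann factor
#' in the model.
#'
#' @param temperature Absolute temperature in kelvin. Default 300 K
#'   (room-temperature operation).
#' @return An object of class `thermal_state`: a list with `temperature` (K)
#'   and `phi_th` (V).
#' @examples
#' thermal_state()$phi_th # ~25.85 mV
#' @export
thermal_state <- function(temperature = 300) {
  .assert(.is_num1(temperature) && temperature > 0,
          "`temperature` must be a single positive number (kelvin)")
  structure(
    list(temperature = temperature,
         phi_th = .const$kB * temperature / .const$q),
    class = "thermal_state"
  )
}

#' Two-valley band structure of a 2D semiconductor
#'
#' Effective-mass description of the lowest conduction (highest valence)
#' valleys. In most transition-metal dichalcogenides the second valley lies
#' only a few `kB*T` above the first and contributes to transport, so two
#' valleys are kept; remaining valleys are neglected.
#'
#' @param carrier_type `"n"` (electrons) or `"p"` (holes).
#' @param m1_rel,m2_rel Effective masses of the first and second valley in
#'   units of the free-electron mass.
#' @param g1,g2 Valley degeneracy factors (positive integers).
#' @param dE12 Energy separation between first and second valley, eV
#'   (non-negative).
#' @return An object of class `band_structure`.
#' @examples
#' band_structure("n", 0.54, 0.58, 2, 6, 0.07) # monolayer MoS2 conduction band
#' @export
band_structure <- function(carrier_type = c("n", "p"),
                           m1_rel, m2_rel, g1, g2, dE12) {
  carrier_type <- match.arg(carrier_type)
  .assert(.is_num1(m1_rel) && m1_rel > 0, "`m1_rel` must be positive")
  .assert(.is_num1(m2_rel) && m2_rel > 0, "`m2_rel` must be positive")
  .assert(.is_num1(g1) && g1 >= 1, "`g1` must be >= 1")
  .assert(.is_num1(g2) && g2 >= 1, "`g2` must be >= 1")
  .assert(.is_num1(dE12) && dE12 >= 0, "`dE12` must be >= 0 (eV)")
  structure(
    list(carrier_type = carrier_type, m1_rel = m1_rel, m2_rel = m2_rel,
         g1 = g1, g2 = g2, dE12 = dE12),
    class = "band_structure"
  )
}

#' Sheet-charge model of the 2D channel
#'
#' Combines a band structure and a thermal state into the degenerate quantum
#' capacitance `Cdq = q^2 * D0`, where `D0` is the areal density of states.
#' `Cdq` is the upper limit of the channel's charge-voltage response reached
#' deep in degeneracy.
#'
#' @param band A [band_structure()].
#' @param thermal A [thermal_state()].
#' @return An object of class `sheet_charge_model` with fields `D0`
#'   (1/(J m^2)), `Cdq` (F/m^2), `band` and `thermal`.
#' @examples
#' sheet_charge_model(band_structure("n", 0.54, 0.58, 2, 6, 0.07))$Cdq
#' @export
sheet_charge_model <- function(band, thermal = thermal_state()) {
  .assert(inherits(band, "band_structure"), "`band` must be a band_structure")
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  D0 <- density_of_states(band, thermal)
  structure(
    list(D0 = D0, Cdq = .const$q^2 * D0, band = band, thermal = thermal),
    class = "sheet_charge_model"
  )
}

#' Amphoteric site-binding specification of the barrier-oxide surface
#'
#' Describes protonation/deprotonation equilibria of surface hydroxyl groups
#' (-MOH2+ <-> -MOH <-> -MO-) through the total site density and the two
#' dissociation constants, plus the bulk pH of the electrolyte.
#'
#' @param Ns Total surface hydroxyl site density, 1/m^2 (non-negative;
#'   `Ns = 0` describes a fully functionalized, chemically inert surface).
#' @param pKa,pKb Dissociation constants on the -log10 scale
#'   (`Ka = 10^-pKa`, `Kb = 10^-pKb`), dimensionless molar activities.
#' @param pH Bulk pH of the solution, so the bulk proton activity is
#'   `10^-pH`.
#' @return An object of class `site_binding_spec` with fields `Ns`, `pKa`,
#'   `pKb`, `Ka`, `Kb`, `pH`.
#' @examples
#' site_binding_spec(Ns = 4e18, pKa = 7, pKb = 7, pH = 5)
#' @export
site_binding_spec <- function(Ns, pKa, pKb, pH) {
  .assert(.is_num1(Ns) && Ns >= 0, "`Ns` must be >= 0 (1/m^2)")
  .assert(.is_num1(pKa), "`pKa` must be a single number")
  .assert(.is_num1(pKb), "`pKb` must be a single number")
  .assert(.is_num1(pH), "`pH` must be a single number")
  structure(
    list(Ns = Ns, pKa = pKa, pKb = pKb,
         Ka = 10^(-pKa), Kb = 10^(-pKb), pH = pH),
    class = "site_binding_spec"
  )
}

#' Electrolyte specification
#'
#' Ionic strength and dielectric description of a symmetric 1:1 electrolyte,
#' plus the Stern-layer capacitance of the oxide-electrolyte interface.
#' The number concentration of each ionic species is `n0 = N_A * i0` (with
#' mol/L converted to mol/m^3).
#'
#' @param i0 Ionic molar concentration, mol/L.
#' @param eps_w_rel Relative permittivity of the aqueous electrolyte
#'   (default 80).
#' @param eps_m_rel Relative permittivity inside the ion-permeable membrane;
#'   defaults to `eps_w_rel` (macromolecule layer dilute enough not to
#'   perturb the solvent dielectric).
#' @param C_stern Stern capacitance, F/m^2 (default 0.20 F/m^2
#'   = 20 uF/cm^2).
#' @param thermal A [thermal_state()].
#' @return An object of class `electrolyte_spec` with SI fields `i0`
#'   (mol/L), `n0` (1/m^3), `eps_w`, `eps_m` (F/m), `C_stern` (F/m^2) and
#'   `thermal`.
#' @examples
#' electrolyte_spec(i0 = 1e-3)$n0 # 1 mM -> 6.022e23 ions/m^3
#' @export
electrolyte_spec <- function(i0, eps_w_rel = 80, eps_m_rel = eps_w_rel,
                             C_stern = 0.20, thermal = thermal_state()) {
  .assert(.is_num1(i0) && i0 >= 0, "`i0` must be >= 0 (mol/L)")
  .assert(.is_num1(eps_w_rel) && eps_w_rel > 0, "`eps_w_rel` must be positive")
  .assert(.is_num1(eps_m_rel) && eps_m_rel > 0, "`eps_m_rel` must be positive")
  .assert(.is_num1(C_stern) && C_stern > 0, "`C_stern` must be positive (F/m^2)")
  .assert(inherits(thermal, "thermal_state"), "`thermal` must be a thermal_state")
  structure(
    list(i0 = i0, n0 = bulk_ion_concentration(i0),
         eps_w = eps_w_rel * .const$eps0, eps_m = eps_m_rel * .const$eps0,
         C_stern = C_stern, thermal = thermal),
    class = "electrolyte_spec"
  )
}

#' Ion-permeable membrane specification
#'
#' The layer of receptor-target macromolecules next to the oxide is treated
#' as a uniform volumetric fixed charge `Nm` (signed, 1/m^3). `Nm` is either
#' given directly (`fixed_Nm` mode) or derived from Langmuir equilibrium
#' occupancy of surface receptors (`langmuir` mode), in which case the
#' receptor density `Nr`, target concentration `Nt`, binding constant `Kc`,
#' membrane thickness `hm`, and the signed number of fundamental charges per
#' bound macromolecule `kq` must all be supplied. Supplying both `Nm` and
#' Langmuir parameters is a validation error.
#'
#' @param Nm Fixed membrane charge concentration, 1/m^3 (signed; carries the
#'   sign of the macromolecule charge).
#' @param Nr Receptor surface density, 1/m^2.
#' @param Nt Target molar concentration, mol/L.
#' @param Kc Binding constant, L/mol.
#' @param hm Membrane thickness, m (must be positive in Langmuir mode).
#' @param kq Signed number of fundamental charges per bound macromolecule
#'   (e.g. from a protein protonation-state calculation; positive below the
#'   isoelectric point, negative above it).
#' @return An object of class `membrane_spec` with field `mode` equal to
#'   `"fixed_Nm"` or `"langmuir"`.
#' @examples
#' membrane_spec(Nm = 0) # buffer only, no bound charge
#' membrane_spec(Nr = 2.3e17, Nt = 100e-15, Kc = 1e13, hm = 5e-9, kq = 22.3)
#' @export
membrane_spec <- function(Nm = NULL, Nr = NULL, Nt = NULL, Kc = NULL,
                          hm = NULL, kq = NULL) {
  langmuir_args <- list(Nr = Nr, Nt = Nt, Kc = Kc, hm = hm, kq = kq)
  has_langmuir <- !vapply(langmuir_args, is.null, logical(1))
  if (!is.null(Nm) && any(has_langmuir)) {
    abort(paste0(
      "conflicting membrane description: give either a fixed `Nm` or the ",
      "Langmuir parameters (", paste(names(langmuir_args)[has_langmuir],
                                     collapse = ", "), "), not both"))
  }
  if (!is.null(Nm)) {
    .assert(.is_num1(Nm), "`Nm` must be a single finite number (1/m^3)")
    return(structure(list(mode = "fixed_Nm", Nm = Nm), class = "membrane_spec"))
  }
  if (!all(has_langmuir)) {
    abort(paste0("incomplete Langmuir membrane: missing ",
                 paste(names(langmuir_args)[!has_langmuir], collapse = ", ")))
  }
  .assert(.is_num1(Nr) && Nr >= 0, "`Nr` must be >= 0 (1/m^2)")
  .assert(.is_num1(Nt) && Nt >= 0, "`Nt` must be >= 0 (mol/L)")
  .assert(.is_num1(Kc) && Kc >= 0, "`Kc` must be >= 0 (L/mol)")
  .assert(.is_num1(hm) && hm > 0, "`hm` must be positive (m); a zero-thickness membrane is degenerate")
  .assert(.is_num1(kq), "`kq` must be a single finite number")
  structure(list(mode = "langmuir", Nr = Nr, Nt = Nt, Kc = Kc,
                 hm = hm, kq = kq),
            class = "membrane_spec")
}

#' Device geometry and gate-stack parameters
#'
#' Double-gated device: the liquid gate couples through the top (barrier)
#' oxide and the substrate back gate through the buried oxide. Oxide
#' capacitances per unit area are derived as `C = eps / t`.
#'
#' @param W,L Channel width and length, m.
#' @param t_tox,t_box Top (barrier) and back (buried) oxide thickness, m.
#' @param eps_tox_rel,eps_box_rel Relative permittivities of the two oxides.
#' @param Vgo,Vbo Liquid-gate and back-gate offset voltages, V. These absorb
#'   electrode/channel work-function differences and fixed interface charge.
#' @param mu Carrier effective mobility, m^2/(V s); constant (diffusive
#'   transport, no field dependence).
#' @param sheet A [sheet_charge_model()] for the channel.
#' @return An object of class `device_params` including derived `C_tox`,
#'   `C_box`, `C_tb` (F/m^2).
#' @examples
#' dev <- device_params(W = 20e-6, L = 5e-6, t_tox = 30e-9, eps_tox_rel = 25,
#'                      t_box = 270e-9, eps_box_rel = 3.9, Vgo = 0.48,
#'                      Vbo = 0, mu = 20e-4,
#'                      sheet = sheet_charge_model(
#'                        band_structure("n", 0.54, 0.58, 2, 6, 0.07)))
#' dev$C_tb
#' @export
device_params <- function(W, L, t_tox, eps_tox_rel, t_box, eps_box_rel,
                          Vgo = 0, Vbo = 0, mu, sheet) {
  .assert(.is_num1(W) && W > 0, "`W` must be positive (m)")
  .assert(.is_num1(L) && L > 0, "`L` must be positive (m)")
  .assert(.is_num1(t_tox) && t_tox > 0, "`t_tox` must be positive (m)")
  .assert(.is_num1(t_box) && t_box > 0, "`t_box` must be positive (m)")
  .assert(.is_num1(eps_tox_rel) && eps_tox_rel > 0, "`eps_tox_rel` must be positive")
  .assert(.is_num1(eps_box_rel) && eps_box_rel > 0, "`eps_box_rel` must be positive")
  .assert(.is_num1(Vgo), "`Vgo` must be a single number (V)")
  .assert(.is_num1(Vbo), "`Vbo` must be a single number (V)")
  .assert(.is_num1(mu) && mu > 0, "`mu` must be positive (m^2/(V s))")
  .assert(inherits(sheet, "sheet_charge_model"),
          "`sheet` must be a sheet_charge_model")
  C_tox <- eps_tox_rel * .const$eps0 / t_tox
  C_box <- eps_box_rel * .const$eps0 / t_box
  structure(
    list(W = W, L = L, t_tox = t_tox, t_box = t_box,
         eps_tox = eps_tox_rel * .const$eps0,
         eps_box = eps_box_rel * .const$eps0,
         C_tox = C_tox, C_box = C_box, C_tb = C_tox + C_box,
         Vgo = Vgo, Vbo = Vbo, mu = mu, sheet = sheet),
    class = "device_params"
  )
}

#' Full study configuration
#'
#' Bundle of device, electrolyte, site-binding and membrane specifications —
#' everything needed to solve the interface electrostatics and run bias
#' sweeps. An optional list of sweep definitions drives [run_study()].
#'
#' @param device A [device_params()].
#' @param electrolyte An [electrolyte_spec()].
#' @param site_binding A [site_binding_spec()].
#' @param membrane A [membrane_spec()].
#' @param sweeps Optional list of sweep definitions (see [run_study()]).
#' @return An object of class `biofet_config`.
#' @seealso [preset_table1()] for the reference MoS2 device.
#' @export
biofet_config <- function(device, electrolyte, site_binding, membrane,
                          sweeps = list()) {
  .assert(inherits(device, "device_params"), "`device` must be a device_params")
  .assert(inherits(electrolyte, "electrolyte_spec"),
          "`electrolyte` must be an electrolyte_spec")
  .assert(inherits(site_binding, "site_binding_spec"),
          "`site_binding` must be a site_binding_spec")
  .assert(inherits(membrane, "membrane_spec"), "`membrane` must be a membrane_spec")
  structure(
    list(device = device, electrolyte = electrolyte,
         site_binding = site_binding, membrane = membrane, sweeps = sweeps),
    class = "biofet_config"
  )
}

#' @export
print.biofet_config <- function(x, ...) {
  d <- x$device
  cat("<biofet_config>\n")
  cat(sprintf("  device:      W/L = %g/%g um, t_tox = %g nm, t_box = %g nm, %s-type\n",
              d$W * 1e6, d$L * 1e6, d$t_tox * 1e9, d$t_box * 1e9,
              d$sheet$band$carrier_type))
  cat(sprintf("  electrolyte: i0 = %g mM, C_stern = %g uF/cm^2, T = %g K\n",
              x$electrolyte$i0 * 1e3, x$electrolyte$C_stern * 1e2,
              x$electrolyte$thermal$temperature))
  cat(sprintf("  surface:     Ns = %g cm^-2, pKa = %g, pKb = %g, pH = %g\n",
              x$site_binding$Ns * 1e-4, x$site_binding$pKa, x$site_binding$pKb,
              x$site_binding$pH))
  if (x$membrane$mode == "fixed_Nm") {
    cat(sprintf("  membrane:    fixed Nm = %g cm^-3\n", x$membrane$Nm * 1e-6))
  } else {
    cat(sprintf("  membrane:    Langmuir, Nr = %g cm^-2, Nt = %g M, Kc = %g 1/M, hm = %g nm, kq = %g\n",
                x$membrane$Nr * 1e-4, x$membrane$Nt, x$membrane$Kc,
                x$membrane$hm * 1e9, x$membrane$kq))
  }
  invisible(x)
}
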