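#' Oxide capacitances per unit area
#'
#' `C_tox = eps_tox / t_tox`, `C_box = eps_box / t_box`, and their parallel
#' sum `C_tb = C_tox + C_box` (the total geometric gate capacitance seen by
#' the channel).
#'
#' @param dev A [device_params()].
#' @return A one-row tibble with columns `C_tox`, `C_box`, `C_tb` (F/m^2).
#' @examples
#' dev <- device_params(20e-6, 5e-6, 30e-9, 25, 270e-9, 3.9, 0.48, 0, 20e-4,
#'                      sheet_charge_model(band_structure("n", 0.54, 0.58, 2, 6, 0.07)))
#' oxide_capacitances(dev)
#' @export
oxide_capacitances <- function(dev) {
  .assert(inherits(dev, "device_params"), "`dev` must be a device_params")
  tibble(C_tox = dev$C_tox, C_box = dev$C_box, C_tb = dev$C_tb)
}

# gate-overdrive terms of the channel electrostatics; the electrolyte drop
# psi0 (surface minus bulk) ADDS to the liquid-gate potential: a positively
# charged interface pulls the n-channel towards accumulation and lowers Vth,
# reproducing the observed pH and macromolecule-charge response directions
.channel_residual_fun <- function(Vlg, Vb, phi, psi0, dev) {
  sheet <- dev$sheet
  a_top <- Vlg - dev$Vgo + psi0 - phi
  a_back <- Vb - dev$Vbo - phi
  function(phi_ch) {
    sheet_charge(phi_ch, sheet) +
      dev$C_tox * (a_top + phi_ch) + dev$C_box * (a_back + phi_ch)
  }
}

#' Channel chemical potential at one quasi-Fermi level
#'
#' Solves the double-gate charge balance for the channel chemical potential
#' `phi_ch` at quasi-Fermi potential `phi` (`phi = Vs` at the source,
#' `phi = Vd` at the drain):
#' \deqn{\sigma_{2D}(\phi_{ch}) + C_{tox}(V_{lg}-V_{go}+\psi_0-\phi+\phi_{ch})
#'   + C_{box}(V_b-V_{bo}-\phi+\phi_{ch}) = 0.}
#' The residual is strictly increasing in `phi_ch` (the sheet charge is
#' non-decreasing and the capacitive term is linear), so the root is unique.
#' The equation depends only on voltage differences: shifting `Vlg`, `Vb`
#' and `phi` by a common constant leaves `phi_ch` unchanged.
#'
#' @param Vlg Liquid-gate voltage, V.
#' @param Vb Back-gate voltage, V.
#' @param phi Quasi-Fermi potential of the evaluation point, V.
#' @param psi0 Electrolyte surface potential from
#'   [solve_surface_potentials()], V (or a `biofet_interface`).
#' @param dev A [device_params()].
#' @param tol_sigma Residual tolerance, C/m^2.
#' @return The channel chemical potential, V.
#' @export
solve_channel_potential <- function(Vlg, Vb, phi, psi0, dev,
                                    tol_sigma = 1e-12) {
  .assert(inherits(dev, "device_params"), "`dev` must be a device_params")
  if (inherits(psi0, "biofet_interface")) psi0 <- psi0$psi0
  h <- .channel_residual_fun(Vlg, Vb, phi, psi0, dev)
  sol <- .solve_monotone(h, lo = -2, hi = 2, limit = 50, tol_f = tol_sigma,
                         what = "channel potential")
  sol$root
}

# scalar bias-point solve: phi_ch at source and drain, u values, current
.bias_point <- function(Vlg, Vb, Vs, Vd, psi0, dev, tol_sigma = 1e-12) {
  sheet <- dev$sheet
  phi_ch_s <- solve_channel_potential(Vlg, Vb, Vs, psi0, dev, tol_sigma)
  phi_ch_d <- solve_channel_potential(Vlg, Vb, Vd, psi0, dev, tol_sigma)
  us <- u_value(phi_ch_s, sheet)
  ud <- u_value(phi_ch_d, sheet)
  phith <- sheet$thermal$phi_th
  k <- dev$mu * (dev$W / dev$L) * sheet$Cdq * phith^2
  cr <- 1 + sheet$Cdq / dev$C_tb
  Ids <- if (sheet$band$carrier_type == "n") {
    k * (cr * (us^2 - ud^2) / 2 + (exp(-ud) - exp(-us)))
  } else {
    k * (cr * (ud^2 - us^2) / 2 + (exp(-us) - exp(-ud)))
  }
  list(phi_ch_s = phi_ch_s, phi_ch_d = phi_ch_d, us = us, ud = ud, Ids = Ids)
}

#' Drain current at a single bias point
#'
#' Closed-form drift-diffusion drain current of the double-gated 2D channel.
#' For an n-type device
#' \deqn{I_{ds} = \mu_n \frac{W}{L} C_{dq} \phi_{th}^2
#'   \left[\left(1+\frac{C_{dq}}{C_{tb}}\right)\frac{u_s^2-u_d^2}{2}
#'   + (e^{-u_d} - e^{-u_s})\right]}
#' with `us`, `ud` evaluated from the channel electrostatics at the source
#' and drain quasi-Fermi levels. Vanishes identically at `Vds = 0` and has
#' the sign of `Vds` for n-type.
#'
#' @param Vlg,Vb,Vs,Vd Terminal voltages, V (vectorised, recycled).
#' @param dev A [device_params()].
#' @param interface A `biofet_interface` (or a numeric `psi0` in volts).
#' @param tol_sigma Residual tolerance of the channel solves, C/m^2.
#' @return Drain current(s), A.
#' @export
drain_current <- function(Vlg, Vb = 0, Vs = 0, Vd, dev, interface,
                          tol_sigma = 1e-12) {
  psi0 <- if (inherits(interface, "biofet_interface")) interface$psi0 else interface
  n <- max(length(Vlg), length(Vb), length(Vs), length(Vd))
  Vlg <- rep_len(Vlg, n); Vb <- rep_len(Vb, n)
  Vs <- rep_len(Vs, n); Vd <- rep_len(Vd, n)
  vapply(seq_len(n), function(i) {
    .bias_point(Vlg[i], Vb[i], Vs[i], Vd[i], psi0, dev, tol_sigma)$Ids
  }, numeric(1))
}

.iv_tibble <- function(Vlg, Vb, Vs, Vd, psi0, dev, tol_sigma = 1e-12) {
  n <- length(Vlg)
  pts <- purrr::map(seq_len(n), function(i) {
    .bias_point(Vlg[i], Vb[i], Vs[i], Vd[i], psi0, dev, tol_sigma)
  })
  tibble(
    Vlg = Vlg, Vb = Vb, Vs = Vs, Vd = Vd,
    psi0 = rep(psi0, n),
    phi_ch_s = purrr::map_dbl(pts, "phi_ch_s"),
    phi_ch_d = purrr::map_dbl(pts, "phi_ch_d"),
    us = purrr::map_dbl(pts, "us"),
    ud = purrr::map_dbl(pts, "ud"),
    Ids = purrr::map_dbl(pts, "Ids")
  )
}

.as_iv <- function(df, config, interface) {
  attr(df, "WL") <- config$device$W / config$device$L
  attr(df, "interface") <- interface
  class(df) <- c("biofet_iv", class(df))
  df
}

# coarse scan to centre the default gate sweep on the turn-on region
.auto_vlg_grid <- function(config, interface, vds, vb, vs, n = 201,
                           below = 0.4, above = 1.1) {
  dev <- config$device
  i_target <- 1e-7 * dev$W / dev$L
  for (half_span in c(3, 6)) {
    coarse_v <- seq(dev$Vgo - interface$psi0 - half_span,
                    dev$Vgo - interface$psi0 + half_span, length.out = 61)
    ids <- drain_current(coarse_v, vb, vs, vs + vds, dev, interface)
    hit <- which(ids >= i_target)
    if (length(hit) > 0 && hit[1] > 1) {
      vth_rough <- coarse_v[hit[1]]
      return(seq(vth_rough - below, vth_rough + above, length.out = n))
    }
  }
  abort("could not locate the turn-on region automatically; supply `vlg` explicitly")
}

#' Transfer characteristic (Ids versus liquid-gate voltage)
#'
#' Solves the interface electrostatics once (the electrolyte drop is
#' bias-independent), then the channel electrostatics and drain current at
#' every gate bias. With `vlg = NULL` the sweep window is centred on the
#' turn-on region by a coarse pre-scan.
#'
#' @param config A [biofet_config()].
#' @param vlg Numeric vector of liquid-gate voltages, V, or `NULL` for an
#'   automatic 201-point grid bracketing threshold.
#' @param vds Drain-source voltage, V (default 1).
#' @param vb Back-gate voltage, V.
#' @param vs Source voltage, V (reference terminal, default 0).
#' @param interface Optional precomputed `biofet_interface` to reuse.
#' @param tol_sigma Residual tolerance of the nonlinear solves, C/m^2.
#' @return A tibble of class `biofet_iv` with one row per bias point and
#'   columns `Vlg`, `Vb`, `Vs`, `Vd`, `psi0`, `phi_ch_s`, `phi_ch_d`, `us`,
#'   `ud`, `Ids`.
#' @examples
#' cfg <- preset_table1(pH = 5)
#' iv <- transfer_sweep(cfg, vlg = seq(0, 1, 0.25))
#' iv$Ids
#' @export
transfer_sweep <- function(config, vlg = NULL, vds = 1, vb = 0, vs = 0,
                           interface = NULL, tol_sigma = 1e-12) {
  .assert(inherits(config, "biofet_config"), "`config` must be a biofet_config")
  if (is.null(interface)) {
    interface <- solve_surface_potentials(config$site_binding,
                                          config$electrolyte, config$membrane,
                                          tol_sigma = tol_sigma)
  }
  if (is.null(vlg)) {
    vlg <- .auto_vlg_grid(config, interface, vds, vb, vs)
  }
  .assert(is.numeric(vlg) && length(vlg) >= 1, "`vlg` must be a non-empty numeric vector")
  df <- .iv_tibble(vlg, rep_len(vb, length(vlg)), rep_len(vs, length(vlg)),
                   rep_len(vs + vds, length(vlg)),
                   interface$psi0, config$device, tol_sigma)
  .as_iv(df, config, interface)
}

#' Output characteristic (Ids versus drain-source voltage)
#'
#' @param config A [biofet_config()].
#' @param vds Numeric vector of drain-source voltages, V.
#' @param vlg Liquid-gate voltage, V.
#' @param vb Back-gate voltage, V.
#' @param vs Source voltage, V.
#' @param interface Optional precomputed `biofet_interface`.
#' @param tol_sigma Residual tolerance, C/m^2.
#' @return A tibble of class `biofet_iv` (see [transfer_sweep()]).
#' @export
output_sweep <- function(config, vds, vlg, vb = 0, vs = 0,
                         interface = NULL, tol_sigma = 1e-12) {
  .assert(inherits(config, "biofet_config"), "`config` must be a biofet_config")
  .assert(is.numeric(vds) && length(vds) >= 1, "`vds` must be a non-empty numeric vector")
  if (is.null(interface)) {
    interface <- solve_surface_potentials(config$site_binding,
                                          config$electrolyte, config$membrane,
                                          tol_sigma = tol_sigma)
  }
  n <- length(vds)
  df <- .iv_tibble(rep_len(vlg, n), rep_len(vb, n), rep_len(vs, n), vs + vds,
                   interface$psi0, config$device, tol_sigma)
  .as_iv(df, config, interface)
}
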