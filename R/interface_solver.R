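#' Solve the oxide-electrolyte interface electrostatics
#'
#' Finds the surface potential `psi0` (oxide surface relative to electrolyte
#' bulk) and the outer-Helmholtz-plane potential `psi_m` that satisfy charge
#' neutrality between the site-binding surface charge and the membrane plus
#' diffuse-layer countercharge, with the Stern capacitance linking the two
#' planes:
#' \deqn{\sigma_0(\psi_0) + \sigma_{md}(\psi_m) = 0,\qquad
#'       \psi_m = \psi_0 - \sigma_0(\psi_0)/C_{Stern}.}
#' The channel sheet charge is neglected in this balance (it is orders of
#' magnitude smaller than the interfacial charges), which decouples the
#' electrolyte drop from the transistor bias — `psi0` depends only on pH,
#' membrane charge and ionic strength, not on the terminal voltages.
#'
#' The Stern substitution reduces the system to one strictly decreasing
#' scalar residual `g(psi0)`, so the root is unique; it is located by
#' bracketed bisection (default) or safeguarded Newton, both run to the
#' charge-residual tolerance.
#'
#' @param site A [site_binding_spec()].
#' @param elec An [electrolyte_spec()].
#' @param mem A [membrane_spec()].
#' @param tol_sigma Absolute tolerance on the charge-neutrality residual,
#'   C/m^2. Default `1e-12`, far below the physical charge scale
#'   (`q*Ns` is of order 0.1-1 C/m^2).
#' @param method `"bisection"` (default) or `"newton"`. Both are safeguarded
#'   by the same expanding bracket and agree to better than 1e-10 V.
#' @param psi_limit Physical search limit for `|psi0|`, V. Exceeding it
#'   without a sign change raises an error.
#' @return An object of class `biofet_interface`: a list with elements
#'   `psi0`, `psi_m`, `psi_DP` (V), `sigma0`, `sigma_md`, `residual`
#'   (C/m^2), `Nm` (1/m^3), `iterations`, `method`.
#' @examples
#' sol <- solve_surface_potentials(
#'   site_binding_spec(Ns = 4e18, pKa = 7, pKb = 7, pH = 5),
#'   electrolyte_spec(i0 = 1e-3),
#'   membrane_spec(Nm = 0))
#' sol$psi0
#' @export
solve_surface_potentials <- function(site, elec, mem, tol_sigma = 1e-12,
                                     method = c("bisection", "newton"),
                                     psi_limit = 5) {
  .assert(inherits(site, "site_binding_spec"), "`site` must be a site_binding_spec")
  .assert(inherits(elec, "electrolyte_spec"), "`elec` must be an electrolyte_spec")
  .assert(inherits(mem, "membrane_spec"), "`mem` must be a membrane_spec")
  method <- match.arg(method)
  thermal <- elec$thermal
  Nm <- membrane_charge_concentration(mem)
  if (elec$n0 <= 0 && Nm != 0) {
    abort("zero ionic strength with a charged membrane: the Donnan potential is undefined")
  }
  psi_DP <- donnan_potential(Nm, elec$n0, thermal)

  sigma0_of <- function(psi0) {
    oxide_surface_charge(surface_proton_activity(site$pH, psi0, thermal), site)
  }
  psi_m_of <- function(psi0, s0) psi0 - s0 / elec$C_stern
  g <- function(psi0) {
    s0 <- sigma0_of(psi0)
    s0 + membrane_diffuse_charge(psi_m_of(psi0, s0), psi_DP, elec$n0,
                                 elec$eps_m, thermal)
  }

  sol <- .solve_monotone(g, lo = -2, hi = 2, limit = psi_limit,
                         tol_f = tol_sigma, method = method,
                         what = "charge-neutral surface potential")
  psi0 <- sol$root
  s0 <- sigma0_of(psi0)
  psi_m <- psi_m_of(psi0, s0)
  smd <- membrane_diffuse_charge(psi_m, psi_DP, elec$n0, elec$eps_m, thermal)
  structure(
    list(psi0 = psi0, psi_m = psi_m, psi_DP = psi_DP,
         sigma0 = s0, sigma_md = smd, residual = s0 + smd, Nm = Nm,
         iterations = sol$iterations, method = method,
         tol_sigma = tol_sigma),
    class = "biofet_interface"
  )
}

#' @export
print.biofet_interface <- function(x, ...) {
  cat("<biofet_interface>\n")
  cat(sprintf("  psi0 = %.6g V, psi_m = %.6g V, psi_DP = %.6g V\n",
              x$psi0, x$psi_m, x$psi_DP))
  cat(sprintf("  sigma0 = %.6g C/m^2, sigma_md = %.6g C/m^2, residual = %.3g C/m^2\n",
              x$sigma0, x$sigma_md, x$residual))
  cat(sprintf("  %d %s iterations\n", x$iterations, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interface solution into a long tibble
#'
#' @param x A `biofet_interface` object.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @method tidy biofet_interface
#' @export
tidy.biofet_interface <- function(x, ...) {
  tibble(
    quantity = c("psi0", "psi_m", "psi_DP", "sigma0", "sigma_md", "residual", "Nm"),
    value = c(x$psi0, x$psi_m, x$psi_DP, x$sigma0, x$sigma_md, x$residual, x$Nm),
    unit = c("V", "V", "V", "C/m^2", "C/m^2", "C/m^2", "1/m^3")
  )
}

#' One-row summary of an interface solution
#'
#' @param x A `biofet_interface` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance biofet_interface
#' @export
glance.biofet_interface <- function(x, ...) {
  tibble(psi0 = x$psi0, psi_m = x$psi_m, psi_DP = x$psi_DP,
         sigma0 = x$sigma0, sigma_md = x$sigma_md, residual = x$residual,
         Nm = x$Nm, iterations = x$iterations, method = x$method)
}

#' Electrolyte potential drop across a pH grid
#'
#' Solves the interface electrostatics at each pH in `pH_grid` (input order
#' preserved) and returns the per-pH surface potentials as a tibble.
#'
#' @inheritParams solve_surface_potentials
#' @param pH_grid Numeric vector of bulk pH values (non-empty).
#' @return A tibble of class `biofet_ph` with columns `pH`, `psi0`, `psi_m`,
#'   `psi_DP`, `sigma0`, `sigma_md`, `residual`, `iterations`.
#' @examples
#' electrolyte_drop_vs_ph(
#'   site_binding_spec(4e18, 7, 7, 5), electrolyte_spec(1e-3),
#'   membrane_spec(Nm = 0), pH_grid = c(3, 5, 7))
#' @export
electrolyte_drop_vs_ph <- function(site, elec, mem, pH_grid,
                                   tol_sigma = 1e-12,
                                   method = c("bisection", "newton")) {
  .assert(is.numeric(pH_grid) && length(pH_grid) >= 1,
          "`pH_grid` must be a non-empty numeric vector")
  method <- match.arg(method)
  rows <- purrr::map(pH_grid, function(ph) {
    s <- site_binding_spec(site$Ns, site$pKa, site$pKb, pH = ph)
    sol <- tryCatch(
      solve_surface_potentials(s, elec, mem, tol_sigma = tol_sigma,
                               method = method),
      error = function(e) abort(sprintf("interface solve failed at pH = %g: %s",
                                        ph, conditionMessage(e)))
    )
    tibble(pH = ph, psi0 = sol$psi0, psi_m = sol$psi_m, psi_DP = sol$psi_DP,
           sigma0 = sol$sigma0, sigma_md = sol$sigma_md,
           residual = sol$residual, iterations = sol$iterations)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("biofet_ph", class(out))
  out
}
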