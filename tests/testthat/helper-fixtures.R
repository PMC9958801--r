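# shared fixtures: the reference MoS2 device and its pieces
const <- physical_constants()

mos2_band <- band_structure("n", m1_rel = 0.54, m2_rel = 0.58,
                            g1 = 2, g2 = 6, dE12 = 0.07)
room <- thermal_state(300)
mos2_sheet <- sheet_charge_model(mos2_band, room)

# functionalized-surface streptavidin study at pH 3 (1% of bare sites)
strep_cfg <- function(Nt, kq = 22.3, pH = 3, i0 = 1e-3, Ns = 4e16) {
  preset_table1(pH = pH, i0 = i0, Ns = Ns,
                membrane = streptavidin_membrane(Nt = Nt, kq = kq))
}

# brute-force drift-diffusion current: trapezoidal integral of mu*(W/L)*
# |sigma_2D(phi_ch(phi))| d(phi) with the channel potential solved pointwise
dd_current_numeric <- function(config, Vlg, Vds, Vb = 0, Vs = 0,
                               interface = NULL, n_grid = 2000) {
  dev <- config$device
  if (is.null(interface)) {
    interface <- solve_surface_potentials(config$site_binding,
                                          config$electrolyte, config$membrane)
  }
  phi <- seq(Vs, Vs + Vds, length.out = n_grid)
  absq <- vapply(phi, function(p) {
    abs(sheet_charge(solve_channel_potential(Vlg, Vb, p, interface, dev),
                     dev$sheet))
  }, numeric(1))
  h <- diff(phi)
  dev$mu * (dev$W / dev$L) * sum((absq[-1] + absq[-n_grid]) / 2 * h)
}
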