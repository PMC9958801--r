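cfg <- preset_table1(pH = 5)
iface <- solve_surface_potentials(cfg$site_binding, cfg$electrolyte,
                                  cfg$membrane)

test_that("oxide capacitances follow eps/t and sum to C_tb", {
  caps <- oxide_capacitances(cfg$device)
  expect_equal(caps$C_tox, 25 * const$eps0 / 30e-9, tolerance = 1e-12)
  expect_equal(caps$C_tox, 7.3785e-3, tolerance = 1e-4)   # ~0.738 uF/cm^2
  expect_equal(caps$C_box, 1.2789e-4, tolerance = 1e-4)
  expect_equal(caps$C_tb, caps$C_tox + caps$C_box, tolerance = 1e-15)
  expect_error(device_params(1e-6, 1e-6, 0, 25, 1e-7, 3.9, 0, 0, 1e-3,
                             mos2_sheet), "t_tox")
})

test_that("channel potential solve meets its residual and linearised limits", {
  dev <- cfg$device
  # residual contract: plugging the root back into the charge balance
  for (vlg in c(-0.5, 0.3, 1.2)) {
    pc <- solve_channel_potential(vlg, 0, 0, iface, dev)
    h <- sheet_charge(pc, dev$sheet) +
      dev$C_tox * (vlg - dev$Vgo + iface$psi0 + pc) +
      dev$C_box * (-dev$Vbo + pc)
    expect_lt(abs(h), 1e-12)
  }

  # deep subthreshold: sheet charge negligible, capacitive divider exact
  vlg_deep <- -1.5
  pc <- solve_channel_potential(vlg_deep, 0, 0, iface, dev)
  lin <- -(dev$C_tox * (vlg_deep - dev$Vgo + iface$psi0) +
             dev$C_box * (-dev$Vbo)) / dev$C_tb
  expect_lt(abs(pc - lin) / abs(lin), 0.01)

  # gauge invariance: common shift of all terminals leaves phi_ch unchanged
  d <- 0.37
  expect_equal(solve_channel_potential(0.8 + d, 0 + d, 0 + d, iface, dev),
               solve_channel_potential(0.8, 0, 0, iface, dev),
               tolerance = 1e-9)
})

test_that("drain current vanishes at zero drain bias and grows with gate and drain", {
  dev <- cfg$device
  expect_equal(drain_current(0.8, 0, 0, 0, dev, iface), 0, tolerance = 1e-18)

  vlg <- seq(-0.2, 1.4, length.out = 33)
  ids <- drain_current(vlg, 0, 0, 1, dev, iface)
  expect_true(all(ids > 0))
  expect_true(all(diff(ids) > 0)) # monotone in Vlg at Vds = 1

  vds <- seq(0, 1.5, length.out = 31)
  ido <- drain_current(1.2, 0, 0, vds, dev, iface)
  expect_true(all(diff(ido) >= 0)) # non-decreasing in Vds
  # saturation plateau: the last decade of Vds changes the current little
  expect_lt((ido[31] - ido[21]) / ido[31], 0.05)
})

test_that("closed-form current matches brute-force drift-diffusion integration", {
  for (vds in c(0.05, 0.5, 1)) {
    closed <- drain_current(1.2, 0, 0, vds, cfg$device, iface)
    brute <- dd_current_numeric(cfg, Vlg = 1.2, Vds = vds, interface = iface)
    expect_lt(abs(closed - brute) / brute, 0.01)
  }
  # and in subthreshold
  closed_sub <- drain_current(0.25, 0, 0, 0.5, cfg$device, iface)
  brute_sub <- dd_current_numeric(cfg, Vlg = 0.25, Vds = 0.5,
                                  interface = iface)
  expect_lt(abs(closed_sub - brute_sub) / brute_sub, 0.005)
  # near threshold the closed form deviates most; stays within 1 percent
  closed_th <- drain_current(0.45, 0, 0, 0.5, cfg$device, iface)
  brute_th <- dd_current_numeric(cfg, Vlg = 0.45, Vds = 0.5, interface = iface)
  expect_lt(abs(closed_th - brute_th) / brute_th, 0.01)
})

test_that("current is gauge invariant and mirrors between n- and p-type", {
  dev <- cfg$device
  d <- -0.83
  expect_equal(drain_current(0.9 + d, d, d, 1 + d, dev, iface),
               drain_current(0.9, 0, 0, 1, dev, iface), tolerance = 1e-9)

  # p-type device with mirrored parameters and reversed terminals
  p_sheet <- sheet_charge_model(band_structure("p", 0.54, 0.58, 2, 6, 0.07),
                                room)
  p_dev <- device_params(dev$W, dev$L, dev$t_tox, 25, dev$t_box, 3.9,
                         Vgo = -dev$Vgo, Vbo = -dev$Vbo, mu = dev$mu,
                         sheet = p_sheet)
  i_n <- drain_current(0.9, 0, 0, 1, dev, iface$psi0)
  i_p <- drain_current(-0.9, 0, 0, -1, p_dev, -iface$psi0)
  expect_equal(abs(i_p), i_n, tolerance = 1e-9)
  expect_lt(i_p, 0)
})

test_that("transfer and output sweeps return aligned tidy tables", {
  iv <- transfer_sweep(cfg, vlg = seq(0, 1, 0.1), vds = 1)
  expect_s3_class(iv, "biofet_iv")
  expect_s3_class(iv, "tbl_df")
  expect_equal(nrow(iv), 11)
  expect_equal(iv$us, u_value(iv$phi_ch_s, cfg$device$sheet), tolerance = 1e-12)
  expect_equal(iv$ud, u_value(iv$phi_ch_d, cfg$device$sheet), tolerance = 1e-12)
  expect_equal(iv$Vd - iv$Vs, rep(1, 11))
  expect_equal(iv$psi0, rep(iface$psi0, 11), tolerance = 1e-12)

  # one-point grid reproduces the scalar bias solve
  one <- transfer_sweep(cfg, vlg = 0.7, vds = 1)
  expect_equal(one$Ids, drain_current(0.7, 0, 0, 1, cfg$device, iface),
               tolerance = 1e-12)

  # zero drain bias gives an all-zero current column
  flat <- transfer_sweep(cfg, vlg = seq(0, 1, 0.25), vds = 0)
  expect_true(all(flat$Ids == 0))

  ov <- output_sweep(cfg, vds = seq(0, 1, 0.25), vlg = 1)
  expect_equal(ov$Ids[1], 0, tolerance = 1e-18)
  expect_true(all(diff(ov$Ids) >= 0))
})

test_that("deep-subthreshold swing approaches the capacitive-divider limit", {
  iv <- transfer_sweep(cfg, vds = 1)
  vth <- threshold_voltage(iv)
  deep <- dplyr::filter(iv, Vlg > vth - 0.45, Vlg < vth - 0.25)
  ss <- 1 / stats::coef(stats::lm(log10(Ids) ~ Vlg, data = deep))[[2]]
  ss_ideal <- log(10) * room$phi_th * (1 + cfg$device$C_box / cfg$device$C_tox)
  expect_lt(abs(ss - ss_ideal) / ss_ideal, 0.02)
})
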