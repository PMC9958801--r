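elec_ref <- electrolyte_spec(i0 = 1e-3, thermal = room)
no_membrane <- membrane_spec(Nm = 0)

test_that("chargeless interfaces solve to exactly zero potentials", {
  # at the point of zero charge with no membrane both charges vanish
  at_pzc <- site_binding_spec(4e18, 7, 7, pH = 7)
  sol <- solve_surface_potentials(at_pzc, elec_ref, no_membrane)
  expect_equal(sol$psi0, 0, tolerance = 1e-14)
  expect_equal(sol$psi_m, 0, tolerance = 1e-14)
  expect_equal(sol$sigma0, 0, tolerance = 1e-14)
  expect_equal(sol$sigma_md, 0, tolerance = 1e-14)

  # no sites and no membrane charge
  inert <- site_binding_spec(0, 7, 7, pH = 4)
  sol2 <- solve_surface_potentials(inert, elec_ref, no_membrane)
  expect_equal(sol2$psi0, 0, tolerance = 1e-14)
  expect_equal(sol2$psi_m, 0, tolerance = 1e-14)
})

test_that("every solve meets the charge-neutrality and Stern contracts", {
  cases <- list(
    list(site = site_binding_spec(4e18, 7, 7, 3), mem = no_membrane),
    list(site = site_binding_spec(4e18, 7, 7, 10), mem = no_membrane),
    list(site = site_binding_spec(4e16, 7, 7, 3),
         mem = membrane_spec(Nm = 5.129e26)),
    list(site = site_binding_spec(0, 7, 7, 5),
         mem = membrane_spec(Nm = -5e26)),
    list(site = site_binding_spec(4e18, 6, 8, 8),
         mem = streptavidin_membrane(Nt = 1e-9, kq = -15.2))
  )
  for (cs in cases) {
    sol <- solve_surface_potentials(cs$site, elec_ref, cs$mem)
    expect_lt(abs(sol$residual), 1e-12)
    expect_equal(sol$psi0 - sol$psi_m, sol$sigma0 / elec_ref$C_stern,
                 tolerance = 1e-12)
    # sigma0 stays within its physical bounds
    expect_lt(abs(sol$sigma0), const$q * cs$site$Ns + 1e-30)
  }
})

test_that("bisection and safeguarded Newton find the same root", {
  site <- site_binding_spec(4e18, 7, 7, 3.5)
  mem <- membrane_spec(Nm = -2e26)
  a <- solve_surface_potentials(site, elec_ref, mem, method = "bisection")
  b <- solve_surface_potentials(site, elec_ref, mem, method = "newton")
  expect_lt(abs(a$psi0 - b$psi0), 1e-10)
})

test_that("pH response is monotone and bounded by the Nernst slope", {
  ph <- seq(2, 10, by = 0.5)
  tab <- electrolyte_drop_vs_ph(site_binding_spec(4e18, 7, 7, 5), elec_ref,
                                no_membrane, ph)
  expect_true(all(diff(tab$psi0) < 0)) # psi0 falls as pH rises
  slopes <- abs(diff(tab$psi0) / diff(tab$pH))
  nernst <- log(10) * room$phi_th
  expect_true(all(slopes <= nernst * (1 + 1e-9)))
  expect_true(all(abs(tab$residual) < 1e-12))
})

test_that("pH sweeps preserve the requested grid order", {
  site <- site_binding_spec(4e18, 7, 7, 5)
  fwd <- electrolyte_drop_vs_ph(site, elec_ref, no_membrane, c(3, 4, 5))
  rev <- electrolyte_drop_vs_ph(site, elec_ref, no_membrane, c(5, 4, 3))
  expect_equal(fwd$pH, c(3, 4, 5))
  expect_equal(rev$psi0, rev(fwd$psi0), tolerance = 1e-14)
  one <- electrolyte_drop_vs_ph(site_binding_spec(4e18, 7, 7, 7), elec_ref,
                                no_membrane, 7)
  expect_equal(one$psi0, 0, tolerance = 1e-14)
})

test_that("membrane charge moves the interface potentials in its own direction", {
  site <- site_binding_spec(0, 7, 7, 5) # isolate the membrane effect
  pos <- solve_surface_potentials(site, elec_ref, membrane_spec(Nm = 5e26))
  neg <- solve_surface_potentials(site, elec_ref, membrane_spec(Nm = -5e26))
  expect_gt(pos$psi0, 0)
  expect_lt(neg$psi0, 0)
  # with no surface sites the whole drop is the Donnan plateau
  # cosh cancellation flattens the residual within ~1e-9 V of the root
  expect_equal(pos$psi0, pos$psi_DP, tolerance = 1e-7)
  expect_equal(pos$psi0, -neg$psi0, tolerance = 1e-7)
})
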