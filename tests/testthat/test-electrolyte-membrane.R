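test_that("bulk ion concentration converts molarity to number density", {
  expect_identical(bulk_ion_concentration(0), 0)
  expect_equal(bulk_ion_concentration(1e-3), 6.02214076e23, tolerance = 1e-12)
  expect_equal(bulk_ion_concentration(0.1), 100 * bulk_ion_concentration(1e-3),
               tolerance = 1e-12)
})

test_that("Langmuir isotherm maps target concentration to membrane charge", {
  m0 <- streptavidin_membrane(Nt = 0, kq = 22.3)
  expect_identical(langmuir_membrane_charge(m0), 0)

  # Kc*Nt = 1: half occupancy; reference streptavidin numbers at 100 fM
  m_half <- membrane_spec(Nr = 2.3e17, Nt = 100e-15, Kc = 1e13, hm = 5e-9,
                          kq = 22.3)
  expect_equal(langmuir_membrane_charge(m_half), 22.3 * 2.3e17 / (2 * 5e-9),
               tolerance = 1e-12)
  expect_equal(langmuir_membrane_charge(m_half) * 1e-6, 5.129e20,
               tolerance = 1e-3) # cm^-3 scale

  # sign follows the molecular charge; saturation at kq*Nr/hm
  m_neg <- membrane_spec(Nr = 2.3e17, Nt = 1e-6, Kc = 1e13, hm = 5e-9,
                         kq = -15.2)
  expect_lt(langmuir_membrane_charge(m_neg), 0)
  m_sat <- membrane_spec(Nr = 2.3e17, Nt = 1, Kc = 1e13, hm = 5e-9, kq = 22.3)
  expect_equal(langmuir_membrane_charge(m_sat), 22.3 * 2.3e17 / 5e-9,
               tolerance = 1e-10)
  # monotone in Nt
  nts <- 10^seq(-15, -6, length.out = 10)
  nm <- vapply(nts, function(nt) langmuir_membrane_charge(
    membrane_spec(Nr = 2.3e17, Nt = nt, Kc = 1e13, hm = 5e-9, kq = 22.3)),
    numeric(1))
  expect_true(all(diff(nm) > 0))

  # degenerate membrane thickness rejected
  expect_error(membrane_spec(Nr = 1e17, Nt = 1e-12, Kc = 1e13, hm = 0,
                             kq = 1), "hm")
})

test_that("Donnan potential has the asinh closed form and its symmetries", {
  n0 <- bulk_ion_concentration(1e-3)
  phith <- room$phi_th
  expect_identical(donnan_potential(0, n0, room), 0)
  expect_equal(donnan_potential(2 * n0, n0, room), phith * asinh(1),
               tolerance = 1e-12)
  # odd in the membrane charge
  nm <- c(1e22, 1e24, 5e26)
  expect_equal(donnan_potential(-nm, n0, room), -donnan_potential(nm, n0, room),
               tolerance = 1e-12)
  # linearised limit for weak membrane charge (within 1% up to Nm/2n0 = 0.1)
  for (r in c(0.001, 0.01, 0.1)) {
    psi <- donnan_potential(2 * n0 * r, n0, room)
    expect_lt(abs(psi - phith * r) / abs(phith * r), 0.01)
  }
  expect_error(donnan_potential(1e20, 0, room), "Donnan")
})

test_that("membrane-diffuse charge reduces to Gouy-Chapman at zero Donnan potential", {
  n0 <- bulk_ion_concentration(1e-3)
  eps_m <- 80 * const$eps0
  phith <- room$phi_th
  psi <- seq(-0.5, 0.5, length.out = 101)
  got <- membrane_diffuse_charge(psi, 0, n0, eps_m, room)
  gc <- -sqrt(8 * eps_m * const$kB * room$temperature * n0) *
    sinh(psi / (2 * phith))
  expect_equal(got, gc, tolerance = 1e-10)
})

test_that("membrane-diffuse charge sign, zero and monotonicity contracts", {
  n0 <- bulk_ion_concentration(1e-3)
  eps_m <- 80 * const$eps0
  for (psi_dp in c(-0.2, 0, 0.174)) {
    expect_identical(
      membrane_diffuse_charge(psi_dp, psi_dp, n0, eps_m, room), 0)
    psi <- seq(psi_dp - 0.4, psi_dp + 0.4, length.out = 81)
    s <- membrane_diffuse_charge(psi, psi_dp, n0, eps_m, room)
    expect_true(all(s[psi > psi_dp] < 0))
    expect_true(all(s[psi < psi_dp] > 0))
    expect_true(all(diff(s) < 0)) # monotone decreasing in psi_m
  }
})

test_that("the radicand is non-negative on a wide potential grid", {
  phith <- room$phi_th
  grid <- expand.grid(psi_m = seq(-1, 1, length.out = 41),
                      psi_dp = seq(-1, 1, length.out = 41))
  f <- with(grid, cosh(psi_m / phith) - cosh(psi_dp / phith) -
              ((psi_m - psi_dp) / phith) * sinh(psi_dp / phith))
  expect_true(all(f >= -1e-12 * pmax(1, abs(f))))
  # and the resulting charge is finite and continuous through psi_m = psi_DP
  n0 <- bulk_ion_concentration(1e-3)
  s <- membrane_diffuse_charge(grid$psi_m, grid$psi_dp, n0, 80 * const$eps0,
                               room)
  expect_true(all(is.finite(s)))
  eps_step <- membrane_diffuse_charge(0.1 + c(-1e-9, 1e-9), 0.1, n0,
                                      80 * const$eps0, room)
  expect_lt(abs(diff(eps_step)), 1e-6)
})
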