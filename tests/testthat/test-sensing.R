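# ideal exponential transfer curve with known subthreshold swing
synthetic_curve <- function(V0 = 0.3, SS = 0.065, I0 = 1e-9,
                            vlg = seq(-0.2, 1, 0.005)) {
  structure(tibble::tibble(Vlg = vlg, Ids = I0 * 10^((vlg - V0) / SS)),
            WL = 4, class = c("biofet_iv", class(tibble::tibble())))
}

test_that("constant-current threshold matches the closed form on an exponential curve", {
  cur <- synthetic_curve()
  i_target <- 1e-7 * 4
  vth <- threshold_voltage(cur, "constant_current", Ith = 1e-7)
  expect_equal(vth, 0.3 + 0.065 * log10(i_target / 1e-9), tolerance = 1e-10)

  # translation equivariance (both methods)
  shifted <- synthetic_curve(vlg = seq(-0.2, 1, 0.005) + 0.123)
  shifted$Ids <- cur$Ids
  expect_equal(threshold_voltage(shifted), vth + 0.123, tolerance = 1e-10)

  # scaling current and criterion together leaves the threshold unchanged
  scaled <- cur
  scaled$Ids <- 10 * scaled$Ids
  expect_equal(threshold_voltage(scaled, Ith = 1e-6), vth, tolerance = 1e-10)

  # criterion never reached
  tiny <- synthetic_curve(I0 = 1e-30, vlg = seq(-0.2, 0.2, 0.01))
  expect_error(threshold_voltage(tiny), "not crossed")
})

test_that("max-gm threshold is translation equivariant and close to constant-current", {
  iv <- transfer_sweep(preset_table1(pH = 5), vds = 1)
  v_cc <- threshold_voltage(iv, "constant_current")
  v_gm <- threshold_voltage(iv, "max_gm")
  expect_lt(abs(v_cc - v_gm), 0.6)
  shifted <- iv
  shifted$Vlg <- shifted$Vlg + 0.2
  attr(shifted, "WL") <- attr(iv, "WL")
  expect_equal(threshold_voltage(shifted, "max_gm"), v_gm + 0.2,
               tolerance = 1e-9)
})

test_that("current sensitivity implements |dI|/min(I) and is symmetric", {
  a <- synthetic_curve(I0 = 1e-9)
  b <- synthetic_curve(I0 = 3e-9)
  expect_equal(current_sensitivity(a, a, 0.2), 0, tolerance = 1e-12)
  expect_equal(current_sensitivity(a, b, 0.2), 2, tolerance = 1e-9)
  expect_equal(current_sensitivity(b, a, 0.2), 2, tolerance = 1e-9)
  expect_error(current_sensitivity(a, b, 5), "outside")
})

test_that("operating regions split at threshold and at the overdrive", {
  expect_equal(classify_region(-0.5, 1, 0), "subthreshold")
  expect_equal(classify_region(0.5, 1, 0), "saturation")   # Vds > Vov
  expect_equal(classify_region(2, 0.05, 0), "linear")
  expect_equal(classify_region(c(-1, 0.5, 2), c(1, 1, 0.05), 0),
               c("subthreshold", "saturation", "linear"))
  # margin shrinks the subthreshold region (guard band below threshold)
  expect_equal(classify_region(-0.05, 1, 0, margin = 0.1), "saturation")
  expect_equal(classify_region(-0.15, 1, 0, margin = 0.1), "subthreshold")
})

test_that("membrane charge sign sets the threshold-shift direction", {
  base <- preset_table1(pH = 5, Ns = 0)
  vlg <- seq(-0.4, 1.4, length.out = 181)
  ref <- transfer_sweep(base, vlg = vlg, vds = 1)
  neg_cfg <- preset_table1(pH = 5, Ns = 0, membrane = membrane_spec(Nm = -5e26))
  pos_cfg <- preset_table1(pH = 5, Ns = 0, membrane = membrane_spec(Nm = 5e26))
  neg <- transfer_sweep(neg_cfg, vlg = vlg, vds = 1)
  pos <- transfer_sweep(pos_cfg, vlg = vlg, vds = 1)
  expect_gt(threshold_shift(ref, neg), 0)
  expect_lt(threshold_shift(ref, pos), 0)
  # shift magnitude grows with |Nm| at fixed sign
  nm_ladder <- -c(1e25, 5e25, 2e26, 8e26, 3e27)
  shifts <- vapply(nm_ladder, function(nm) {
    cfg <- preset_table1(pH = 5, Ns = 0, membrane = membrane_spec(Nm = nm))
    threshold_shift(ref, transfer_sweep(cfg, vlg = vlg, vds = 1))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("salt concentration screens the threshold response", {
  vlg <- seq(-0.4, 1.4, length.out = 181)
  shift_at <- function(i0) {
    ref <- transfer_sweep(preset_table1(pH = 5, Ns = 0, i0 = i0), vlg = vlg)
    ana <- transfer_sweep(preset_table1(pH = 5, Ns = 0, i0 = i0,
                                        membrane = membrane_spec(Nm = -5e26)),
                          vlg = vlg)
    threshold_shift(ref, ana)
  }
  expect_gt(abs(shift_at(1e-3)), abs(shift_at(0.1)))

  # a highly charged bare oxide also mitigates the shift
  shift_ns <- function(ns) {
    ref <- transfer_sweep(preset_table1(pH = 5, Ns = ns), vlg = vlg)
    ana <- transfer_sweep(preset_table1(pH = 5, Ns = ns,
                                        membrane = membrane_spec(Nm = -5e26)),
                          vlg = vlg)
    threshold_shift(ref, ana)
  }
  expect_gt(abs(shift_ns(0)), abs(shift_ns(4e18)))
})

test_that("sensing report orders the regional sensitivities and shifts", {
  rep <- sensing_report(strep_cfg(Nt = 0), strep_cfg(Nt = 100e-15))
  g <- glance(rep)
  expect_lt(g$dVth, 0) # positive molecular charge turns the device on earlier
  expect_gt(g$S_subthreshold, g$S_saturation)
  expect_gt(g$S_saturation, g$S_linear)
  expect_equal(rep$report$S,
               abs(rep$report$I_after - rep$report$I_before) /
                 pmin(rep$report$I_before, rep$report$I_after),
               tolerance = 1e-12)

  # basic solution: streptavidin is negatively charged, current decreases
  rep9 <- sensing_report(strep_cfg(Nt = 0, kq = -15.2, pH = 9),
                         strep_cfg(Nt = 100e-15, kq = -15.2, pH = 9))
  expect_gt(glance(rep9)$dVth, 0)

  # JSON serialisation round-trips the headline numbers
  f <- withr::local_tempfile(fileext = ".json")
  write_sensing_report(rep, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$dVth_V, rep$dVth, tolerance = 1e-12)
  expect_equal(j$regions[[1]]$S, rep$report$S[1], tolerance = 1e-12)
})
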