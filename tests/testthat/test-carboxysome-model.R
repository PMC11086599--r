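# Helpers: a closed single-phase configuration (no transport, no Rubisco)
# isolates the interconversion chemistry; zero_transport() builds it.
zero_transport <- function(...) {
  tp0 <- c(co2 = 0, hco3 = 0, h = 0, o2 = 0, rubp = 0)
  carboxysome_model(rubisco = NULL, transport_ext = tp0,
                    transport_shell = tp0, ...)
}

test_that("geometry gives the expected active-site concentration", {
  expect_equal(rubisco_site_concentration(224, 8, 100), 5.68,
               tolerance = 0.01 / 5.68)
  expect_identical(rubisco_site_concentration(0, 8, 100), 0)
  expect_equal(rubisco_site_concentration(112, 8, 100),
               rubisco_site_concentration(224, 8, 100) / 2)
  expect_error(rubisco_site_concentration(224, 8, -1), "positive")
})

test_that("Rubisco rate laws respect their saturation anatomy", {
  p <- rubisco_params()
  vmax <- p$kcat_c * p$e_sites_mM
  expect_identical(
    rubisco_carboxylation_rate(c(co2 = 0, o2 = 0.25, rubp = 1), p), 0)
  # RuBP-saturated, no O2, CO2 at its Km -> half of Vmax
  expect_equal(
    rubisco_carboxylation_rate(c(co2 = 0.169, o2 = 0, rubp = 1e9), p),
    vmax / 2, tolerance = 1e-6)
  # all three couplings at Km-matched inputs -> Vmax * (1/3) * (1/2)
  expect_equal(
    rubisco_carboxylation_rate(c(co2 = 0.169, o2 = 1.4, rubp = 0.040), p),
    vmax * (1 / 3) * (1 / 2), tolerance = 1e-12)
  # oxygenation mirrors it
  vmax_o <- p$kcat_o * p$e_sites_mM
  expect_identical(
    rubisco_oxygenation_rate(c(co2 = 0.1, o2 = 0, rubp = 1), p), 0)
  expect_equal(
    rubisco_oxygenation_rate(c(co2 = 0, o2 = 1.4, rubp = 1e9), p),
    vmax_o / 2, tolerance = 1e-6)
  expect_equal(
    rubisco_oxygenation_rate(c(co2 = 0.169, o2 = 1.4, rubp = 0.040), p),
    vmax_o * (1 / 3) * (1 / 2), tolerance = 1e-12)
  # carboxylation never exceeds kcat_c * E
  set.seed(4)
  for (i in 1:20) {
    st <- c(co2 = runif(1, 0, 50), o2 = runif(1, 0, 5), rubp = runif(1, 0, 50))
    expect_lt(rubisco_carboxylation_rate(st, p), vmax)
  }
})

test_that("transport flux is first-order, symmetric and validated", {
  tp <- c(co2 = 100, hco3 = 100, h = 1000, o2 = 100, rubp = 10)
  expect_identical(transport_flux("co2", 2, 2, tp), 0)
  expect_identical(transport_flux("rubp", 5, 1, c(rubp = 0)), 0)
  expect_equal(transport_flux("hco3", 8, 2, tp),
               2 * transport_flux("hco3", 5, 2, tp))
  expect_error(transport_flux("pga", 1, 0, tp), "No transport coefficient")
})

test_that("derivatives honour conservation and detailed balance", {
  # all-zero dynamic state against an all-zero boundary
  m0 <- carboxysome_model(external = c(co2 = 0, hco3 = 0, h = 0, o2 = 0,
                                       rubp = 0))
  st0 <- setNames(rep(0, 10), names(carboxysome_derivatives(
    setNames(rep(0, 10), c(paste0(c("co2", "hco3", "h", "o2", "rubp"), "_u"),
                           paste0(c("co2", "hco3", "h", "o2", "rubp"), "_c"))),
    m0)))
  expect_true(all(carboxysome_derivatives(st0, m0) == 0))

  # closed compartments without Rubisco conserve inorganic carbon
  mc <- zero_transport()
  set.seed(7)
  for (i in 1:10) {
    st <- setNames(runif(10, 0, 10), names(st0))
    d <- carboxysome_derivatives(st, mc)
    expect_equal(d[["co2_u"]] + d[["hco3_u"]], 0, tolerance = 1e-12)
    expect_equal(d[["co2_c"]] + d[["hco3_c"]], 0, tolerance = 1e-12)
  }

  # chemical equilibrium is a fixed point for any CA factor
  keq <- 0.05 / 100
  for (caf in c(1, 1e3, 1e5)) {
    m <- zero_transport(
      ca_carboxysome = ca_kinetics(ca_factor = caf),
      external = c(co2 = 0, hco3 = 0, h = 0, o2 = 0, rubp = 0))
    co2 <- 0.2; hco3 <- 10; hplus <- keq * co2 / hco3
    st <- setNames(c(co2, hco3, hplus, 0.25, 0, co2, hco3, hplus, 0.25, 0),
                   names(st0))
    expect_lt(max(abs(carboxysome_derivatives(st, m))), 1e-9)
  }
  expect_error(carboxysome_derivatives(st0 - 1, m0), "nonnegative")
})

test_that("closed-system steady state recovers the k1/k2 equilibrium ratio", {
  states <- lapply(c(1, 1e3, 1e5), function(caf) {
    m <- zero_transport(ca_carboxysome = ca_kinetics(ca_factor = caf))
    solve_steady_state(m)
  })
  for (ss in states) {
    ratio <- ss[["hco3_c"]] * ss[["h_c"]] / ss[["co2_c"]]
    expect_equal(ratio, 5e-4, tolerance = 5e-7)
  }
  # identical fixed point regardless of catalytic enhancement
  expect_equal(as.numeric(states[[1]]), as.numeric(states[[3]]),
               tolerance = 1e-6)
})

test_that("modulation pinned at 1 reproduces the unregulated model", {
  # a vanishing K_half makes the Hill factor indistinguishable from 1
  pinned <- carboxysome_model(
    regulated = TRUE, hill = hill_activation(k_half_uM = 1e-12))
  unreg <- carboxysome_model(regulated = FALSE)
  s1 <- solve_steady_state(pinned)
  s2 <- solve_steady_state(unreg)
  expect_lt(max(abs(s1 - s2) / pmax(abs(s2), 1e-12)), 1e-9)
})

test_that("steady state shows CO2 elevation and closes the flux balance", {
  m <- carboxysome_model(regulated = FALSE,
                         external = c(co2 = 0.01, hco3 = 20, h = 1e-5,
                                      o2 = 0.25, rubp = 5))
  ss <- solve_steady_state(m)

  # CCM: luminal CO2 above external free CO2
  expect_gt(ss[["co2_c"]], m$external[["co2"]])

  # independent recomputation of the luminal CO2 balance from the printed
  # rate laws (not via the package's derivative assembler)
  f_act <- 1 # unregulated
  hyd <- 1e5 * 0.05 * ss[["co2_c"]] * f_act
  deh <- 1e5 * 100 * ss[["hco3_c"]] * ss[["h_c"]] * f_act
  km_c <- 0.169 * (1 + ss[["o2_c"]] / 1.4)
  vc <- 9.4 * 5.68 * ss[["co2_c"]] / (km_c + ss[["co2_c"]]) *
    ss[["rubp_c"]] / (0.040 + ss[["rubp_c"]])
  influx <- 100 * (ss[["co2_u"]] - ss[["co2_c"]])
  expect_equal(influx + (deh - hyd), vc, tolerance = 1e-7)

  # and the effective turnover stays below kcat_c
  fl <- carboxysome_fluxes(ss, m)
  expect_lt(fl$kcat_c_eff_s, 9.4)
})

test_that("a one-level sweep matches the direct solve", {
  m <- carboxysome_model(regulated = FALSE)
  sw <- run_rubp_sweep(m, rubp_levels_mM = 0.05)
  m$external[["rubp"]] <- 0.05
  ss <- solve_steady_state(m)
  expect_equal(sw$co2_c, ss[["co2_c"]], tolerance = 1e-9)
  expect_equal(sw$ph_cbx, carboxysome_pH(ss[["h_c"]]), tolerance = 1e-9)
  expect_equal(nrow(run_rubp_sweep(m, rubp_levels_mM = c(0.01, 0.1, 1))), 3L)
  expect_error(run_rubp_sweep(m, rubp_levels_mM = c(1, 0.1)), "sorted")
})

test_that("pH and RuBP speciation behave as closed forms", {
  expect_equal(carboxysome_pH(1e-5), 8)
  expect_equal(carboxysome_pH(1e-4), 7)
  ph <- 7.43
  expect_equal(carboxysome_pH(10^(-ph) * 1000), ph)
  expect_error(carboxysome_pH(0), "positive")
  expect_equal(rubp_speciation(1, pH = 6.7, pka_eff = 6.7), 0.5)
  expect_gt(rubp_speciation(1, pH = 12, pka_eff = 6.7), 0.9999)
  # frozen closed-form evaluation at pKa 6.7, pH 8
  expect_equal(rubp_speciation(1, pH = 8, pka_eff = 6.7),
               0.95227327896579609, tolerance = 1e-12)
  expect_equal(rubp_speciation(2, pH = 7, mode = "full"), 2)
})
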