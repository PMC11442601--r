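test_that("stiff solver matches the first-order singlet-oxygen closed form", {
  k <- 2.9e5
  net <- singlet_decay_network(k)
  tr <- simulate_closed(net, c(`1O2` = 1e-6), t_end = 2e-5, output_dt = 1e-6)
  cc <- trajectory_concentration(tr, "1O2", "bulk")
  expect_lt(max(abs(cc$`1O2` - 1e-6 * exp(-k * cc$time)) / 1e-6), 1e-6)
})

test_that("stiff solver matches the second-order recombination closed form", {
  k <- 5.5e9
  net <- ho_recombination_network(k)
  c0 <- 1e-6
  tr <- simulate_closed(net, c("HO." = c0), t_end = 1e-3, output_dt = 1e-4)
  cc <- trajectory_concentration(tr, "HO.", "bulk")
  # d[HO.]/dt = -2 k [HO.]^2  =>  1/c - 1/c0 = 2 k t
  analytic <- c0 / (1 + 2 * k * c0 * cc$time)
  expect_lt(max(abs(cc$`HO.` - analytic) / analytic), 1e-6)
  # and the H2O2 produced is half the HO. consumed
  h <- trajectory_concentration(tr, "H2O2", "bulk")$H2O2
  expect_equal(h, (c0 - cc$`HO.`) / 2, tolerance = 1e-6)
})

test_that("stiff solver agrees with a fixed-step RK4 reference on small sub-networks", {
  # three coupled reactions: Fenton pair + catalase, moderate stiffness
  net <- tiny_network(c(
    "19\tFe2+ + H2O2\tFe3+ + HO. + OH-\t76\tM-1 s-1\tbulk\tNA\tt",
    "20\tFe3+ + H2O2\tFe2+ + HO2. + H+\t1e-2\tM-1 s-1\tbulk\tNA\tt",
    "22\t2 H2O2 + CAT\t2 H2O + O2 + CAT\t8.5e6\tM-1 s-1\tenzymatic\tNA\tt"))
  init <- c(`Fe2+` = 4e-6, H2O2 = 1e-3, CAT = 3.2e-8)
  tr <- simulate_closed(net, init, t_end = 5, output_dt = 1)
  kin <- pefros:::compile_kinetics(net)
  f_ho2 <- superoxide_protonated_fraction(net)
  iH <- match("HO2.", kin$species); iO <- match("O2.-", kin$species)
  f <- function(t, y) {
    d <- as.vector(kin$S %*% (kin$k *
      ifelse(is.na(kin$i1), 1, y[kin$i1]) *
      ifelse(is.na(kin$i2), 1, y[kin$i2])))
    # same instantaneous acid-base repartition the model applies
    s <- d[iH] + d[iO]
    d[iH] <- f_ho2 * s; d[iO] <- (1 - f_ho2) * s
    d
  }
  y0 <- numeric(length(kin$species)); names(y0) <- kin$species
  y0[names(init)] <- init
  yref <- rk4(f, y0, 0, 5, dt = 1e-4)
  yend <- tr$concentrations[nrow(tr$concentrations) - 0, , "bulk"]
  nz <- yref > 1e-12
  expect_lt(max(abs(yend[kin$species][nz] - yref[nz]) / yref[nz]), 1e-3)
})

test_that("iron and enzyme totals are conserved through a full simulation", {
  net <- load_network()
  sc <- pef_scenario("bsa_h2o2_sod")
  sc$init["CAT"] <- 3.2e-8
  pro <- pulse_protocol(n_pulses = 3)
  tr <- simulate_pef(net, sc, protocol = pro, t_end = 70)
  vols <- tr$volumes
  total <- function(sp1, sp2 = NULL) {
    m <- tr$concentrations[, sp1, ] %*% vols
    if (!is.null(sp2)) m <- m + tr$concentrations[, sp2, ] %*% vols
    as.vector(m)
  }
  fe <- total("Fe2+", "Fe3+")
  expect_lt(max(abs(fe - fe[1])) / fe[1], 1e-5)
  sod <- total("SOD"); cat_ <- total("CAT")
  expect_lt(max(abs(sod - sod[1])) / sod[1], 1e-5)
  expect_lt(max(abs(cat_ - cat_[1])) / cat_[1], 1e-5)
})

test_that("elemental O and H balance holds on a closed sub-network", {
  # reactions that exchange nothing with the buffered species
  net <- tiny_network(c(
    "5b\t2 HO.\tH2O2\t5.5e9\tM-1 s-1\tbulk\tNA\tt",
    "16\tBSA. + O2\tBSAOO.\t5e8\tM-1 s-1\tbulk\tNA\tt"))
  tr <- simulate_closed(net, c("HO." = 1e-6, "BSA." = 1e-7, O2 = 3e-4),
                        t_end = 1e-3, output_dt = 1e-4)
  conc <- tr$concentrations[, , "bulk"]
  # O in HO., H2O2, O2 (BSAOO. carries the O2 it captured: count it)
  o_total <- conc[, "HO."] + 2 * conc[, "H2O2"] + 2 * conc[, "O2"] +
    2 * conc[, "BSAOO."]
  h_total <- conc[, "HO."] + 2 * conc[, "H2O2"]
  expect_lt(diff(range(o_total)) / o_total[1], 1e-8)
  expect_lt(diff(range(h_total)) / h_total[1], 1e-8)
})

test_that("zero initial ROS with sources off yields zero photons and derivatives", {
  net <- load_network()
  sc <- pef_scenario("pb")
  sc$init <- c(O2 = 0)
  prof <- build_current_profile(pulse_protocol(), mode = "constant",
                                amplitude = 0)
  tr <- simulate_pef(net, sc, current_profile = prof, t_end = 10,
                     compartments = "single")
  expect_true(all(tr$photon_rate == 0))
  expect_true(all(tr$cum_photons == 0))
  expect_true(all(tr$concentrations == 0))
})

test_that("scenario constructor encodes the experimental roster", {
  sc <- pef_scenario("bsa_h2o2")
  expect_equal(unname(sc$init["BSA"]), 6e-4)
  expect_equal(unname(sc$init["H2O2"]), 1e-3)
  expect_equal(unname(sc$init["Fe2+"] + sc$init["Fe3+"]), 4e-6)
  expect_equal(unname(pef_scenario("pb")$init["Fe2+"]), 0)
  expect_equal(unname(pef_scenario("bsa_h2o2_cat")$init["CAT"]), 3.2e-8)
  expect_equal(unname(pef_scenario("bsa_h2o2_sod")$init["SOD"]), 9.9e-8)
  expect_error(pef_scenario("serum"), "unknown scenario")
  expect_error(pef_scenario("bsa_xyz"), "token")
  sc$init["H2O2"] <- -1
  expect_error(simulate_pef(load_network(), sc), ">= 0")
})
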