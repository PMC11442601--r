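test_that("current profiles carry the protocol's charge", {
  pro <- pulse_protocol()
  prof <- build_current_profile(pro, sample_properties(), chamber_geometry())
  expect_equal(prof$total_charge, 0.0387, tolerance = 2e-3)
  expect_equal(prof$amplitude, 12.9, tolerance = 2e-3)
  prof2 <- build_current_profile(pro, mode = "constant", amplitude = 12.5)
  expect_equal(prof2$total_charge, 0.0375)
  prof0 <- build_current_profile(pulse_protocol(n_pulses = 0),
                                 mode = "constant", amplitude = 12.5)
  expect_equal(prof0$total_charge, 0)
  expect_true(all(prof0$current(seq(0, 100, 0.1)) == 0))
  # rectangular: on during pulses, zero between
  expect_equal(prof2$current(c(60, 60.00005, 60.0002, 60.5, 61.00005)),
               c(12.5, 12.5, 0, 0, 12.5))
})

test_that("electrode current partition satisfies Faraday bookkeeping", {
  net <- load_network()
  ch <- electrode_channels(net, "anodic")
  expect_true(all(c("1", "4", "10", "14") %in% ch$id))
  conc <- c(H2O2 = 1e-3, BSA = 0.01, "HO." = 1e-12, "HO2." = 1e-12)
  ev <- partition_anodic_current(12.5, conc, ch)
  expect_equal(96485 * sum(ch$z * ev), 12.5, tolerance = 1e-12)
  expect_true(all(partition_anodic_current(0, conc, ch) == 0))
  # single water channel takes everything when nothing else is present
  ch1 <- ch[ch$id == "1", ]
  expect_equal(unname(partition_anodic_current(12.5, c(), ch1)),
               12.5 / 96485, tolerance = 1e-9)
  # two constant channels of equal weight and z split 50/50
  ch2 <- data.frame(id = c("a", "b"), z = 1, weight = 1,
                    weight_species = NA_character_)
  ev2 <- partition_anodic_current(10, c(), ch2)
  expect_equal(unname(ev2["a"]), unname(ev2["b"]))
  expect_equal(unname(ev2["a"]), 10 / (2 * 96485), tolerance = 1e-12)
  # all weights zero while current flows is a configuration error
  ch0 <- data.frame(id = "a", z = 1, weight = 0, weight_species = NA_character_)
  expect_error(partition_anodic_current(1, c(), ch0), "configuration error")
})

test_that("simulated charge bookkeeping closes to well under 0.01 %", {
  net <- load_network()
  pro <- pulse_protocol(n_pulses = 3)
  tr <- simulate_pef(net, pef_scenario("bsa_h2o2"), protocol = pro,
                     t_end = 64)
  q <- max(tr$charge)
  expect_equal(q, theoretical_current(sample_properties(), chamber_geometry(),
                                      pro) * 3 * 100e-6, tolerance = 1e-9)
  qa <- max(tr$faraday_charge$anodic)
  qc <- max(tr$faraday_charge$cathodic)
  expect_lt(abs(qa - q) / q, 1e-4)
  expect_lt(abs(qc - q) / q, 1e-4)   # series circuit: equal at both electrodes
})

test_that("protein migration flux is linear in field and concentration", {
  smp <- sample_properties()
  fx <- bsa_migration_flux(7.35e5, smp)
  expect_equal(fx, 1.4e-8 * 7.35e5 * 0.6, tolerance = 1e-9)   # 6.17e-3
  expect_equal(fx * 3e-3, 1.85e-5, tolerance = 2e-3)  # integrates to the accumulation
  expect_equal(bsa_migration_flux(0, smp), 0)
  expect_equal(bsa_migration_flux(7.35e5, smp, bulk_concentration = 0.3),
               fx / 2)
})

test_that("electrode-layer source scaling is dimensionally consistent in delta", {
  # doubling the layer thickness halves the local concentration rate
  net <- load_network()
  sc <- pef_scenario("pb")
  pro <- pulse_protocol(n_pulses = 1)
  run <- function(delta) {
    geo <- chamber_geometry(anode_layer_thickness = delta)
    rhs <- assemble_rhs(net, geo, sample_properties(), "three_box")
    y <- numeric(length(rhs$state_names))
    names(y) <- rhs$state_names
    y[grep("^O2\\.", names(y))] <- 3e-4
    d <- rhs$func(0, y, list(I = 12.9, E = 0))[[1]]
    names(d) <- rhs$state_names
    d["HO..anode"]
  }
  expect_equal(unname(run(1e-7) / run(2e-7)), 2, tolerance = 1e-9)
})

test_that("migration accumulates protein and carried iron in the anode layer", {
  net <- load_network()
  pro <- pulse_protocol(n_pulses = 5)
  tr <- simulate_pef(net, pef_scenario("bsa"), protocol = pro, t_end = 66)
  at_end <- tr$concentrations[nrow(tr$concentrations), , ]
  expect_gt(at_end["BSA", "anode"], 10 * at_end["BSA", "bulk"])
  fe_anode <- at_end["Fe2+", "anode"] + at_end["Fe3+", "anode"]
  fe_bulk <- at_end["Fe2+", "bulk"] + at_end["Fe3+", "bulk"]
  expect_gt(fe_anode, 10 * fe_bulk)  # the catalyst rides on the protein
  # accumulated amount tracks the closed-form swept-volume estimate
  gamma_sim <- at_end["BSA", "anode"] * 1e3 * tr$geometry$anode_layer_thickness
  d5 <- sample_properties()$bsa_mobility * 7.35e5 * 5 * 100e-6
  gamma_theory <- 0.6 * d5
  expect_equal(gamma_sim, gamma_theory, tolerance = 0.15)
})
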