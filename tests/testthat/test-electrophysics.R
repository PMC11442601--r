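test_that("chamber geometry derives area and volume from printed dimensions", {
  geo <- chamber_geometry()
  expect_equal(geo$area * 1e4, 5.31, tolerance = 1e-3)
  expect_equal(geo$volume * 1e6, 1.06, tolerance = 2e-3)
  expect_error(chamber_geometry(gap = 0), "gap")
  expect_error(chamber_geometry(area = 6e-4), "0.5")
  expect_error(chamber_geometry(volume = 2e-6), "0.5")
})

test_that("field strength follows U/d with the published value", {
  geo <- chamber_geometry()
  expect_equal(field_strength(pulse_protocol(), geo), 7.35e5)
  expect_equal(field_strength(pulse_protocol(amplitude = 0), geo), 0)
  expect_equal(field_strength(pulse_protocol(amplitude = 100),
                              chamber_geometry(gap = 1e-3)), 1e5)
})

test_that("ohmic current matches the published theoretical value", {
  i <- theoretical_current(sample_properties(), chamber_geometry(),
                           pulse_protocol())
  expect_equal(signif(i, 3), 12.9)
  expect_equal(theoretical_current(sample_properties(conductivity = 1e-12),
                                   chamber_geometry(), pulse_protocol()),
               0, tolerance = 1e-6)
  i2 <- theoretical_current(
    sample_properties(conductivity = 0.01),
    chamber_geometry(gap = 1e-3, electrode_diameter = 2 * sqrt(1e-4 / pi)),
    pulse_protocol(amplitude = 100))
  expect_equal(i2, 0.1, tolerance = 1e-6)
})

test_that("electromigration displacement and anode accumulation reproduce the published estimates", {
  smp <- sample_properties(); geo <- chamber_geometry(); pro <- pulse_protocol()
  d <- electromigration_displacement(smp, pro, geo)
  expect_equal(d, 3.1e-5, tolerance = 0.01)
  expect_equal(electromigration_displacement(
    smp, pulse_protocol(amplitude = 0), geo), 0)
  # hand arithmetic mu*E*t
  expect_equal(sample_properties(bsa_mobility = 1e-8)$bsa_mobility * 1e6 * 1e-3,
               1e-5)
  gam <- accumulated_surface_amount(smp$bsa_concentration, d)
  expect_equal(gam, 1.8e-5, tolerance = 0.04)
  expect_equal(accumulated_surface_amount(0, d), 0)
  expect_equal(accumulated_surface_amount(1, 1e-6), 1e-6)
  # displacement capped at the gap
  expect_equal(electromigration_displacement(
    sample_properties(bsa_mobility = 1), pro, geo), geo$gap)
})

test_that("monolayer coverage and layer count give hundreds of layers", {
  mono <- monolayer_coverage(7e-9)
  expect_gt(mono, 3.9e-8); expect_lt(mono, 4.0e-8)
  expect_equal(monolayer_coverage(14e-9), mono / 4)
  expect_equal(monolayer_coverage(1e-9, avogadro = 6.022e23),
               2 / (sqrt(3) * 1e-18 * 6.022e23))
  n <- layer_count(1.8e-5, 4.0e-8)
  expect_equal(n, 450)
  expect_gt(n, 100)   # "hundreds of layers"
  expect_equal(layer_count(4e-8, 4e-8), 1)
  expect_equal(layer_count(0, 4e-8), 0)
  expect_error(layer_count(1, 0), "> 0")
})

test_that("adiabatic Joule heating equals energy over heat capacity times mass", {
  pro <- pulse_protocol(); geo <- chamber_geometry(); smp <- sample_properties()
  dt <- joule_heating_adiabatic(pro, 12.5, geo, smp)
  expect_equal(dt, 12.4, tolerance = 0.01)     # "circa 12"
  expect_equal(joule_heating_adiabatic(pro, 0, geo, smp), 0)
  # 100 V, 1 A, 1 s into 1 L of water
  geo1 <- chamber_geometry(gap = 0.1, electrode_diameter = 2 * sqrt(1e-2 / pi))
  pro1 <- pulse_protocol(n_pulses = 1, pulse_width = 1, period = 2,
                         amplitude = 100)
  expect_equal(joule_heating_adiabatic(pro1, 1, geo1, smp),
               100 / (998 * 1e-3 * 4180), tolerance = 1e-6)
  # exact identity: energy / (c_p * mass), any inputs
  expect_equal(joule_heating_adiabatic(pro, 7.3, geo, smp),
               pro$amplitude * 7.3 * pro$total_on_time /
                 (smp$density * geo$volume * smp$heat_capacity))
})

test_that("current-rise thermometry inverts the viscosity correlation", {
  dt <- temperature_from_current_rise(1.075, 22)
  expect_equal(dt, 3, tolerance = 0.1)         # "ca 3 C, final 25 C"
  expect_equal(22 + dt, 25, tolerance = 0.15)
  expect_equal(temperature_from_current_rise(1, 22), 0, tolerance = 1e-9)
  # exact round trip through the forward map, many temperatures
  for (t1 in c(23, 25, 30, 40, 55)) {
    r <- current_ratio_at_temperature(t1, 22)
    expect_equal(temperature_from_current_rise(r, 22), t1 - 22,
                 tolerance = 1e-5)
  }
  r30 <- water_viscosity(22) / water_viscosity(30)
  expect_equal(temperature_from_current_rise(r30, 22), 8, tolerance = 1e-6)
  expect_error(temperature_from_current_rise(0.9, 22), ">= 1")
  expect_error(temperature_from_current_rise(5, 22), "range")
  expect_error(water_viscosity(75), "range")
})

test_that("Faraday coulometry and diffusion length follow their closed forms", {
  expect_equal(faraday_amount(12.5 * 3e-3, 2), 1.94e-7, tolerance = 1e-3)
  expect_equal(faraday_amount(0, 3), 0)
  expect_equal(faraday_amount(96485, 1), 1)
  expect_error(faraday_amount(-1, 1), ">= 0")
  expect_error(faraday_amount(1, 0), ">= 1")
  expect_equal(faraday_fraction(1e-9, 96485e-9, 1), 1)
  l <- diffusion_length(2.3e-9, 1e-6)
  expect_gt(l, 1e-8); expect_lt(l, 1e-7)       # tens of nanometres
  expect_equal(diffusion_length(5, 0), 0)
  expect_equal(diffusion_length(1e-8, 1e-4), 1e-6)
})

test_that("linear scalings double with their driving input", {
  geo <- chamber_geometry(); smp <- sample_properties()
  p1 <- pulse_protocol(); p2 <- pulse_protocol(amplitude = 2940)
  expect_equal(field_strength(p2, geo), 2 * field_strength(p1, geo))
  expect_equal(theoretical_current(sample_properties(conductivity = 0.066),
                                   geo, p1),
               2 * theoretical_current(smp, geo, p1))
  expect_equal(electromigration_displacement(smp, p2, geo),
               2 * electromigration_displacement(smp, p1, geo))
  expect_equal(accumulated_surface_amount(1.2, 1e-5),
               2 * accumulated_surface_amount(0.6, 1e-5))
  # full-depletion bound: accumulation never exceeds c * gap
  d <- electromigration_displacement(smp, p1, geo)
  expect_lte(accumulated_surface_amount(smp$bsa_concentration, d),
             smp$bsa_concentration * geo$gap)
})

test_that("physics report covers every derived quantity", {
  rep <- physics_report()
  expect_s3_class(rep, "data.frame")
  expect_true(all(c("field_strength", "theoretical_current",
                    "joule_heating_adiabatic") %in% rep$quantity))
  expect_true(all(is.finite(rep$value)))
})
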