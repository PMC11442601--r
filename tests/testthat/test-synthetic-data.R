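test_that("synthetic transients reproduce the dark floor and are seed-stable", {
  spec <- synthetic_spec("pb", expected = function(t) rep(0, length(t)),
                         n_replicates = 1, seed = 7, t_max = 500,
                         report_max = 500)
  tr <- generate_transient(spec)[[1]]
  # sample mean over 500 bins within 3 standard errors of the dark rate
  se <- sqrt(21 / 500)
  expect_lt(abs(mean(tr$counts) - 21), 3 * se)
  # identical seed, identical draws
  tr2 <- generate_transient(spec)[[1]]
  expect_identical(tr$counts, tr2$counts)
  # different seed differs
  spec3 <- synthetic_spec("pb", expected = function(t) rep(0, length(t)),
                          n_replicates = 1, seed = 8, t_max = 500,
                          report_max = 500)
  expect_false(identical(generate_transient(spec3)[[1]]$counts, tr$counts))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_transient(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("Poisson counting noise has variance equal to its mean", {
  spec <- synthetic_spec("pb", expected = function(t) rep(29, length(t)),
                         n_replicates = 20, seed = 11, t_max = 500,
                         report_max = 500)
  counts <- unlist(lapply(generate_transient(spec), `[[`, "counts"))
  expect_gte(length(counts), 1e4)
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("window integrals of synthetic data recover the template integral", {
  f <- parametric_template("bsa_h2o2")
  spec <- synthetic_spec("bsa_h2o2", expected = f, n_replicates = 200,
                         seed = 3, t_max = 150)
  avg <- average_replicates(generate_transient(spec))
  got <- integrate_window(avg$mean, c(60, 90), basis = 30)
  want <- sum(f(seq(60.5, 89.5)) + 21)
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("templates have the observed phase shapes", {
  tt_pulse <- seq(61, 89, 0.5)
  # buffer: flat during pulsing
  f_pb <- parametric_template("pb")
  expect_lt(diff(range(f_pb(tt_pulse))), 1e-9)
  # protein: monotone rise during pulsing
  f_bsa <- parametric_template("bsa")
  expect_true(all(diff(f_bsa(tt_pulse)) > 0))
  # every scenario relaxes toward its (slowly decaying) pre-pulse baseline:
  # shortly after pulsing the pulse excess has died away
  for (lab in c("pb", "pb_h2o2", "bsa", "bsa_h2o2")) {
    f <- parametric_template(lab)
    t_late <- 90 + 20 * 20        # many post-relaxation time constants
    baseline <- parametric_template(lab)(59.99) *
      exp(-(t_late - 59.99) / 300)
    expect_lt(abs(f(t_late) - baseline), 1e-6 * max(1, f(89)))
  }
  expect_error(parametric_template("plasma"), "unknown scenario")
})

test_that("template pulsing integrals are scenario-ordered with synergy", {
  integral <- function(lab) {
    f <- parametric_template(lab)
    sum(f(seq(60.5, 89.5)))
  }
  i_pb <- integral("pb"); i_pbh <- integral("pb_h2o2")
  i_bsa <- integral("bsa"); i_bsah <- integral("bsa_h2o2")
  expect_true(i_bsah > i_bsa && i_bsa > i_pbh && i_pbh > i_pb)
  expect_gt(i_bsah, i_bsa + i_pbh)                       # synergy
  expect_lt(integral("bsa_h2o2_cat"), i_bsah)            # catalase protects
  expect_lt(integral("bsa_h2o2_sod"), i_bsah)            # SOD protects
})

test_that("synthetic assay data round-trip through the calculators", {
  ms <- generate_assay_data(1e-5, noise_sd = 0, seed = 1, assay = "ellman")
  expect_equal(ellman_sh_concentration(ms[[1]]), 1e-5, tolerance = 1e-12)
  # 10 uM free -SH gives A = 0.1415 over blank before noise
  expect_equal(ms[[1]]$absorbance - ms[[1]]$blank, 0.1415, tolerance = 1e-9)
  mb <- generate_assay_data(0.1, noise_sd = 0, seed = 1, assay = "brady")
  expect_equal(brady_carbonyl_concentration(mb[[1]]), 0.1, tolerance = 1e-12)
  # with noise, recovery within a few noise SDs
  msn <- generate_assay_data(1e-5, noise_sd = 0.002, seed = 5, n = 20)
  rec <- vapply(msn, ellman_sh_concentration, 0)
  expect_lt(abs(mean(rec) - 1e-5), 3 * 0.002 / 14150 / sqrt(20))
  # seed reproducibility
  msn2 <- generate_assay_data(1e-5, noise_sd = 0.002, seed = 5, n = 20)
  expect_identical(vapply(msn2, `[[`, 0, "absorbance"),
                   vapply(msn, `[[`, 0, "absorbance"))
})
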