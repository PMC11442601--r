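#' Parametric expected-chemiluminescence template for a scenario
#'
#' A fast stand-in for the full kinetic simulator: a piecewise expected
#' count-rate curve (counts/s above the dark floor) with the shapes the
#' experiment displays. Pre-pulsing: zero for buffer-only samples, an
#' elevated slowly decaying level when protein and peroxide react
#' (Fenton chemistry consuming H2O2); pulsing (60-90 s): flat for buffer
#' (electrooxidation at a constant rate) versus a saturating rise for
#' protein (electromigrative accumulation at the anode, gradually
#' limited by local H2O2); post-pulsing: exponential relaxation back to
#' the pre-pulse baseline. Peroxide scales amplitudes through a
#' saturating (non-linear) dose factor `c/(c + K)`.
#'
#' Default parameters place the scenarios in the qualitative order the
#' experiment shows (pulsing-window integrals
#' bsa_h2o2 > bsa > pb_h2o2 > pb, with synergy
#' bsa_h2o2 > bsa + pb_h2o2), with catalase suppressing
#' peroxide-dependent amplitudes and superoxide dismutase acting mostly
#' in the pulsing and early post-pulsing phases.
#'
#' @param scenario Scenario label (`"pb"`, `"bsa_h2o2_sod"`, ...).
#' @param h2o2 H2O2 concentration (M) when the label includes `h2o2`.
#' @param pulse_window `c(start, end)` of the pulsing period (s).
#' @param params Optional overrides of the template parameter list (see
#'   Details in the package vignette).
#' @return Function `f(t)` returning the expected count rate (counts/s
#'   above dark) at time `t` (vectorised).
#' @export
#' @examples
#' f <- parametric_template("bsa_h2o2")
#' f(c(30, 75, 100))
parametric_template <- function(scenario, h2o2 = 1e-3,
                                pulse_window = c(60, 90),
                                params = list()) {
  tokens <- strsplit(scenario, "_", fixed = TRUE)[[1]]
  if (!tokens[1] %in% c("pb", "bsa"))
    stop("unknown scenario label: ", scenario, call. = FALSE)
  has_bsa <- tokens[1] == "bsa"
  has_h2o2 <- "h2o2" %in% tokens
  has_cat <- "cat" %in% tokens
  has_sod <- "sod" %in% tokens

  p <- list(
    dose_K = 2e-3,        # M, half-saturation of the peroxide dose factor
    pb_pulse = 6,         # counts/s, buffer-only pulsing plateau
    pb_h2o2_pulse = 30,   # counts/s added by peroxide electrooxidation
    bsa_pulse = 45,       # counts/s, protein pulsing rise amplitude
    bsa_h2o2_pulse = 420, # counts/s, protein+peroxide synergy amplitude
    bsa_pre = 40,         # counts/s, Fenton pre-pulse level (per dose)
    pre_decay_tau = 300,  # s, slow pre-pulse Fenton decay
    rise_tau = 15,        # s, pulsing-phase saturating rise
    post_tau = 20,        # s, post-pulse relaxation
    cat_factor = 0.25,    # catalase suppression of peroxide amplitudes
    sod_pulse_factor = 0.7,  # SOD suppression during pulsing/early post
    sod_pre_factor = 0.95)   # SOD suppression before pulsing
  p[names(params)] <- params

  dose <- if (has_h2o2) h2o2 / (h2o2 + p$dose_K) else 0
  if (has_cat) dose <- dose * p$cat_factor
  pre_level <- if (has_bsa) p$bsa_pre * dose else 0
  pulse_amp <- if (has_bsa) p$bsa_pulse + p$bsa_h2o2_pulse * dose
               else p$pb_pulse + p$pb_h2o2_pulse * dose
  if (has_sod) {
    pre_level <- pre_level * p$sod_pre_factor
    pulse_amp <- pulse_amp * p$sod_pulse_factor
  }
  t_on <- pulse_window[1]; t_off <- pulse_window[2]

  pre_fun <- function(t) pre_level * exp(-pmax(t, 0) / p$pre_decay_tau)
  rise <- function(t) {
    if (has_bsa) 1 - exp(-(t - t_on) / p$rise_tau) else 1
  }
  end_level <- pre_fun(t_off) + pulse_amp * rise(t_off)

  function(t) {
    out <- numeric(length(t))
    pre <- t < t_on
    out[pre] <- pre_fun(t[pre])
    on <- t >= t_on & t < t_off
    out[on] <- pre_fun(t[on]) + pulse_amp * rise(t[on])
    post <- t >= t_off
    out[post] <- pre_fun(t[post]) +
      (end_level - pre_fun(t_off)) * exp(-(t[post] - t_off) / p$post_tau)
    out
  }
}

#' Specification for a synthetic photon-count data set
#'
#' @param scenario Scenario label (see [parametric_template()]).
#' @param h2o2 H2O2 concentration (M).
#' @param expected Expected-rate source: a function of time (counts/s
#'   above dark), a `pef_trajectory` (converted through
#'   [trajectory_counts()]), or `NULL` for the scenario's parametric
#'   template.
#' @param dark_rate Dark floor (counts s^-1), default 21.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param t_max Record length (s); counting runs on a 1 s grid over
#'   `[0, t_max)`.
#' @param report_max Reported subset (s); the experiment records 500 s
#'   but only the first 150 s carry signal changes.
#' @param detector Detector model used when `expected` is a trajectory.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scenario = "bsa_h2o2", h2o2 = 1e-3,
                           expected = NULL, dark_rate = 21,
                           n_replicates = 3, seed = 1,
                           t_max = 500, report_max = 150,
                           detector = detector_model()) {
  stopifnot(n_replicates >= 1, t_max > 0, report_max <= t_max)
  if (is.null(expected))
    expected <- parametric_template(scenario, h2o2)
  if (inherits(expected, "pef_trajectory")) {
    tr <- trajectory_counts(expected, detector)
    rate <- stats::approxfun(tr$time, pmax(tr$counts / tr$bin_width -
                                             detector$dark_rate, 0),
                             rule = 2)
    expected <- rate
  }
  structure(list(scenario = scenario, h2o2 = h2o2, expected = expected,
                 dark_rate = dark_rate, n_replicates = n_replicates,
                 seed = seed, t_max = t_max, report_max = report_max),
            class = "synthetic_spec")
}

#' Generate synthetic photon-count transients
#'
#' Per replicate, counts in each 1 s bin are drawn as
#' `Poisson(dark + expected(t))`, emulating the experiment's structure:
#' a 60 s pre-pulsing baseline, 30 s of pulsing, post-pulsing decay, a
#' dark floor of ~21 counts/s and shot (counting) noise. The generator
#' stream is fully determined by one integer seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [luminescence_transient()] replicates covering
#'   `[0, report_max)`.
#' @export
#' @examples
#' trs <- generate_transient(synthetic_spec("bsa_h2o2", n_replicates = 2))
#' length(trs)
generate_transient <- function(spec) {
  tt <- seq(0, spec$t_max - 1)
  lambda <- spec$dark_rate + spec$expected(tt + 0.5)
  if (any(lambda < 0)) stop("negative expected rate", call. = FALSE)
  keep <- tt < spec$report_max
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)
  lapply(seq_len(spec$n_replicates), function(r) {
    counts <- stats::rpois(length(tt), lambda)
    luminescence_transient(tt[keep], counts[keep],
                           scenario = spec$scenario, replicate = r)
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate synthetic Beer-Lambert assay measurements
#'
#' Forward Beer-Lambert absorbances for a known true concentration with
#' additive Gaussian noise, for testing the assay calculators'
#' round-trip behaviour.
#'
#' @param true_concentration True analyte concentration (assay units:
#'   mol/L for Ellman, mmol/L for Brady).
#' @param noise_sd Absorbance noise standard deviation.
#' @param seed Integer seed.
#' @param assay `"ellman"` or `"brady"`.
#' @param n Number of replicate measurements.
#' @param blank Blank absorbance added to all measurements.
#' @param dilution Dilution factor.
#' @return List of [assay_measurement()] objects.
#' @export
generate_assay_data <- function(true_concentration, noise_sd = 0, seed = 1,
                                assay = c("ellman", "brady"), n = 3,
                                blank = 0.05, dilution = 1) {
  assay <- match.arg(assay)
  stopifnot(true_concentration >= 0, noise_sd >= 0)
  eps <- if (assay == "ellman") 14150 else 22
  path <- if (assay == "ellman") 1 else 0.2893
  a_true <- eps * path * true_concentration / dilution + blank
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  lapply(seq_len(n), function(i) {
    a <- a_true + stats::rnorm(1, 0, noise_sd)
    if (assay == "ellman")
      ellman_measurement(a, blank = blank, dilution = dilution)
    else
      brady_measurement(a, blank = blank, dilution = dilution)
  })
}
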