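#' Luminescence transient: binned photon counts over time
#'
#' A uniformly binned photon-count record with band, scenario and
#' replicate metadata. Measured or synthetic records carry non-negative
#' integer counts; expected (model) curves carry non-negative reals
#' (`integer_counts = FALSE`).
#'
#' @param time Bin start times (s), uniform spacing.
#' @param counts Counts per bin, same length as `time`.
#' @param band Wavelength-band label (e.g. `"300-650"`).
#' @param scenario Scenario label.
#' @param replicate Replicate identifier.
#' @param integer_counts Require integer counts (default TRUE).
#' @return Object of class `luminescence_transient`.
#' @export
luminescence_transient <- function(time, counts, band = "300-650",
                                   scenario = NA_character_,
                                   replicate = 1L,
                                   integer_counts = TRUE) {
  stopifnot(length(time) == length(counts), length(time) >= 2)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniformly binned", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (integer_counts && any(abs(counts - round(counts)) > 1e-9))
    stop("measured counts must be integers", call. = FALSE)
  structure(list(time = time, counts = counts, bin_width = dt[1],
                 band = band, scenario = scenario, replicate = replicate),
            class = "luminescence_transient")
}

#' @export
print.luminescence_transient <- function(x, ...) {
  cat(sprintf("Luminescence transient [%s, %s, rep %s]: %d bins of %.3g s, mean %.3g counts/bin\n",
              x$scenario, x$band, x$replicate, length(x$time), x$bin_width,
              mean(x$counts)))
  invisible(x)
}

#' Timing windows of the PEF experiment
#'
#' Disjoint, ordered pre-pulsing / pulsing / post-pulsing intervals with
#' a common integration basis so that period integrals are comparable.
#' Defaults: pre [30, 60) s, pulsing [60, 90) s, post [90, 120) s, basis
#' 30 s (the pulsing period is 30 s; the pre and post windows are placed
#' adjacent to it).
#'
#' @param pre,pulse,post Two-element `c(start, end)` intervals (s).
#' @param basis Common integration basis (s), at most the shortest
#'   interval length.
#' @return Object of class `window_scheme`.
#' @export
window_scheme <- function(pre = c(30, 60), pulse = c(60, 90),
                          post = c(90, 120), basis = 30) {
  iv <- rbind(pre, pulse, post)
  if (any(iv[, 2] <= iv[, 1]))
    stop("window intervals must have positive length", call. = FALSE)
  if (pre[2] > pulse[1] || pulse[2] > post[1])
    stop("windows must be disjoint and ordered pre < pulse < post",
         call. = FALSE)
  if (basis <= 0 || basis > min(iv[, 2] - iv[, 1]))
    stop("basis must be positive and no longer than each window",
         call. = FALSE)
  structure(list(pre = pre, pulse = pulse, post = post, basis = basis),
            class = "window_scheme")
}

#' Integrate a transient over a time window
#'
#' Sums the counts over the first `basis` seconds of the interval
#' (default: the whole interval). For real-valued expected curves a
#' trapezoid rule on the per-bin rate is available; for counted data the
#' sum IS the integral.
#'
#' @param transient A [luminescence_transient()].
#' @param interval `c(start, end)` (s); must lie within the data.
#' @param basis Integration basis (s); `NULL` = full interval.
#' @param method `"sum"` (default) or `"trapezoid"`.
#' @return Integrated counts over the window.
#' @export
#' @examples
#' tr <- luminescence_transient(0:99, rep(21, 100))
#' integrate_window(tr, c(30, 60))  # 630
integrate_window <- function(transient, interval, basis = NULL,
                             method = c("sum", "trapezoid")) {
  method <- match.arg(method)
  if (is.null(basis)) basis <- interval[2] - interval[1]
  end <- min(interval[1] + basis, interval[2])
  t0 <- transient$time[1]
  t1 <- transient$time[length(transient$time)] + transient$bin_width
  if (interval[1] < t0 - 1e-9 || end > t1 + 1e-9)
    stop("integration window [", interval[1], ", ", end,
         ") outside the transient support [", t0, ", ", t1, ")",
         call. = FALSE)
  sel <- transient$time >= interval[1] - 1e-9 & transient$time < end - 1e-9
  if (method == "sum") {
    sum(transient$counts[sel])
  } else {
    tt <- transient$time[sel]; cc <- transient$counts[sel] / transient$bin_width
    if (sum(sel) < 2) return(sum(transient$counts[sel]))
    sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2) +
      cc[length(cc)] * transient$bin_width
  }
}

#' Integrals of a transient in the pre / pulsing / post windows
#'
#' @param transient A [luminescence_transient()].
#' @param scheme A [window_scheme()].
#' @return Named numeric vector `c(pre, pulse, post)`.
#' @export
window_integrals <- function(transient, scheme = window_scheme()) {
  c(pre = integrate_window(transient, scheme$pre, scheme$basis),
    pulse = integrate_window(transient, scheme$pulse, scheme$basis),
    post = integrate_window(transient, scheme$post, scheme$basis))
}

#' Average replicate transients
#'
#' Element-wise mean and sample (n-1) standard deviation over replicates
#' sharing a common time grid. A single replicate yields SD 0 with a
#' warning flag.
#'
#' @param transients List of [luminescence_transient()] objects.
#' @return List: `mean` (a real-valued transient), `sd` (per-bin vector),
#'   `n`, `single_replicate` flag.
#' @export
average_replicates <- function(transients) {
  stopifnot(length(transients) >= 1)
  t0 <- transients[[1]]$time
  for (tr in transients)
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9)
      stop("alignment error: replicate time grids differ", call. = FALSE)
  m <- do.call(rbind, lapply(transients, `[[`, "counts"))
  mn <- colMeans(m)
  sdv <- if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m))
  list(mean = luminescence_transient(t0, mn, band = transients[[1]]$band,
                                     scenario = transients[[1]]$scenario,
                                     replicate = "mean",
                                     integer_counts = FALSE),
       sd = sdv, n = length(transients),
       single_replicate = length(transients) == 1)
}

#' Per-bin difference of two transients
#'
#' Used for enzyme-effect analysis: the difference of the signals
#' recorded without and with the enzyme localises when the enzyme acts.
#'
#' @param a,b [luminescence_transient()] objects on a common grid.
#' @return Numeric per-bin difference `a - b`.
#' @export
difference_transient <- function(a, b) {
  if (length(a$time) != length(b$time) || max(abs(a$time - b$time)) > 1e-9)
    stop("alignment error: transient grids differ", call. = FALSE)
  a$counts - b$counts
}

#' Dose-response table of window integrals versus prooxidant concentration
#'
#' Sorts integrals by H2O2 concentration and flags monotone increase and
#' deviation from proportionality (ratio test: the integrals-to-
#' concentration ratios of a strictly proportional response are all
#' equal; spread beyond `ratio_tol` flags non-linearity).
#'
#' @param integrals Window integrals, one per concentration.
#' @param concentration H2O2 concentrations (M), all distinct.
#' @param ratio_tol Allowed max/min spread of `integral/concentration`
#'   before the response is called non-linear (default 1.25).
#' @return List: `table` (sorted data.frame), `monotone_increasing`,
#'   `nonlinear`.
#' @export
dose_response <- function(integrals, concentration, ratio_tol = 1.25) {
  if (length(integrals) != length(concentration) || length(integrals) < 2)
    stop("need >= 2 matched integral/concentration pairs", call. = FALSE)
  if (anyDuplicated(concentration))
    stop("duplicate concentrations", call. = FALSE)
  o <- order(concentration)
  tab <- data.frame(concentration = concentration[o],
                    integral = integrals[o])
  ratios <- tab$integral / tab$concentration
  list(table = tab,
       monotone_increasing = all(diff(tab$integral) > 0),
       nonlinear = max(ratios) / min(ratios) > ratio_tol)
}

#' Absorbance measurement for a Beer-Lambert assay
#'
#' @param absorbance Measured absorbance.
#' @param blank Blank absorbance.
#' @param extinction Molar extinction coefficient (in the assay's
#'   concentration units^-1 cm^-1).
#' @param path Optical path length (cm).
#' @param dilution Dilution factor applied to the stock (>= 1).
#' @return Object of class `assay_measurement`.
#' @export
assay_measurement <- function(absorbance, blank = 0, extinction, path = 1,
                              dilution = 1) {
  stopifnot(extinction > 0, path > 0, dilution >= 1)
  structure(list(absorbance = absorbance, blank = blank,
                 extinction = extinction, path = path, dilution = dilution),
            class = "assay_measurement")
}

beer_lambert_concentration <- function(m) {
  net <- m$absorbance - m$blank
  if (any(net < 0)) {
    warning("absorbance below blank; concentration clamped to 0",
            call. = FALSE)
    net <- pmax(net, 0)
  }
  m$dilution * net / (m$extinction * m$path)
}

#' Free sulfhydryl concentration from an Ellman (DTNB) assay
#'
#' c = dilution * (A412 - A_blank) / (epsilon * l) with the TNB molar
#' extinction coefficient 14150 M^-1 cm^-1 and a 1 cm cuvette by
#' default.
#'
#' @param m An [assay_measurement()]; when constructed with
#'   `ellman_measurement()` the assay defaults are pre-filled.
#' @return Free -SH concentration (mol L^-1).
#' @export
ellman_sh_concentration <- function(m) beer_lambert_concentration(m)

#' @rdname ellman_sh_concentration
#' @inheritParams assay_measurement
#' @export
ellman_measurement <- function(absorbance, blank = 0, dilution = 1,
                               extinction = 14150, path = 1) {
  assay_measurement(absorbance, blank, extinction, path, dilution)
}

#' Carbonyl concentration from a Brady (DNPH) assay
#'
#' c = dilution * (A375 - A_blank) / (epsilon * l) with the hydrazone
#' extinction coefficient 22 mM^-1 cm^-1 and the 0.2893 cm well path of
#' the plate assay by default; the result is therefore in mmol L^-1.
#'
#' @param m An [assay_measurement()]; see `brady_measurement()`.
#' @return Carbonyl concentration (mmol L^-1).
#' @export
brady_carbonyl_concentration <- function(m) beer_lambert_concentration(m)

#' @rdname brady_carbonyl_concentration
#' @inheritParams assay_measurement
#' @export
brady_measurement <- function(absorbance, blank = 0, dilution = 1,
                              extinction = 22, path = 0.2893) {
  assay_measurement(absorbance, blank, extinction, path, dilution)
}

#' Read / write transient TSV files
#'
#' Two-column `time_s counts` tables with `# band=`, `# scenario=`,
#' `# replicate=` header comment lines.
#'
#' @param transient A [luminescence_transient()].
#' @param path File path.
#' @return `read_transient` returns a [luminescence_transient()];
#'   `write_transient` returns `path` invisibly.
#' @export
write_transient <- function(transient, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# band=%s", transient$band),
               sprintf("# scenario=%s", transient$scenario),
               sprintf("# replicate=%s", transient$replicate),
               "time_s\tcounts"), con)
  utils::write.table(data.frame(transient$time, transient$counts), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_transient
#' @export
read_transient <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    h <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(h)) sub(paste0("^# ", key, "="), "", h[1]) else default
  }
  df <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]))
  integer_counts <- all(abs(df[[2]] - round(df[[2]])) < 1e-9)
  luminescence_transient(df[[1]], df[[2]], band = meta("band", "300-650"),
                         scenario = meta("scenario", NA_character_),
                         replicate = meta("replicate", 1L),
                         integer_counts = integer_counts)
}
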