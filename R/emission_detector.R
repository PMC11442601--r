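#' Photomultiplier detector model
#'
#' Band-resolved model of the photon-counting detector: non-overlapping
#' wavelength bands with an averaged quantum efficiency each, one scalar
#' geometric collection efficiency (solid angle plus perforated-cathode
#' transmission; not fitted), a dark-count rate and a binning width.
#' Defaults follow the H7360-01-class photomultiplier used for this kind
#' of experiment: QE 12.2 % averaged over 300-550 nm, 0.55 % over
#' 550-650 nm, essentially zero in the near infrared (so the 1278 nm
#' monomolecular singlet-oxygen line is invisible), dark floor
#' 21 counts/s, 1 s bins.
#'
#' @param bands data.frame with columns `name`, `lower`, `upper` (nm)
#'   and `qe` (fraction 0..1); bands must not overlap.
#' @param collection Geometric collection efficiency (fraction).
#' @param dark_rate Dark count rate (counts s^-1).
#' @param bin_s Counting bin width (s).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(bands = data.frame(
                             name = c("uv_vis", "red", "ir"),
                             lower = c(300, 550, 1100),
                             upper = c(550, 650, 1400),
                             qe = c(0.122, 0.0055, 0)),
                           collection = 0.01, dark_rate = 21, bin_s = 1) {
  stopifnot(all(bands$qe >= 0 & bands$qe <= 1), dark_rate >= 0,
            collection > 0, collection <= 1, bin_s > 0)
  o <- order(bands$lower)
  b <- bands[o, ]
  if (any(b$upper <= b$lower) ||
      (nrow(b) > 1 && any(b$lower[-1] < b$upper[-nrow(b)])))
    stop("detector bands must be ordered and non-overlapping", call. = FALSE)
  structure(list(bands = b, collection = collection,
                 dark_rate = dark_rate, bin_s = bin_s),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("Photon-counting detector model\n")
  for (i in seq_len(nrow(x$bands)))
    cat(sprintf("  %-8s %4.0f-%4.0f nm  QE %.3g %%\n", x$bands$name[i],
                x$bands$lower[i], x$bands$upper[i], 100 * x$bands$qe[i]))
  cat(sprintf("  collection %.3g, dark %.3g counts/s, bin %.3g s\n",
              x$collection, x$dark_rate, x$bin_s))
  invisible(x)
}

# Which detector band a wavelength falls into (NA if outside all bands).
band_index <- function(detector, wavelength_nm) {
  vapply(wavelength_nm, function(w) {
    i <- which(w >= detector$bands$lower & w < detector$bands$upper)
    if (length(i)) i[1] else NA_integer_
  }, 1L)
}

# Quantum efficiency applying to each emission wavelength (0 outside).
band_qe <- function(detector, wavelength_nm) {
  i <- band_index(detector, wavelength_nm)
  qe <- detector$bands$qe[i]
  qe[is.na(i)] <- 0
  qe
}

#' Emission assignment: reaction to band and photon yield
#'
#' Maps each emission reaction of a network to its wavelength (the
#' `band_nm` column: 1278 nm monomolecular singlet-oxygen decay, 634 nm
#' bimolecular singlet-oxygen decay, ~425 nm triplet carbonyl) and a
#' photon yield per reaction event.
#'
#' @param network A `pef_network`.
#' @param phi Named photon yields (see [default_photon_yields()]).
#' @return data.frame reaction id, wavelength_nm, phi.
#' @export
emission_assignment <- function(network, phi = default_photon_yields(network)) {
  idx <- which(network$reactions$kind == "emission")
  ids <- network$reactions$id[idx]
  bad <- setdiff(names(phi), network$reactions$id)
  if (length(bad))
    stop("photon yield assigned to unknown reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(phi < 0 | phi > 1))
    stop("photon yields must lie in [0, 1]", call. = FALSE)
  data.frame(id = ids,
             wavelength_nm = as.numeric(network$reactions$band_nm[idx]),
             phi = unname(phi[match(ids, names(phi))]),
             stringsAsFactors = FALSE)
}

#' Band-resolved photon emission rates from reaction fluxes
#'
#' rate_band = N_A * sum over assigned reactions of phi_i * flux_i, with
#' fluxes in mol events per second summed over photon-visible
#' compartments. When given a `pef_trajectory` this re-derives the rates
#' from the stored concentrations; a named flux vector (mol/s) can be
#' supplied directly instead.
#'
#' @param fluxes Named molar event rates (mol s^-1) keyed by emission
#'   reaction id, or a `pef_trajectory`.
#' @param assignment An [emission_assignment()]; defaults to the
#'   trajectory's own network and yields when a trajectory is given.
#' @param detector A [detector_model()] defining the band layout.
#' @return Named photon rate vector (photons s^-1) per detector band
#'   (plus `outside` for emission falling into no band), or a
#'   time x band matrix for a trajectory.
#' @export
photon_rates <- function(fluxes, assignment = NULL,
                         detector = detector_model()) {
  if (inherits(fluxes, "pef_trajectory")) {
    return(fluxes$photon_rate)
  }
  if (is.null(assignment))
    stop("an emission assignment is required for raw fluxes", call. = FALSE)
  unknown <- setdiff(names(fluxes), assignment$id)
  if (length(unknown))
    stop("flux for reaction(s) without emission assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  avo <- pef_constants()$avogadro
  out <- stats::setNames(rep(0, nrow(detector$bands) + 1),
                         c(detector$bands$name, "outside"))
  for (i in seq_along(fluxes)) {
    a <- assignment[assignment$id == names(fluxes)[i], ]
    b <- band_index(detector, a$wavelength_nm)
    tgt <- if (is.na(b)) "outside" else detector$bands$name[b]
    out[tgt] <- out[tgt] + avo * a$phi * fluxes[i]
  }
  out
}

#' Expected detector counts from band photon rates
#'
#' counts per bin = bin * (dark + collection * sum_b QE_b * rate_b).
#'
#' @param rates Named photon rates (photons s^-1) per detector band
#'   (band names must match the detector's; extra `outside` entries are
#'   ignored since no QE applies).
#' @param detector A [detector_model()].
#' @return Expected counts in one bin (real-valued).
#' @export
expected_counts <- function(rates, detector = detector_model()) {
  stopifnot(all(rates >= 0))
  rates <- rates[names(rates) %in% detector$bands$name]
  qe <- detector$bands$qe[match(names(rates), detector$bands$name)]
  detector$bin_s * (detector$dark_rate + detector$collection *
                      sum(qe * rates))
}

#' Invert measured counts in one band to a source photon rate
#'
#' Dark-subtracted inverse of [expected_counts()] for a single band:
#' `rate = (counts/bin - dark) / (collection * QE_band)`. Exact
#' round-trip with [expected_counts()] by construction. Bands with zero
#' quantum efficiency (the near-IR) cannot be inverted.
#'
#' @param counts Measured counts in one bin.
#' @param band Band name.
#' @param detector A [detector_model()].
#' @return Source photon rate (photons s^-1) in that band.
#' @export
qe_correct <- function(counts, band, detector = detector_model()) {
  i <- match(band, detector$bands$name)
  if (is.na(i)) stop("unknown detector band: ", band, call. = FALSE)
  qe <- detector$bands$qe[i]
  if (qe <= 0)
    stop("band '", band, "' has zero quantum efficiency and cannot be inverted",
         call. = FALSE)
  pmax(counts / detector$bin_s - detector$dark_rate, 0) /
    (detector$collection * qe)
}
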