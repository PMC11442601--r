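#' Rectangular pulse current profile
#'
#' Converts the voltage protocol into the piecewise-constant current the
#' chamber draws: rectangular pulses of ohmic amplitude (mode
#' `"theoretical"`, I = sigma A U / d) or of a user-supplied constant
#' amplitude (mode `"constant"`, e.g. the observed 12.5 A pulse top),
#' zero between pulses. Double-layer charging overshoots are ignored.
#'
#' @param protocol A [pulse_protocol()].
#' @param sample A [sample_properties()]; needed for theoretical mode.
#' @param geometry A [chamber_geometry()]; needed for theoretical mode.
#' @param mode `"theoretical"` or `"constant"`.
#' @param amplitude Pulse-top current (A) for constant mode.
#' @param t_start Time (s) at which the first pulse starts.
#' @return Object of class `pef_current_profile`: function `I(t)`, pulse
#'   on/off edge times, amplitude and total charge.
#' @export
#' @examples
#' prof <- build_current_profile(pulse_protocol(), sample_properties(),
#'                               chamber_geometry())
#' prof$total_charge  # ~0.0387 C
build_current_profile <- function(protocol, sample = NULL, geometry = NULL,
                                  mode = c("theoretical", "constant"),
                                  amplitude = NULL, t_start = 60) {
  mode <- match.arg(mode)
  if (mode == "theoretical") {
    if (is.null(sample) || is.null(geometry))
      stop("theoretical mode needs sample and geometry", call. = FALSE)
    amplitude <- theoretical_current(sample, geometry, protocol)
  } else if (is.null(amplitude)) {
    stop("constant mode needs an amplitude", call. = FALSE)
  }
  n <- protocol$n_pulses
  on <- if (n > 0) t_start + (seq_len(n) - 1) * protocol$period else numeric(0)
  off <- on + protocol$pulse_width
  amp <- amplitude
  fun <- function(t) {
    if (n == 0) return(rep(0, length(t)))
    idx <- findInterval(t, on)
    ifelse(idx >= 1 & t < off[pmax(idx, 1)], amp, 0)
  }
  structure(
    list(current = fun, amplitude = amplitude, on = on, off = off,
         protocol = protocol, t_start = t_start,
         total_charge = amplitude * n * protocol$pulse_width),
    class = "pef_current_profile")
}

#' @export
print.pef_current_profile <- function(x, ...) {
  cat(sprintf("Current profile: %d pulses of %.3g A (total charge %.4g C)\n",
              x$protocol$n_pulses, x$amplitude, x$total_charge))
  invisible(x)
}

#' Electrode reaction channels of a network
#'
#' Extracts the anodic or cathodic charge-transfer channels: reaction id,
#' electrons per event z, competition weight (the `k` column of electrode
#' rows) and the concentration species that scales the weight (the first
#' non-buffered reactant; water- and proton-fed channels have constant
#' weights since their activities are fixed).
#'
#' @param network A `pef_network`.
#' @param electrode `"anodic"` or `"cathodic"`.
#' @return data.frame with columns id, z, weight, weight_species.
#' @export
electrode_channels <- function(network, electrode = c("anodic", "cathodic")) {
  electrode <- match.arg(electrode)
  idx <- which(network$reactions$kind == electrode)
  wsp <- vapply(idx, function(i) {
    r <- names(network$reactant_stoich[[i]])
    r <- r[!(r %in% network$fixed_species)]
    if (length(r)) r[1] else NA_character_
  }, "")
  data.frame(id = network$reactions$id[idx],
             z = network$reactions$z[idx],
             weight = network$reactions$k[idx],
             weight_species = wsp,
             stringsAsFactors = FALSE)
}

#' Partition an electrode current over competing charge-transfer channels
#'
#' Each channel i receives the fraction f_i of the instantaneous current,
#' with f_i proportional to weight_i (constant-activity channels such as
#' water oxidation) or weight_i * c_i (solution-species channels, a
#' concentration-weighted competition). The per-channel molar event rate
#' is `I * f_i / (z_i * F)` so that `F * sum(z_i * rate_i) = I` exactly
#' (Faraday bookkeeping).
#'
#' @param current Instantaneous current I (A), >= 0.
#' @param conc Named concentration vector (M) of the electrode-layer
#'   compartment.
#' @param channels Channel table from [electrode_channels()].
#' @param faraday Faraday constant override.
#' @return Named vector of molar event rates (mol s^-1) keyed by reaction
#'   id.
#' @export
partition_electrode_current <- function(current, conc, channels,
                                        faraday = pef_constants()$faraday) {
  stopifnot(current >= 0)
  w <- channels$weight
  has_sp <- !is.na(channels$weight_species)
  cs <- rep(1, nrow(channels))
  cs[has_sp] <- pmax(conc[channels$weight_species[has_sp]], 0)
  raw <- w * cs
  tot <- sum(raw)
  if (tot <= 0) {
    if (current > 0)
      stop("configuration error: all channel weights zero while current flows",
           call. = FALSE)
    return(stats::setNames(rep(0, nrow(channels)), channels$id))
  }
  f <- raw / tot
  stats::setNames(current * f / (channels$z * faraday), channels$id)
}

#' @rdname partition_electrode_current
#' @export
partition_anodic_current <- partition_electrode_current

#' Electromigrative protein flux toward the anode
#'
#' While a pulse is on, the anionic protein drifts toward the anode with
#' flux `mu * E * c_bulk` (mol m^-2 s^-1); between pulses the flux is
#' zero. Material delivered to the anode layer is treated as deposited
#' (it does not diffuse back), so cumulative delivery is naturally capped
#' by bulk depletion.
#'
#' @param field Instantaneous field strength E (V m^-1), >= 0.
#' @param sample A [sample_properties()] (mobility, concentration).
#' @param bulk_concentration Current bulk protein concentration
#'   (mol m^-3); defaults to the sample's nominal concentration.
#' @return Flux (mol m^-2 s^-1).
#' @export
bsa_migration_flux <- function(field, sample,
                               bulk_concentration = sample$bsa_concentration) {
  stopifnot(field >= 0, bulk_concentration >= 0)
  sample$bsa_mobility * field * bulk_concentration
}
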