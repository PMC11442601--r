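#' Treatment chamber geometry
#'
#' Describes a parallel-plate electroporation/PEF chamber: two circular
#' electrodes facing each other across a thin liquid layer. The default
#' values are those of a thin-layer steel-electrode chamber with a 2.00 mm
#' gap, 26 mm electrode diameter (area 5.31 cm^2) and 1.06 mL volume.
#'
#' When `area` or `volume` are supplied explicitly they are checked for
#' consistency (0.5 %) with the circular-electrode and slab formulas;
#' omitted values are derived from `electrode_diameter` and `gap`.
#'
#' @param gap Electrode gap d (m). Must be > 0.
#' @param electrode_diameter Electrode diameter (m).
#' @param area Cross-sectional sample area A (m^2); default `pi*(diameter/2)^2`.
#' @param volume Chamber volume (m^3); default `area * gap`.
#' @param anode_layer_thickness Thickness delta (m) of the anodic diffusion
#'   layer compartment used by the simulator. Must be small compared to the
#'   gap; default 100 nm, motivated by the diffusional length scale of the
#'   hydroxyl radical (tens to hundreds of nanometres).
#' @return Object of class `chamber_geometry`.
#' @export
#' @examples
#' geo <- chamber_geometry()
#' geo$area * 1e4   # cm^2
#' geo$volume * 1e6 # mL
chamber_geometry <- function(gap = 2.00e-3,
                             electrode_diameter = 26e-3,
                             area = NULL,
                             volume = NULL,
                             anode_layer_thickness = 1e-7) {
  if (!is.numeric(gap) || length(gap) != 1L || !is.finite(gap) || gap <= 0)
    stop("invalid geometry: electrode gap must be a single positive number", call. = FALSE)
  if (electrode_diameter <= 0)
    stop("invalid geometry: electrode diameter must be positive", call. = FALSE)
  area_circ <- pi * (electrode_diameter / 2)^2
  if (is.null(area)) {
    area <- area_circ
  } else if (abs(area - area_circ) / area_circ > 0.005) {
    stop("invalid geometry: area deviates from pi*(diameter/2)^2 by more than 0.5 %",
         call. = FALSE)
  }
  vol_slab <- area * gap
  if (is.null(volume)) {
    volume <- vol_slab
  } else if (abs(volume - vol_slab) / vol_slab > 0.005) {
    stop("invalid geometry: volume deviates from area*gap by more than 0.5 %",
         call. = FALSE)
  }
  if (anode_layer_thickness <= 0 || anode_layer_thickness > gap / 10)
    stop("invalid geometry: anode layer thickness must be positive and << gap",
         call. = FALSE)
  structure(
    list(gap = gap, electrode_diameter = electrode_diameter, area = area,
         volume = volume, anode_layer_thickness = anode_layer_thickness),
    class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("PEF chamber geometry\n")
  cat(sprintf("  gap:            %.3g mm\n", x$gap * 1e3))
  cat(sprintf("  electrode diam: %.3g mm\n", x$electrode_diameter * 1e3))
  cat(sprintf("  area:           %.3g cm^2\n", x$area * 1e4))
  cat(sprintf("  volume:         %.3g mL\n", x$volume * 1e6))
  cat(sprintf("  anode layer:    %.3g nm\n", x$anode_layer_thickness * 1e9))
  invisible(x)
}

#' Pulsed electric field protocol
#'
#' A train of rectangular unipolar voltage pulses. Defaults describe
#' 30 pulses of 1470 V, 100 microseconds each, fired at 1 Hz.
#'
#' @param n_pulses Number of pulses (>= 0; 0 gives a null protocol).
#' @param pulse_width Width of each pulse (s); must be < `period`.
#' @param period Pulse repetition period (s).
#' @param amplitude Pulse voltage amplitude (V).
#' @return Object of class `pulse_protocol` with derived field
#'   `total_on_time = n_pulses * pulse_width`.
#' @export
#' @examples
#' pulse_protocol()$total_on_time  # 3 ms
pulse_protocol <- function(n_pulses = 30, pulse_width = 100e-6,
                           period = 1, amplitude = 1470) {
  if (n_pulses < 0 || n_pulses != round(n_pulses))
    stop("n_pulses must be a non-negative integer", call. = FALSE)
  if (pulse_width <= 0 || period <= 0 || pulse_width >= period)
    stop("pulse_width must be positive and smaller than the period", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(
    list(n_pulses = as.integer(n_pulses), pulse_width = pulse_width,
         period = period, amplitude = amplitude,
         total_on_time = n_pulses * pulse_width),
    class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("PEF protocol: %d pulses x %.3g us at %.3g Hz, %.4g V (on-time %.3g ms)\n",
              x$n_pulses, x$pulse_width * 1e6, 1 / x$period, x$amplitude,
              x$total_on_time * 1e3))
  invisible(x)
}

#' Physical properties of the treated sample
#'
#' Defaults describe a 0.6 mM (40 mg/mL) BSA solution: conductivity
#' 0.033 S/m, pH 7.2, BSA electrophoretic mobility 1.4e-8 m^2 s^-1 V^-1,
#' diffusion coefficient 6.3e-11 m^2/s, molecular diameter 7.0 nm, and
#' water-like thermal properties starting from 22 degrees C.
#'
#' @param conductivity Electrical conductivity sigma (S m^-1), > 0.
#' @param pH Sample pH (buffered; clamped during simulation).
#' @param bsa_concentration Protein concentration (mol m^-3; 0.6 mol m^-3 = 0.6 mM).
#' @param bsa_mobility Electrophoretic mobility mu (m^2 s^-1 V^-1).
#' @param bsa_diffusion_coeff Diffusion coefficient (m^2 s^-1).
#' @param bsa_diameter Effective molecular diameter (m).
#' @param density Mass density (kg m^-3).
#' @param heat_capacity Specific heat capacity (J kg^-1 K^-1).
#' @param initial_temperature Starting temperature (degrees C).
#' @return Object of class `sample_properties`.
#' @export
sample_properties <- function(conductivity = 0.033, pH = 7.2,
                              bsa_concentration = 0.6,
                              bsa_mobility = 1.4e-8,
                              bsa_diffusion_coeff = 6.3e-11,
                              bsa_diameter = 7.0e-9,
                              density = 998, heat_capacity = 4180,
                              initial_temperature = 22) {
  if (conductivity <= 0) stop("conductivity must be > 0", call. = FALSE)
  stopifnot(bsa_concentration >= 0, bsa_mobility >= 0,
            bsa_diffusion_coeff >= 0, bsa_diameter > 0,
            density > 0, heat_capacity > 0)
  structure(
    list(conductivity = conductivity, pH = pH,
         bsa_concentration = bsa_concentration, bsa_mobility = bsa_mobility,
         bsa_diffusion_coeff = bsa_diffusion_coeff, bsa_diameter = bsa_diameter,
         density = density, heat_capacity = heat_capacity,
         initial_temperature = initial_temperature),
    class = "sample_properties")
}

#' Homogeneous field strength between parallel-plate electrodes
#'
#' E = U / d for the applied amplitude U and electrode gap d. For the
#' default protocol and chamber this is 1470 V / 2.00 mm = 0.735 MV/m.
#'
#' @param protocol A [pulse_protocol()].
#' @param geometry A [chamber_geometry()].
#' @return Field strength (V m^-1).
#' @export
field_strength <- function(protocol, geometry) {
  if (geometry$gap <= 0)
    stop("invalid geometry: non-positive electrode gap", call. = FALSE)
  protocol$amplitude / geometry$gap
}

#' Theoretical ohmic current through the chamber
#'
#' I = sigma * A * U / d for a homogeneously conducting slab. For the
#' default BSA sample and chamber this gives 12.9 A, matching the observed
#' pulse-top current of 12.5 +/- 0.8 A.
#'
#' @inheritParams field_strength
#' @param sample A [sample_properties()].
#' @return Current (A).
#' @export
theoretical_current <- function(sample, geometry, protocol) {
  stopifnot(geometry$area > 0, geometry$gap > 0)
  sample$conductivity * geometry$area * protocol$amplitude / geometry$gap
}

#' Electromigration displacement of the protein over a pulse train
#'
#' d_mig = mu * E * (n_pulses * pulse_width), capped at the electrode gap
#' (molecules that reach the anode surface do not move further). With the
#' default mobility and protocol the anionic protein travels ~31 um toward
#' the anode.
#'
#' @inheritParams theoretical_current
#' @return Displacement (m).
#' @export
electromigration_displacement <- function(sample, protocol, geometry) {
  stopifnot(sample$bsa_mobility >= 0)
  e <- field_strength(protocol, geometry)
  min(sample$bsa_mobility * e * protocol$total_on_time, geometry$gap)
}

#' Surface amount of protein accumulated at the anode
#'
#' Swept-volume estimate Gamma = c * d_mig: all molecules initially within
#' the migration distance of the anode end up at its surface. For 0.6 mM
#' BSA moved 31 um this is 1.8e-5 mol m^-2.
#'
#' @param concentration Bulk concentration (mol m^-3).
#' @param displacement Migration displacement (m).
#' @return Surface amount (mol m^-2).
#' @export
accumulated_surface_amount <- function(concentration, displacement) {
  stopifnot(concentration >= 0, displacement >= 0)
  concentration * displacement
}

#' Monolayer surface coverage of hexagonally packed spheres
#'
#' One molecule per hexagonal unit cell of area (sqrt(3)/2) d^2:
#' Gamma_mono = 2 / (sqrt(3) * d^2 * N_A). For a 7.0 nm sphere this is
#' about 4.0e-8 mol m^-2.
#'
#' @param molecule_diameter Sphere diameter (m), > 0.
#' @param avogadro Avogadro constant override.
#' @return Surface amount (mol m^-2).
#' @export
monolayer_coverage <- function(molecule_diameter,
                               avogadro = pef_constants()$avogadro) {
  if (molecule_diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  2 / (sqrt(3) * molecule_diameter^2 * avogadro)
}

#' Number of molecular layers in an accumulated surface deposit
#'
#' @param gamma Accumulated surface amount (mol m^-2).
#' @param gamma_mono Monolayer coverage (mol m^-2), > 0.
#' @return Dimensionless layer count Gamma / Gamma_mono.
#' @export
layer_count <- function(gamma, gamma_mono) {
  if (gamma_mono <= 0)
    stop("monolayer coverage must be > 0", call. = FALSE)
  gamma / gamma_mono
}

#' Adiabatic Joule heating over the pulse train
#'
#' Delta T = U * I * t_on / (rho * V * c_p): all dissipated electrical
#' energy retained in the chamber liquid, no heat loss. The default
#' protocol at the observed 12.5 A predicts circa 12 K; the measured rise
#' is smaller because the electrodes conduct heat away.
#'
#' @inheritParams theoretical_current
#' @param current Pulse-top current (A).
#' @return Temperature rise (K).
#' @export
joule_heating_adiabatic <- function(protocol, current, geometry, sample) {
  stopifnot(geometry$volume > 0, sample$density > 0, sample$heat_capacity > 0)
  energy <- protocol$amplitude * current * protocol$total_on_time
  energy / (sample$density * geometry$volume * sample$heat_capacity)
}

#' Dynamic viscosity of water
#'
#' Vogel-Fulcher-Tammann correlation
#' eta(T) = 0.02939 * exp(507.88 / (T_K - 149.3)) mPa s
#' (Viswanath & Natarajan-type fit), accurate to well under 1 % between
#' 0 and 60 degrees C (0.9544 mPa s at 22 C vs 0.9548 tabulated).
#'
#' @param temperature_c Temperature (degrees C), within 0-60.
#' @return Viscosity (mPa s).
#' @export
water_viscosity <- function(temperature_c) {
  if (any(temperature_c < 0 | temperature_c > 60))
    stop("temperature outside the 0-60 C validity range of the viscosity correlation",
         call. = FALSE)
  0.02939 * exp(507.88 / (temperature_c + 273.15 - 149.3))
}

#' Forward map from temperature to conductivity (current) ratio
#'
#' Walden-type relation sigma proportional to 1/eta: heating the sample
#' from `t0` to `t` multiplies the ohmic current by eta(t0)/eta(t).
#'
#' @param temperature_c Final temperature (degrees C).
#' @param t0 Initial temperature (degrees C).
#' @return Dimensionless current ratio I(t)/I(t0) >= 1 for t >= t0.
#' @export
current_ratio_at_temperature <- function(temperature_c, t0) {
  water_viscosity(t0) / water_viscosity(temperature_c)
}

#' Infer the in-chamber temperature rise from the current rise
#'
#' During pulsing the ohmic current slowly grows because Joule heating
#' lowers the solution viscosity and thus raises ionic mobilities
#' (sigma ~ 1/eta, Walden's rule). Given the observed ratio of final to
#' initial pulse-top current, this inverts the water
#' viscosity-temperature correlation in closed form:
#' T = 149.3 K + B / log(eta(T0) / (ratio * A)).
#' A 7.5 % current rise from 22 C yields a rise of about 3 K
#' (final temperature about 25 C).
#'
#' @param current_ratio Final/initial current ratio, >= 1.
#' @param t0 Initial temperature (degrees C), within 0-60.
#' @return Temperature rise (K).
#' @export
temperature_from_current_rise <- function(current_ratio, t0) {
  if (current_ratio < 1)
    stop("current ratio must be >= 1 (heating only)", call. = FALSE)
  eta_t <- water_viscosity(t0) / current_ratio
  t_final <- 507.88 / log(eta_t / 0.02939) + 149.3 - 273.15
  if (t_final > 60)
    stop("current ratio implies a temperature outside the 0-60 C correlation range",
         call. = FALSE)
  t_final - t0
}

#' Amount of substance transformed per Faraday's law
#'
#' n = Q / (z F) for transferred charge Q and z electrons per event.
#'
#' @param charge Transferred charge (C), >= 0.
#' @param electrons_per_event Electrons per reaction event z, integer >= 1.
#' @param faraday Faraday constant override (C mol^-1).
#' @return Amount (mol).
#' @export
faraday_amount <- function(charge, electrons_per_event,
                           faraday = pef_constants()$faraday) {
  if (charge < 0) stop("charge must be >= 0", call. = FALSE)
  if (electrons_per_event < 1)
    stop("electrons per event must be >= 1", call. = FALSE)
  charge / (electrons_per_event * faraday)
}

#' Ratio of an observed amount to the Faraday-law prediction
#'
#' Convenience helper for comparing e.g. a detection-limit amount of
#' dissolved electrode metal with the all-charge coulometric bound.
#'
#' @param observed_mol Observed (or bounding) amount (mol).
#' @param charge Transferred charge (C).
#' @param electrons_per_event Electrons per event z.
#' @return Dimensionless fraction observed / predicted.
#' @export
faraday_fraction <- function(observed_mol, charge, electrons_per_event) {
  observed_mol / faraday_amount(charge, electrons_per_event)
}

#' Diffusional length scale for a species of lifetime tau
#'
#' L = sqrt(D * tau). A hydroxyl radical (D ~ 2.3e-9 m^2/s) living a few
#' microseconds travels tens to hundreds of nanometres, which is why
#' anodically generated HO. stays confined near the electrode.
#'
#' @param diffusion_coeff Diffusion coefficient D (m^2 s^-1), >= 0.
#' @param lifetime Species lifetime tau (s), >= 0.
#' @return Length (m).
#' @export
diffusion_length <- function(diffusion_coeff, lifetime) {
  stopifnot(diffusion_coeff >= 0, lifetime >= 0)
  sqrt(diffusion_coeff * lifetime)
}

#' Summary table of derived electrophysical quantities
#'
#' Evaluates every closed-form calculator for one protocol / chamber /
#' sample combination and returns a table of quantity, value, units and
#' formula. This is the "desk calculation" counterpart of the kinetic
#' simulator and the backend of the command-line `physics` report.
#'
#' @inheritParams theoretical_current
#' @param current Observed pulse-top current (A); defaults to the
#'   theoretical ohmic value.
#' @param current_ratio Observed final/initial current ratio during
#'   pulsing (default 1.075, a 7.5 % rise).
#' @param ho_lifetime Hydroxyl radical lifetime (s) for the diffusion
#'   length entry.
#' @param ho_diffusion Hydroxyl radical diffusion coefficient (m^2/s).
#' @return data.frame with columns quantity, value, units, formula.
#' @export
#' @examples
#' physics_report()
physics_report <- function(protocol = pulse_protocol(),
                           geometry = chamber_geometry(),
                           sample = sample_properties(),
                           current = NULL,
                           current_ratio = 1.075,
                           ho_lifetime = 1e-6,
                           ho_diffusion = 2.3e-9) {
  i_theory <- theoretical_current(sample, geometry, protocol)
  if (is.null(current)) current <- i_theory
  e <- field_strength(protocol, geometry)
  d_mig <- electromigration_displacement(sample, protocol, geometry)
  gam <- accumulated_surface_amount(sample$bsa_concentration, d_mig)
  gam_mono <- monolayer_coverage(sample$bsa_diameter)
  q_total <- current * protocol$total_on_time
  data.frame(
    quantity = c("field_strength", "theoretical_current",
                 "migration_displacement", "accumulated_surface_amount",
                 "monolayer_coverage", "layer_count",
                 "total_charge", "faraday_amount_z2",
                 "joule_heating_adiabatic", "temperature_from_current_rise",
                 "ho_diffusion_length"),
    value = c(e, i_theory, d_mig, gam, gam_mono, layer_count(gam, gam_mono),
              q_total, faraday_amount(q_total, 2),
              joule_heating_adiabatic(protocol, current, geometry, sample),
              temperature_from_current_rise(current_ratio,
                                            sample$initial_temperature),
              diffusion_length(ho_diffusion, ho_lifetime)),
    units = c("V/m", "A", "m", "mol/m^2", "mol/m^2", "-", "C", "mol",
              "K", "K", "m"),
    formula = c("U/d", "sigma*A*U/d", "mu*E*n*t_p", "c*d_mig",
                "2/(sqrt(3)*d^2*N_A)", "Gamma/Gamma_mono", "I*n*t_p",
                "Q/(2F)", "U*I*t_on/(rho*V*c_p)",
                "invert eta(T0)/eta(T)=I_ratio", "sqrt(D*tau)"),
    stringsAsFactors = FALSE)
}
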