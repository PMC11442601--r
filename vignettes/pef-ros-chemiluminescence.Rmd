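---
title: "Modelling PEF-driven ROS chemistry and chemiluminescence in protein solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PEF-driven ROS chemistry and chemiluminescence in protein solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pefros)
```

## The system being modelled

When a conductive protein solution is exposed to a train of intense
electric pulses between two electrodes, charge crosses the
electrode/electrolyte interfaces and drives electrochemistry: water and
dissolved species are oxidised at the anode and reduced at the cathode.
The oxidation side generates reactive oxygen species (ROS) — hydroxyl
radicals (HO·), hydroperoxyl radicals (HO2·) and their conjugate base
superoxide (O2·−), and hydrogen peroxide — which attack the protein.
Oxidised protein peroxyl radicals fragment into electronically excited
products (triplet carbonyls, singlet oxygen) whose relaxation emits
photons: ultraweak chemiluminescence, countable with a photomultiplier
through a perforated cathode. `pefros` implements this chain as a
mechanistic simulator for a parallel-plate treatment chamber with a
bovine serum albumin (BSA) solution as the model sample, plus the
closed-form electrophysics of the chamber and the photon-count analysis
pipeline used to quantify such experiments.

The default configuration describes a thin-layer chamber (2.00 mm gap,
5.31 cm² electrode area, 1.06 mL volume) driven by 30 unipolar pulses of
1470 V and 100 µs at 1 Hz, filled with 0.6 mM BSA at pH 7.2 and
conductivity 0.033 S/m. Those inputs fix every desk quantity the package
computes: a field of 0.735 MV/m, an ohmic current of 12.9 A, a
BSA electromigration displacement of ~31 µm toward the anode,
an accumulated surface amount of 1.8×10⁻⁵ mol/m² (hundreds of
monolayers), an adiabatic Joule heating bound of ~12 K, and a
current-rise temperature estimate of ~3 K.

```{r}
physics_report()
```

## The reaction network

`load_network()` reads a delimited table of 29 labelled reactions
grouped into anodic electrooxidation, bulk ROS chemistry, protein
oxidation, Fenton iron cycling, enzymatic antioxidant reactions and
cathodic electroreduction. Species carry charge, elemental composition
and transport metadata; every reaction is checked for charge balance
(counting the transferred electron) and, for small species, element
balance. The network, rate constants, and all channel weights live in
`inst/extdata/reactions_default.tsv` with a provenance string per row;
any value can be overridden per run (`k_overrides`) or by supplying a
different table.

Key modelling decisions, all editable through the table or function
arguments:

* **Rate constants.** Bulk radical constants follow the standard
  aqueous radiation-chemistry compilations (HO· recombination
  5.5×10⁹ M⁻¹s⁻¹, HO·+HO2· 6.6×10⁹, HO2· disproportionation 8.3×10⁵,
  HO2·+O2·⁻ 9.7×10⁷, HO·+H2O2 2.7×10⁷); Fenton 76 M⁻¹s⁻¹; SOD
  2×10⁹ and CAT 1.7×10⁷ M⁻¹s⁻¹ per substrate molecule in the
  kcat/KM (substrate-linear) regime; singlet-oxygen solvent quenching
  2.9×10⁵ s⁻¹. Product assignments that the mechanism leaves verbal
  (the singlet-oxygen branches of the radical–radical reactions, the
  peroxyl fragmentation) are fixed to balanced choices and flagged
  `assumed` in the provenance column.
* **The superoxide/hydroperoxyl acid–base pair** is treated as an
  instantaneous equilibrium at the buffered pH (pKa 4.8, ~0.4 % HO2·
  at pH 7.2), repartitioned continuously inside the ODE right-hand
  side. This removes the fastest (protonation) timescale from the
  system. An explicit-kinetics mode (`superoxide_mode = "explicit"`)
  adds deprotonation/protonation reactions derived from the same pKa.
* **pH is clamped**: the solutions are phosphate-buffered, so H⁺, OH⁻
  and water are fixed species whose activities are folded into rate
  constants.
* **Superoxide-driven peroxide decomposition (reaction 12).** The
  uncatalysed constant for O2·⁻ + H2O2 → HO· is ~0.13 M⁻¹s⁻¹, which
  renders the reaction dynamically inert: with it, superoxide removal
  by SOD could not change the photon output, and no post-pulse
  conversion of the superoxide reservoir into hydroxyl radicals would
  occur — contradicting the observed enzyme effects this mechanism is
  meant to express. Trace transition metals (the iron carried by the
  protein) catalyse this step. The shipped table therefore carries an
  effective iron-catalysed constant of 10⁴ M⁻¹s⁻¹ (flagged `assumed`);
  the uncatalysed value is restored with
  `load_network(k_overrides = c("12" = 0.13))`.

## Electrode source terms

The pulse train is converted into a rectangular current profile
(`build_current_profile()`), ohmic by default (12.9 A per pulse). While
a pulse is on, the instantaneous current is partitioned over the
electrode reaction channels by concentration-weighted competition:
channel *i* receives fraction `f_i ∝ w_i·c_i` (constant-activity
channels such as water oxidation use `w_i` alone), and its molar event
rate is `I·f_i/(z_i·F)`, which closes Faraday's bookkeeping exactly at
both electrodes.

The channel weights are not identifiable from photon-count data and are
explicit tunables. The defaults express the qualitative behaviour of a
steel anode: the lumped four-electron water-oxidation channel (reaction
4, surface ROS intermediates converted directly to ground-state O₂)
carries most of the current, the single-electron HO· escape channel
(reaction 1) a few percent, and H2O2 electrooxidation (reactions 3/10)
competes in proportion to the local H2O2 concentration — which makes
the current partition saturate with peroxide dose and is the model's
source of dose non-linearity. Direct protein electrooxidation (reaction
14) is a minor channel proportional to locally accumulated protein.

## Compartments and transport

The chamber is resolved into three well-mixed boxes: a thin anode layer
(default 100 nm, the diffusional length scale of a microsecond-lived
HO·), the bulk, and a cathode layer. Small species exchange
between a layer and the bulk with first-order coefficient D/δ² using
per-species aqueous diffusion coefficients. Protein-bound material —
BSA and its radicals, the trace iron it carries, and the enzymes — is
treated as *deposited*: it electromigrates into the anode layer while
the field is on (flux µ·E·c, mobility 1.4×10⁻⁸ m²s⁻¹V⁻¹) and does not
diffuse back. This implements the preconcentration picture: by the end
of the train the anode layer holds hundreds of monolayers of protein
*and its iron*, so Fenton chemistry and radical attack are co-located
with the accumulated substrate. A single-box well-mixed mode exists for
oracle tests against closed-form kinetics.

Cathodic chemistry (hydrogen evolution, oxygen reduction to superoxide
and peroxide) is simulated but the cathode layer is not photon-visible:
the detector faces the anode through the perforated cathode, so only
anode-layer and bulk emission reaches it.

## Photon emission and detection

Three emission channels carry a wavelength: monomolecular singlet-oxygen
decay (1278 nm, invisible to the photomultiplier), bimolecular (dimol)
singlet-oxygen decay (634 nm), and triplet-carbonyl relaxation
(~425 nm). Per-band photon rates are `N_A · φ · flux` summed over
visible compartments; cumulative photons per band are integrated as ODE
states, so microsecond emission bursts during pulses are binned exactly
into 1 s counting bins without aliasing. The detector model applies a
geometric collection efficiency (default 0.01, absorbing solid angle
and cathode perforation; not fitted), band quantum efficiencies (12.2 %
averaged over 300–550 nm, 0.55 % over 550–650 nm, 0 in the near IR) and
a dark floor of 21 counts/s.

Absolute chemiluminescence quantum yields for this system are unknown —
there is no absolute photon-flux calibration to anchor them — so all
emission channels share one small placeholder yield (φ = 10⁻⁸ photons
per reaction event, `default_photon_yields()`). It was set once so that
the strongest scenario produces count rates of the order instruments
report (10²–10³ counts/s above dark); because it is a single common
scale factor, every ordering and ratio claim the package makes is
independent of its value. Only relative statements are supported.

## What the simulator reproduces, and what it cannot

With default parameters the simulated scenario suite shows the
qualitative signatures of the mechanism:

* buffer alone (`pb`) gives an essentially flat, very small pulsing
  signal (surface ROS converted to O₂; only dimol emission leaks out);
* protein alone (`bsa`) gives a rising pulsing signal (protein and its
  HO· capture accumulate at the anode pulse by pulse);
* protein + peroxide (`bsa_h2o2`) is far larger than the sum of `bsa`
  and `pb_h2o2` — the synergy arises because peroxide electrooxidation
  feeds a superoxide reservoir whose iron-catalysed conversion to HO·
  attacks the abundant protein, on top of Fenton chemistry co-located
  with the accumulated protein–iron deposit;
* catalase removes the peroxide within seconds of mixing and collapses
  the peroxide-dependent signal; superoxide dismutase removes the
  electrogenerated superoxide reservoir, so its effect is concentrated
  in the pulsing and early post-pulsing phases and nearly absent before
  pulsing;
* pulsing-window integrals grow monotonically and non-linearly with
  peroxide dose (0.1/1/10 mM).

The simulator does *not* reproduce absolute magnitudes: the dimol
channel in particular is quadratic in a nanomolar-scale singlet-oxygen
concentration and lands many orders of magnitude below the dark floor
for buffer scenarios, whereas instruments do record a small signal
there. Passing the qualitative suite therefore shows the mechanism's
internal consistency, not quantitative agreement with any measured
transient (which is experimental data outside the model's reach).

## Synthetic data generator

Analysis-stage code is tested without any kinetics through
`parametric_template()`: piecewise expected-rate curves with the
experiment's structure (60 s pre-pulsing baseline, 30 s pulsing, long
post-pulse relaxation; flat buffer plateau versus saturating protein
rise; a saturating peroxide dose factor c/(c+K) with K = 2 mM;
catalase/SOD suppression factors). `generate_transient()` draws
per-bin counts as Poisson(dark + expected(t)) on a 1 s grid over
0–500 s (reported 0–150 s, where all signal changes occur), driven by a
single integer seed; `generate_assay_data()` produces forward
Beer–Lambert absorbances with Gaussian noise for the Ellman
(ε = 14150 M⁻¹cm⁻¹, 1 cm) and Brady (ε = 22 mM⁻¹cm⁻¹, 0.2893 cm)
calculators. The templates emulate curve shapes, counting noise and the
dark floor; they do not emulate instrument drift, cosmic-ray spikes or
dark-count autocorrelation.

## Numerical choices

* Stiff integration with `deSolve::ode(method = "lsoda")`, relative
  tolerance 10⁻⁶, absolute tolerance 10⁻¹⁵ M on concentrations
  (separate absolute tolerances for the cumulative charge and photon
  states). Integration is segment-wise with every pulse edge an exact
  boundary; within pulses the step is capped at a tenth of the pulse
  width.
* The right-hand side never clips negative concentrations: mass-action
  rates are polynomials and smooth across zero, and clipping would put
  a kink exactly at the operating point of quasi-steady radical
  species, destroying the implicit solver's finite-difference Jacobian
  (observed as microsecond step-size collapse). Small negative
  excursions are clipped only in the reported trajectory, within
  10⁻¹² M; anything worse aborts with a diagnostic.
* The water viscosity–temperature correlation used by the thermometry
  is the Vogel–Fulcher–Tammann fit
  η(T) = 0.02939·exp(507.88/(T−149.3 K)) mPa·s, valid 0–60 °C and
  inverted in closed form, so the forward/inverse round trip is exact
  to well under 0.01 K.
* Default problem sizes: full scenario simulations integrate 17 species
  × 3 compartments from mixing (−170 s) to 120–150 s through 30 pulse
  segments; oracle tests use sub-networks of ≤3 reactions; the Poisson
  recovery check uses 200 replicates of 150 one-second bins.

## Known limitations

Ozone electro-generation, singlet-oxygen attack on the protein,
residue-resolved protein chemistry, pH dynamics, ionic-strength
corrections, spatially resolved fields (the perforation hotspots),
bubble nucleation and electrode passivation are all outside the model's
scope. The three-box topology lets cathodically generated small species
reach the bulk faster than a 2 mm diffusion path allows, which slightly
overstates their contribution at late times. The anode-layer thickness
δ and the electrode channel weights are assumptions, reported with
every network table, not fitted quantities.
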