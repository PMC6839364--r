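---
title: "From CBCT acquisition parameters to organ dose and secondary-cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CBCT acquisition parameters to organ dose and secondary-cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctrisk)
```

## The problem

Kilovoltage cone-beam CT on the treatment gantry is acquired repeatedly
over a radiotherapy course, and respiration-resolved (4D) acquisition
lengthens the scan and raises the imaging dose. `cbctrisk` implements
the standard radiation-protection chain for this setting: organ mean
absorbed dose → equivalent dose → ICRP-103 effective dose → BEIR VII
excess absolute risk (EAR) of secondary cancer incidence, together with
the acquisition-protocol arithmetic that scales dose with tube output
and a synthetic phantom/beam/cohort layer that lets every step be
exercised without patient data.

## The risk model

**Equivalent and effective dose.** For photon fields the radiation
weighting factor is 1, so organ equivalent dose in mSv equals mean
absorbed dose in mGy. The effective dose is the tissue-weighted sum

$$E = \sum_T w_T \sum_R w_R D_{T,R},$$

with the ICRP-103 weights: 0.12 for lung, stomach, bone marrow, colon,
breast and the remainder group; 0.08 for gonads; 0.04 for esophagus,
liver, thyroid and bladder; 0.01 for bone surface, skin, brain and
salivary glands. The remainder weight 0.12 applies to the *arithmetic
mean over the 13 designated remainder organs*, always dividing by 13:
when only a subset of remainder organs is inside the imaged volume (7
of them in a thoracic scan, say), the unmeasured ones contribute zero
rather than shrinking the divisor. This fixed-divisor reading is the
one under which tabulated per-organ doses and their published effective
doses are mutually consistent, and it is the package default
(`icrp103_weights()`); the divisor and the organ lists are editable
through the YAML config shipped in `extdata`. Organs absent from a dose
table simply contribute zero — no re-normalisation of weights — which
is how a thyroid outside the liver-scan range is handled.

The ICRP remainder list is sex-specific in its 13th organ (prostate or
uterus/cervix); the package folds the two into a single
`prostate_uterus` slot so that one scheme with exactly 13 remainder
organs serves both sexes.

**Excess absolute risk.** The BEIR VII incidence model is

$$\mathrm{EAR} = \beta_{M/F}\, D_T\,
  \exp\!\Big(\gamma\,\frac{e-30}{10}\Big)
  \Big(\frac{A}{A_0}\Big)^{\eta},$$

with organ- and sex-specific `β` in cases per 10⁴ person-years per Gy,
exposure age `e`, attained age `A`, and `A₀ = 60`. Doses enter in mSv
and are converted to Gy; results are rescaled to cases per 10⁶
person-years. Two modelling choices deserve note:

* *Unclamped exposure-age modifier.* BEIR VII caps the exposure-age
  term at `e = 30` for later exposures; this package applies
  `exp(γ(e−30)/10)` as written for all `e ≥ 30`. That is the form under
  which an EAR-versus-time-since-exposure series (attained age fixed at
  70, exposure at 60/50/40/30) behaves as the published thyroid series
  does, and it is what `ear_time_series()` computes.
* *Fallback parameters.* Organs without organ-specific EAR parameters
  (thyroid, esophagus, skin, kidney, pancreas, and anything else not in
  the table) resolve to the "other solid cancer" tuple
  (β = 5.1/4.2, γ = −0.39, η = 1.9). The packaged table carries lung,
  stomach, liver and intestine (colon parameters) explicitly.

EARs are computed per sex from the cohort's common mean doses, not per
patient: the sexes differ only through `β`.

## Acquisition-protocol arithmetic

For a pulsed CBCT acquisition the total tube current-time product per
acquisition is `A · T_acq · F · T_pulse` — tube current times wall-clock
acquisition time times frame rate times pulse duration. The three
shipped protocols (thorax 20 mA/60 s/15 f/s, pelvis 80 mA/60 s/15 f/s,
4D 40 mA/120 s/7 f/s, all with 20 ms pulses at 125 kV) give 360, 1440
and 672 mAs. (A published protocol summary elsewhere lists 624 mAs for
the 4D mode; 672 is what the stated parameters multiply to, so the
shipped config uses 672 — protocols are user-editable YAML.)

Absolute dose scales a per-simulation dose by a measured calibration
factor and the protocol output:

$$D_{abs} = D_{MC}\cdot f_{cal}\cdot N\cdot A\cdot T_{acq}\cdot F\cdot
T_{pulse},$$

with `f_cal = D_w / (D_MC · A_cal · T_cal)` from a reference exposure
(257 mA, 0.777 s — times are handled in seconds internally; the
published 777 ms value is converted explicitly). The magnitude of
`f_cal` depends on the Monte Carlo per-history normalisation, so it is
carried as configuration, never recomputed. Everything here is exact
arithmetic: protocol dose ratios equal mAs ratios to the last bit, and
the calibration followed by `absolute_dose()` at reference conditions
returns the measured dose exactly.

## Dose grids, masks and I/O

Dose grids are voxel-centered, 0-based, axes x (patient right), y
(anterior→posterior), z (inferior→superior), 2.5 mm isotropic by
default — stated explicitly because grid conventions are otherwise a
perennial source of silent error. Organ masks are logical volumes
congruent with their grid; mean organ dose is the plain arithmetic mean
over mask voxels, checked in the tests against a brute-force voxel
loop. Grid I/O uses a self-describing text container in two dialects:
`portable` (full-precision, bit-exact round-trips) and `rtdose-like`,
which stores non-negative 16-bit integers with a per-file dose-scaling
factor exactly as DICOM RTDOSE's DoseGridScaling does; the scaling is
chosen to use the full integer range, bounding the reconstruction error
by `max/2¹⁶`. CT-number-to-material labelling uses three increasing
thresholds (defaults −850/−200/250 HU) over air/lung/tissue/bone, with
a value at a cut point assigned to the upper class; the thresholds are
configuration, standing in for a scanner calibration curve. A
treatment-couch slab can be relabelled into the posterior air gap
(overlap with body voxels is an error; zero thickness is a no-op).

Masks congruent with the grid cannot represent an organ extending
beyond the scan range; such organs must be truncated at phantom
definition, and their mean dose then refers to the imaged part only —
the same caveat that applies to real planning-CT ranges.

## The synthetic layer

The synthetic modules replace patient CTs and Monte Carlo transport
with deliberately simple, fully characterised stand-ins.

**Phantoms.** A body is an elliptic cylinder of tissue with ellipsoidal
organs (any of the four materials) placed inside it; voxelization at
2.5 mm recovers analytic ellipsoid volumes within 10%. Cohorts are
sampled from truncated normal height and BMI distributions with
site-specific defaults (lung site: height 154.6 ± 10.3 cm, BMI
21.7 ± 3.2 truncated to 14–29, 43% male; liver site: 159.0 ± 7.7 cm,
22.5 ± 4.4 truncated to 15–35, 80% male) chosen to emulate the
demographic spread of two published 15-patient cohorts, so that default
draws span all three WHO BMI classes. Torso geometry follows from
anthropometry: length 30% of height, volume 40% of body mass at unit
density, lateral-to-AP axis ratio 1.4 — plain textbook proportions,
stated here because they are choices, not data. The seed is a mandatory
field of `cohort_spec()`; all sampling is seed-deterministic.

**Beam and dose deposition.** `simulate_rotational_dose()` is an
analytic primary-beam model: per gantry angle (0° = source anterior;
default 2° steps over a full rotation), parallel rays are attenuated
exponentially through the traversed materials, restricted to the
asymmetric field aperture (26.5 × 19.8 cm at isocenter, lateral
half-widths 23.9/2.6 cm — the offset-detector half-fan geometry — and
axial half-widths 9.9/9.9 cm), and modulated by two monotone
exponential profiles: a half-bowtie across the fan (strength 0.4) and a
heel-effect gradient along the tube axis (strength 0.2). Dose deposits
as fluence × a per-material energy-absorption weight, and the absolute
scale comes from a reference dose rate (0.1 mGy/mAs) times the
protocol's `N ×` total mAs, so the simulator is *exactly* linear in
every protocol factor. Effective attenuation coefficients
(air 2·10⁻⁵, lung 0.0055, tissue 0.021, bone 0.055 mm⁻¹) and the
absorption weights are configuration defaults representative of a
125 kV beam (HVL ≈ 8.9 mm carried as metadata); they are not fitted to
any measurement.

What the simulator is *for* — and what passing tests therefore show —
is geometry, linearity and asymmetry: depth curves decrease
monotonically (no buildup is modelled), a symmetric beam over a
centered cylinder gives a rotationally symmetric dose field within
discretization tolerance, enabling the modulators produces > 2%
lateral/axial profile asymmetry, protocol dose ratios are exact, and
effective dose falls as body radius grows (the BMI trend). What it is
*not* is dosimetry: there is no scatter, no buildup, no spectrum, and
absolute outputs are on the order of, but not calibrated to, clinical
CBCT doses. Conclusions about real organ doses require Monte Carlo
transport or measurement; conclusions about the *risk pipeline
downstream of a dose table* do not, which is why the packaged
fixture tables drive the quantitative checks while the simulator
drives the property checks.

**Numerical choices.** Ray marching steps one voxel along the dominant
beam axis with nearest-neighbour material lookup; voxels outside the
grid attenuate as air. This makes the rotational-symmetry check a
tolerance comparison (5% on mirrored voxels within the body) rather
than an identity. Degenerate inputs fail loudly: empty masks, organs
outside the body, angles outside [−180°, 180°], non-monotone CT
thresholds, couch-body overlap, corrupt grid headers and negative
scalings are all distinct errors.

## The pipeline and its reports

`run_pipeline()` composes sampling → voxelization → simulation → dose
extraction → effective dose → EAR. Simulation mode irradiates each
patient once under the first protocol and derives the other protocols
by their exact mAs ratios (the simulator is linear, so this is an
identity, not an approximation). Default problem sizes — 5 mm voxels,
10° gantry steps, and whatever cohort size the `cohort_spec` requests —
keep a full run at desk scale; the 2.5 mm / 2° settings of a
planning-grade run are available through the same arguments.
Fixture mode feeds the packaged cohort mean-dose tables straight into
the risk computations and is bit-reproducible; simulation mode is
bit-reproducible for a fixed seed. Reports serialize to JSON and read
back with numeric content preserved to near machine precision
(JSON decimal round-trips cost about one ulp, which is why the
round-trip tests use a 10⁻¹² tolerance rather than identity).

Cohort summaries are reported as mean ± SD with *sample* SD by default
(`population = FALSE`); published "±" values rarely state which
convention they use, so the flag exists and the quantitative checks
compare means only.

## Known limitations

* Primary-beam-only transport: no scatter, buildup, spectrum or
  detector model; absolute simulated doses are indicative only.
* The remainder-organ rule is the fixed-divisor reading; schemes with
  per-count averaging can be expressed by editing `remainder_divisor`
  but are not the default.
* No excess-relative-risk, lifetime-attributable-risk or DDREF
  machinery — the EAR model above is the deliberate scope.
* No uncertainty propagation on β, γ, η; EAR uncertainties from
  parameter uncertainty are typically larger than those from dose
  rounding.
* Organ masks are voxel labels; contour (polygon) structures and
  dose-volume histograms beyond the mean are out of scope.
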