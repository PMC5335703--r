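---
title: "Models and methods behind acrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrtools)
```

acrtools packages the quantitative workflow used to discover and
characterise natural anion channelrhodopsins (ACRs): light-gated
chloride channels from cryptophyte algae whose fast, large
photocurrents make them efficient inhibitory optogenetic tools.  This
vignette explains the models the package implements, the defaults it
ships, and the limits of what its synthetic data can show.

## Electrochemistry

All selectivity reasoning rests on three closed forms.

**Nernst and GHK.**  `nernst_potential()` gives the single-ion
equilibrium potential $(RT/zF)\ln(c_\mathrm{out}/c_\mathrm{in})$;
`ghk_current()` the constant-field (Goldman–Hodgkin–Katz) flux
$$I \propto P z^2 \frac{VF^2}{RT}\,
  \frac{c_\mathrm{in} - c_\mathrm{out}e^{-zVF/RT}}{1 - e^{-zVF/RT}},$$
evaluated through the numerically stable factor $u/(1-e^{-u})$ so the
$V=0$ singularity is removed analytically; and `ghk_reversal()` the
zero of the summed flux, found by root bracketing so that divalent
ions need no special-cased voltage equation.  Divalent permeabilities
default to zero: the channels under study are anion-selective, and the
packaged default permeability set is chloride-only.  With a single
permeant ion the numeric root agrees with the Nernst closed form to
better than $10^{-6}$ mV, which the test suite asserts.

**Packaged solutions.**  The pipette (KCl 126, MgCl$_2$ 2, CaCl$_2$
0.5, Na-EGTA 5, HEPES 25 mM) and standard bath (NaCl 150, CaCl$_2$
1.8, MgCl$_2$ 1, glucose 5, HEPES 10 mM) compositions dissolve to 131
and 155.6 mM free Cl$^-$.  HEPES is treated as an uncharged
zwitterion at pH 7.4 and Na-EGTA as the disodium salt; glucose is
neutral.  The chloride Nernst potential between these solutions is
$-4.42$ mV.  The substitution experiment replaces a fraction of the
bath NaCl mole-for-mole with sodium aspartate — aspartate being the
standard non-permeant anion — and the replacement fraction is a
configurable parameter of `aspartate_bath()`.  The underlying protocol
states only that the replacement was partial; the package default is
70%, which puts the non-permeant-limit reversal at $+24.4$ mV and
gives substitution shifts of realistic size (about $-29$ mV).  Solutions
can be serialised to and from YAML (`read_solutions()`).

**Liquid junction potentials.**  Command potentials are corrected as
$V = V_\mathrm{cmd} - E_\mathrm{LJ}$, with $E_\mathrm{LJ}$ from the
Henderson equation (`henderson_ljp()`), the same approximation used by
the LJP calculators built into acquisition software.  Mobilities are
packaged relative to K$^+$ (the equation is scale-invariant), sourced
from the standard patch-clamp junction-potential tables; the sign
convention (bath minus pipette) and the subtraction are documented at
the function and exercised by antisymmetry/closed-form tests.

**Photometry.**  `photon_flux_density()` converts irradiance to photon
flux via $P\lambda/hc$.  Spectral sensitivity uses the Govardovskii
A1 alpha-band nomogram as the default "continuous approximation" of a
retinal pigment's spectrum, with a Gaussian-in-inverse-wavelength
alternative.  The nomogram's analytic peak sits a fraction of a
nanometre off its nominal $\lambda_{max}$, so the package rescales the
wavelength axis by the numerically located peak; this pins the maximum
exactly at $\lambda_{max}$ with value 1, which downstream fitting
assumes.

## The synthetic photocurrent generator

The generator is first-class, tested code: it defines the statistical
structure the analysis pipeline assumes.

**Gating model.**  A three-state scheme (closed/open/desensitized) is
the minimal model producing the observed peak–stationary–decay
phenomenology.  During light, C$\to$O at
$k_\mathrm{act} = k_\mathrm{act}^{max}\,T(\lambda)\,I/(I+I_{50})$,
O$\to$D at $k_d$, D$\to$O at $k_r$; after light-off O$\to$C at
$k_\mathrm{close} = 1/\tau_\mathrm{off}$ and D$\to$C at
$k_\mathrm{rec}$ (default equal to $k_\mathrm{close}$, which makes the
off-decay of the open state exactly single-exponential — an identity
the kinetics tests rely on).  Under saturating light the stationary
open fraction is $k_r/(k_d+k_r)$, so inactivation endpoints of 12.5%
and 83.6% correspond to $(k_d, k_r)$ pairs $(0.25, 1.75)$ and
$(8.36, 1.64)$ s$^{-1}$.  Note that these identities hold in the
steady-state limit: within a 1-s pulse, a relaxation rate of
$k_d+k_r = 2$ s$^{-1}$ has not fully settled and the activation step
is not infinitely fast, so the inactivation a faithful trace pipeline
measures is somewhat below the steady-state arithmetic (about 10.3%
rather than 12.5% for the slow pair, 82.4% rather than 83.6% for the
fast one).  The package reports what the pipeline measures.

Integration is fixed-step 4th-order Runge–Kutta at 0.02 ms (refused if
`dt` times the fastest rate exceeds 0.5); occupancies are conserved to
$10^{-6}$.

**Acquisition.**  Traces are resampled at 5 kHz and passed through a
4-pole low-pass Butterworth at 2 kHz approximating the hardware Bessel
anti-alias filter (the exact Bessel phase response is deliberately not
modelled).  Gaussian noise is injected before the filter, scaled by the
filter's impulse-response energy so that the *output* RMS equals the
configured `noise_sd` — verified against a filtered-white-noise
variance oracle.  Every stochastic element is seeded; the same seed
yields bit-identical traces.

**Current scale.**  $I(t) = g\,O(t)\,u(V)$, where $u(V)$ is the summed
GHK current of the permeant ions normalised to unit slope at the
reversal potential.  This makes `g_scale` the slope conductance at
reversal in nS (so currents come out in pA) while preserving GHK
curvature and the exact zero crossing.

**Protocols.**  `synthesize_iv_family()` reproduces the 20-mV-step
voltage family from $-60$ to $+60$ mV under the standard and
substituted baths; `synthesize_spectral_responses()` the low-intensity
action-spectrum scan, run forward then reverse in wavelength, with
multiplicative noise and an optional linear sensitivity drift
(rundown) that forward/reverse averaging cancels to first order;
intensity is flagged when it leaves the linear range ($>0.1\,I_{50}$).

**Neuron model.**  Spike suppression is simulated with a leaky
integrate-and-fire neuron (exponential-Euler, dt 0.01 ms; C = 100 pF,
g$_\mathrm{leak}$ = 10 nS, rest $-70$, threshold $-50$, reset $-65$ mV,
2 ms refractory) driven by 1-ms, 2.5-nA pulses at 50 Hz — parameters
chosen so each dark pulse fires exactly one spike, which the simulator
enforces as a precondition.  The light-gated chloride conductance steps
instantaneously to $g_0$ at light onset (channel opening is far faster
than a millisecond) and decays exponentially with $\tau_\mathrm{off}$
after light-off.  With $g_0 = 200$ nS, $E_\mathrm{rev} = -75$ mV and a
20-ms pulse placed 2 ms after a spike, $\tau_\mathrm{off} = 2.3$ ms
deletes exactly one spike from the train while the 21-fold slower
48.3-ms variant silences many successive spikes — the qualitative
contrast that motivates fast-closing channels for high-frequency
photoinhibition.

## The analysis pipeline

Metrics are deliberately simple and windowed: peak is the sign-aware
extremum inside the light epoch after a 2-ms settling margin;
stationary is the mean over the final 10% of the epoch ("near the end"
— the fraction is configurable); the reversal-shift metric averages the
whole epoch, trading temporal resolution for noise suppression, which
is justified because peak- and stationary-current reversal potentials
agree within 2 mV when selectivity does not change during
illumination.  Reversal potentials interpolate linearly between the
first bracketing sign change scanning from the most negative voltage
(the tie-break matters once noise creates multiple crossings).
`fit_permeability_ratio()` inverts the GHK prediction of the shift by
1-D root finding, with a 0.5-mV boundary tolerance so that
grid-interpolation error just past the non-permeant floor maps to
ratio 0 instead of an error.

Off-kinetics are summarised twice, on purpose: the model-free
half-decay time (first 50% crossing after light-off, interpolated
between samples; its reciprocal is the "decay rate") and a
single-exponential fit by Levenberg–Marquardt, which also reports
$t_{1/2} = \tau\ln 2$ and $t_{90} = \tau\ln 10$.  The two agree within
one sample interval on exponential data.  The half-decay reference is
the current at the light-off instant (not the preceding peak) — the
natural reading of a "decrease after light-off" — and is switchable.

Action spectra average forward and reverse scans, divide by the photon
flux actually delivered at each wavelength (quantum-density
correction), normalise to the maximum, and fit $\lambda_{max}$ by
least squares against the pigment template with a coarse-grid start
followed by local refinement; a spectrum whose corrected range is
below 10% of its maximum is flagged unreliable rather than fitted
blindly.  Intensity-response data are fitted with the saturation
hyperbola $R = R_{max} I/(I+I_{50})$, the form implied by the gating
model, falling back from `nls` to direct least squares on degenerate
(zero-residual) data; an absence of curvature flags $I_{50}$ as a
lower bound.

Spike metrics mirror the photoinhibition figures: per-stimulus response
amplitudes normalised to the mean of the last five spikes before light
onset (fewer, with a warning, when fewer exist), and suppression
counted per stimulus against the dark control.

## Sequence analysis

Reference-numbered reporting drives everything: queries are globally
aligned (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1, via
Biostrings) to a packaged reference and residues are read off at the
nine selectivity-filter positions 82, 83, 90, 97, 101, 117, 123
(the Schiff-base counterion, homolog of bacteriorhodopsin Asp85), 128
and 242 in channelrhodopsin-2 numbering.  The packaged reference is a
**synthetic** 7TM-like stand-in carrying the authentic residues at
those positions (the real protein sequence is not redistributed);
likewise the GtACR1-like and ZipACR-like fixtures reproduce the
documented alignment relations (e.g. the 90-position glutamate at
native position 68, or Glu96/Asn108/Gly114 at positions 101/117/123)
without being the real sequences.  The GtACR1-like fixture carries Asn
at position 79: the source literature calls that residue both Gln79
and (via the N79E mutant) Asn — the fixture documents rather than
resolves the discrepancy.

Classification is rule-based on three positions: a conserved
90-glutamate with a glutamate at the 242-position and a
non-carboxylate counterion is natural-ACR-like; a carboxylate
counterion with the 90-glutamate is CCR-like; a neutralised or basic
90-position is engineered-anion-like; anything else, or an incomplete
fingerprint, is indeterminate.  Every call carries the caveat that
helix-2 glutamate content alone does not predict selectivity — cation
channels exist with ACR-like helix-2 patterns, and the highly
conductive natural ACRs include one that retains the 101-glutamate.

The search layer is a position-specific log-odds profile (Laplace
pseudocount, uniform background, log2) with affine gaps whose
penalties halve in columns that are majority-gap — a lightweight
stand-in for a profile HMM that supports the recursive-search
semantics; forward-algorithm scoring is a non-goal.  Scoring is best
local profile-to-sequence alignment by Gotoh dynamic programming.
Profile scores are not comparable across search tools, so no universal
threshold is packaged: the default is calibrated per profile from
residue-shuffled decoys (99.5th percentile of 100 shuffles), targeting
a decoy false-positive rate below 1%.  `recursive_search()` rebuilds
the profile from the confirmed set each round and stops at a fixed
point; the confirmed set never shrinks.  `dedup_and_filter()` mirrors
the manual curation of a transcriptome screen: drop sequences covering
under 70% of the reference transmembrane span (positions 34–280 of the
packaged reference), and collapse same-source pairs that are ≥99%
identical over that span, keeping the longest.

`generate_synthetic_family()` is the benchmark generator: homologs at
a stated per-site divergence with fingerprint positions pinned, plus
composition-matched shuffled decoys, all seeded and labelled.  Planted
homologs at 40% divergence separate from decoys with AUROC 1.0.

## Catalog and problem sizes

The packaged catalog replicates the 22-entry study table (accessions
KX879674–KX879692, KP171708/9, KF992074): 20 functional members, of
which 17 are new, and two non-functional transcripts.
`derive_abbreviation()` encodes the naming convention — genus +
species initials, or italicised strain digits for taxa unclassified at
the species (*G1*, *R1*, *R2*) or genus (*C1*) level, plus the last
three transcript digits; *Proteomonas sulcata* keeps the historical
two-letter "su" prefix.  The three previously-known proteins predate
the convention and are stored, not derived.

Simulated problem sizes throughout the tests and the acceptance script
are chosen to exercise the estimators at realistic operating points
while staying desk-scale: 1-s pulses at 5 kHz (≈5,000 samples per
trace), 7-voltage families, 21-wavelength double scans with 20 noise
seeds, 400-ms spike trains at 0.01-ms resolution, and 150–300-residue
synthetic families with up to 100 decoys.

## What passing tests do and do not show

The generator shares its electrochemistry and templates with the
analysis pipeline; round-trip recoveries therefore validate estimator
logic (windows, corrections, interpolation, fitting), not the physics
of real channels.  Real recordings add series-resistance and
capacitive artefacts, rundown that is not linear, cell-to-cell
parameter spread, and Bessel (not Butterworth) phase behaviour — none
of which the generator emulates.  Conclusions about real ACRs should
rest on the pipeline's measurements of real traces; the synthetic
layer exists to prove the measurements correct where the answer is
known.
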