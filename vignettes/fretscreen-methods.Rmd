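---
title: "Models and methods behind fretscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

This vignette documents the statistical models, numerical choices and
design decisions in `fretscreen`, in the spirit of a methods supplement:
what is being fitted, under which assumptions, and what the synthetic-data
generator does and does not emulate.

## The assay and its signal

The assays pair a CFP-fused protein (FRET donor) with a YFP-fused partner
(acceptor). On binding, energy transfer decreases donor emission (477 nm)
and increases acceptor emission (527 nm) under donor excitation (410 nm);
the working signal is the blank-corrected ratio **rFRET = I(527)/I(477)**.
Being a ratio, it is insensitive to well-to-well volume variation — the
single most important robustness property of the design, and the reason
the simulator's dominant noise term (a shared per-well dispense factor)
barely moves it.

Two configurations are built in: `sim_config()` describes a high-affinity
peptide-in-pocket interaction (donor 100 nM, acceptor 200 nM, Kd 35 nM)
and `sam_config()` a weaker surface–surface dimerization (150/300 nM,
Kd 230 nM). Negative controls are the intact pair (0% inhibition);
positive controls contain chaotrope-disrupted pair (100% inhibition),
modelled simply as wells with no complex.

## Spectral unmixing (EmFRET)

Ratios cannot be translated into affinities directly, so titrations use
the sensitized-emission readout. Three channels are measured —
(430, 477), (430, 527), (477, 527) — and the FRET emission is isolated by
linear unmixing:

$$\mathrm{EmFRET} = I_{430,527} - \alpha\, I_{430,477} - \beta\, I_{477,527}$$

* $\alpha$ = donor bleed-through into the acceptor emission channel,
  measured as $I_{430,527}/I_{430,477}$ in donor-only wells;
* $\beta$ = acceptor direct excitation at the donor wavelength, measured
  as $I_{430,527}/I_{477,527}$ in acceptor-only wells.

Both are means over the calibration wells of a plate. The correction is
exact when the donor is not excited at 477 nm and the acceptor does not
emit at 477 nm — excellent approximations for CFP/YFP and exactly true in
the simulator, so round-trip tests can demand exact recovery. The method
assumes complete fluorophore maturation and accurately known protein
concentrations; no maturation-rate correction is attempted.

## Binding model and Kd fitting

Protein concentrations (50 nM–1.1 µM) are comparable to the dissociation
constants (8 nM–2.6 µM), so the dilute approximation $[DA] \approx
DA/K_d$ is invalid. The exact 1:1 ligand-depletion solution is used
throughout:

$$[DA] = \tfrac{1}{2}\left((D + A + K_d) - \sqrt{(D + A + K_d)^2 - 4DA}\right),$$

computed in the numerically stable form $2DA/(b + \sqrt{b^2 - 4DA})$ to
avoid cancellation when $DA \ll b^2$. The titration model is

$$\mathrm{EmFRET}(A) = \mathrm{EmFRET}_{max} \cdot [DA](D, A, K_d)/D,$$

normalized per donor so the plateau parameter is donor-independent. For
fixed $K_d$ the model is linear in $\mathrm{EmFRET}_{max}$, which has a
closed-form least-squares solution; the fit therefore reduces to a
one-dimensional search over $\log_{10} K_d$ (`optimize()`, tolerance
1e-9), which cannot fail to converge away from degenerate data.
Replicates (n = 4 by default) are fitted jointly as pooled points rather
than averaged, preserving the error structure for the interval.

**Profile-likelihood CI.** Under a Gaussian iid error model with profiled
variance, the log-likelihood is $-\tfrac{n}{2}\log \mathrm{RSS}(K_d)$ with
the plateau re-optimized at each $K_d$. The 95% bounds sit where it drops
$\chi^2_1(0.95)/2 = 1.92$ below the optimum, located on a 201-point
log-spaced grid spanning 0.01–100× the estimate and refined by bisection
to 1e-3 relative tolerance. A bound not bracketed inside the grid is
reported at the grid edge and flagged *open* — the expected outcome for
weak binders whose titration never approaches saturation, where only the
initial slope $\mathrm{EmFRET}_{max}/K_d$ is identified. Monte-Carlo
checks (500 titrations at 2% multiplicative noise, 4 replicates) put the
interval's coverage at 96–97%: slightly conservative, because the noise
is mildly heteroscedastic while the likelihood assumes iid errors.

Degenerate inputs are handled explicitly: an all-zero series is an error;
a monotone-decreasing series fits but warns and flags the interval
unreliable; fewer than six distinct acceptor concentrations is an error.

## Quality control

Z′ = 1 − 3(σ₊ + σ₋)/|μ₋ − μ₊| on per-well rFRET of the plate's own
controls, with sample (n−1) standard deviations — the convention matters
little at n = 680 but is fixed for reproducibility. Percent inhibition is
the affine map anchoring the negative control at 0% and the positive at
100%; values outside [0, 100] are reported as-is. Controls are per-plate,
matching plate-wise normalization practice. Z′ is computed on rFRET, not
raw intensities, since every reported signal in this assay family is
ratiometric.

## The interference cascade

Screening at 100 µM compound makes intrinsic fluorescence and aggregation
common; the triage runs in screening order and attributes each exclusion
to the *first* stage that triggers, so stage counts partition the
exclusions:

1. **Fluorescence** (two criteria reported as one stage): compound
   pre-reads (before protein transfer, 410 nm excitation) above 5×
   background in either emission channel, strict inequality; or assay
   wells deviating more than ±30% from the negative-control fluorescence
   in either channel. Sub-flags are retained in the detailed report.
2. **Dual-excitation discrepancy**: apparent inhibition computed
   independently at 410 nm and 430 nm excitation; interfering
   fluorophores are rarely excited equally at both, while genuine
   inhibition is excitation-independent. Strict >10 percentage points.
3. **Pan-assay**: inhibition ≥20% simultaneously in both orthogonal
   assays (each at 410 nm), evaluated on compounds surviving stages 1–2
   in the assay being reported. The two interactions are structurally
   unrelated, so simultaneous "inhibition" indicates aggregation,
   quenching or other non-specific mechanisms. Because survivor sets
   differ between assays, pan counts may differ too. No numeric threshold
   is standard for "signal reduction"; 20% — equal to the hit threshold —
   is the package default and configurable.

Hits are survivors with inhibition ≥20% (inclusive) at 410 nm, a
deliberately low limit that retains weak binders. Report formatting
follows the reporting convention of screening campaigns: exclusion percentages to one decimal,
hit rates to two, round-half-even.

## Dose–response and Ki

IC50s come from the standard variable-slope four-parameter logistic,
fitted by Levenberg–Marquardt on $\log_{10}$ IC50 with asymptotes free;
orientation (raw descending rFRET vs ascending percent inhibition) is
auto-detected and the asymptotes relabelled so `top > bottom` always
holds. Anchor controls placed two log-units outside the titrated range
(no-compound and fully-disrupted) enter as ordinary points. Fits are
flagged unreliable when flat, non-converged, or when the IC50 lands more
than 100× outside the tested range.

At the IC50-assay probe concentrations (donor 50 nM, acceptor 100 nM,
Kd 35 nM) the acceptor is far from dilute, so the Cheng–Prusoff
correction $K_i = IC_{50}/(1 + A_{tot}/K_d)$ is biased by ligand
depletion. The primary conversion therefore inverts the exact ternary
equilibrium: free donor $d$ solves the monotone mass balance

$$d\left(1 + \frac{A}{K_d + d} + \frac{I}{K_i + d}\right) = D,$$

by bracketed root finding plus Newton polish (mass balance verified to
1e-10 relative on every call), and $K_i$ is the value at which the
predicted probe complex halves at $I = IC_{50}$. Both conventions are
reported so results can be compared with either. Round-trip tests
(forward simulation at known Ki → IC50 fit → inversion) close within
0.3% noise-free and a few percent at assay noise. The dose–response
generator works at the normalized-signal level — percent displacement of
the complex, as an EmFRET-style readout linear in complex concentration —
rather than through the spectral plate layer.

## Thermal shift

DSF curves with an environment-sensitive dye rise through unfolding and
then decline as aggregates form; the decline violates the Boltzmann form,
so curves are truncated at the global fluorescence maximum and min–max
normalized (the fit is invariant to this affine rescaling; it only
stabilizes optimization). The Boltzmann sigmoid

$$y = b_{low} + \frac{b_{high} - b_{low}}{1 + e^{(T_m - T)/k}}$$

is fitted per replicate; groups are compared as mean Tm difference with
SD propagated as $\sqrt{s_s^2 + s_c^2}$ (NA for single replicates).
Derivative-based Tm definitions and two-transition models are out of
scope.

## The synthetic-data generator

Every analysis step can be exercised against seeded ground truth. The
signal model per channel is a linear superposition: buffer background,
non-transferring donor emission $(D - E \cdot DA)$, direct acceptor
excitation, sensitized emission $E \cdot DA$, compound fluorescence, and
a multiplicative quench factor on 527 nm emission — no inner-filter depth
effects or photobleaching. Generators are pure functions of
(configuration, seed) and restore the caller's RNG state.

**Fluorophore defaults** are hand-set, not fitted (no spectra tables are
available to fit): donor bleed-through ratio α = 0.25, acceptor
direct-excitation ratio β = 0.08, transfer efficiency E = 0.25. The
modest E keeps the per-channel intensity excursion of even a *complete*
inhibitor inside the ±30% interference band (full inhibition moves the
donor channel by +24% here), so the deviation filter never destroys
genuine hits — a property real optimized assays share, and a prerequisite
for the cascade's 100% sensitivity on simulated inhibitors. The resulting
bound-pair rFRET is ~2× the disrupted control, mirroring the observed
qualitative contrast.

**Noise** has four components with defaults calibrated once by error
propagation against the reported assay behaviour: a per-well volume
factor (CV 2%) shared by all channels (cancels in rFRET), independent
donor/acceptor concentration jitter (CV 1% each — the dominant source of
rFRET scatter, as dispensing error is in real plates), a per-read
detector factor (CV 0.2%) and additive read noise (SD 1 RFU against a
150 RFU background). These defaults give Z′ ≈ 0.93 and 0.90 for the two
assay configurations in the 680+680-control verification design,
preserving the observed ordering (the high-affinity pair scores higher),
and keep Z′ ≥ 0.72 across the five-level concentration scan from 50/100
to 250/500 nM — including the weak pair at its lowest concentration,
where purely optical noise models fail. EmFRET-level Monte-Carlo studies
use the dedicated `simulate_titration_emfret()` generator with plain 2%
multiplicative noise.

**The screening library** (1,120 compounds by default) seeds seven
classes whose parameters are chosen so each interferer lands in exactly
one triage stage under zero noise: strong blue fluorophores (>5×
background pre-read) and moderate blue plus green fluorophores (pass the
pre-read, fail the ±30% deviation) populate stage 1 with 14 compounds;
six excitation-shifted fluorophores (20× stronger absorption at 430 nm
than 410 nm, hence invisible to stage 1, which runs at 410 nm) populate
stage 2; six dual-assay acceptor-emission quenchers (20% quench — inside
the ±30% band, identical apparent inhibition at both excitations, but
~40–60% "inhibition" in both assays) populate stage 3. True inhibitors
(Ki 20 µM, ~50% inhibition at 100 µM) and inactives survive. Ten
inhibitors target assay A and five assay B, so the default screen yields
10 and 5 hits. The truth table emitted with every simulated screen is the
backbone of the end-to-end tests.

**What the generator does not emulate.** Compound interference prevalence
in a real diverse library is emergent chemistry, not a configurable
count; spatial plate artifacts (edge effects, dispense gradients),
DMSO effects, compound aggregation kinetics and inner-filter absorption
are not modelled. Passing the seeded-library tests therefore demonstrates
that the cascade's logic and thresholds behave as designed, not that the
thresholds are optimal for any particular chemical library.

## Problem sizes and determinism

Test-suite and acceptance computations use the study's own designs where
feasible: the 23-point acceptor ladder with 4 replicates, the
1,120-compound two-assay screen in 1536-well format, 680+680 control
replicates for Z′, 48 replicates per concentration-scan level, 4 DSF
replicates, 500 Monte-Carlo repetitions for CI coverage and 1,000 random
parameter triples for oracle agreement. All stochastic steps flow from a
single integer seed.
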