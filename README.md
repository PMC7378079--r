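# fretscreen

Analysis toolkit for **ratiometric FRET high-throughput screening** of
protein–protein interactions, modelled on CFP/YFP assay systems for
tankyrase: the ARC domain binding a tankyrase-binding-motif (TBM) peptide,
and SAM–SAM dimerization. It is written for assay developers and screeners
who need to go from raw plate-reader intensity tables to dissociation
constants, quality-controlled screens, triaged hit lists, Ki values and
thermal-shift confirmation — with a spectrally explicit plate simulator to
validate every step against known ground truth.

## What it computes

**Ratiometric FRET.** Each well is read at donor excitation (410 nm) in the
donor (477 nm) and acceptor (527 nm) emission channels; after blank
subtraction the signal is the ratio rFRET = I(527)/I(477), which rises when
the donor- and acceptor-fused proteins interact.

**Binding affinity.** Sensitized emission is isolated by three-channel
linear unmixing,

```
EmFRET = I(430,527) − α·I(430,477) − β·I(477,527)
```

with α (donor bleed-through) and β (acceptor direct excitation) calibrated
from single-fluorophore wells. Titrating acceptor A against fixed donor D
and fitting

```
EmFRET(A) = EmFRET_max · [DA](D, A, Kd) / D,
[DA] = ((D + A + Kd) − sqrt((D + A + Kd)² − 4·D·A)) / 2
```

gives Kd under the exact 1:1 ligand-depletion (tight-binding) model, with a
profile-likelihood 95% confidence interval.

**Assay QC.** Control wells (intact pair vs chaotrope-disrupted pair) give
the screening window statistic Z′ = 1 − 3(σ₊ + σ₋)/|μ₋ − μ₊| and the
percent-inhibition normalization used for screening.

**Interference triage and hit calling.** A three-stage cascade excludes
compounds that (1) autofluoresce more than 5× background or shift the
FRET-pair fluorescence by more than ±30% vs controls, (2) show >10
percentage points discrepancy in apparent inhibition between 410 nm and
430 nm excitation, or (3) reduce the signal of two orthogonal assays
simultaneously (pan-assay). Survivors with ≥20% inhibition are hits.

**Dose–response and Ki.** Variable-slope four-parameter logistic IC50 fits,
converted to Ki by exact inversion of the ternary competitive equilibrium
D+A⇌DA, D+I⇌DI (with the Cheng–Prusoff value reported alongside).

**Thermal shift.** Boltzmann sigmoid fits of DSF melting curves (truncated
at the fluorescence peak, min–max normalized) and ΔTm with propagated SD.

## Worked example

```r
library(fretscreen)

# simulate a Kd titration of the ARC4-TBM-like pair and re-analyze it
sim    <- simulate_titration(sim_config(kd_pair = 35e-9, seed = 1))
series <- emfret_titration(sim$plate)   # blank-correct, calibrate, unmix
fit    <- fit_kd(series)
fit
#> FRET binding fit (1:1 ligand-depletion model)
#>   Kd         = 3.42e-08  [2.877e-08, 4.014e-08] (95% profile likelihood)
#>   EmFRET_max = 298.6
#>   RSS = 1.09e+04 on 92 points

# quality control of a simulated 1536-well control plate
qc_plate(subtract_blanks(simulate_qc_plate(sim_config(seed = 7))))
#> # A tibble: 1 × 8
#>   zprime pass  mean_neg  sd_neg n_neg mean_pos  sd_pos n_pos
#>    <dbl> <lgl>    <dbl>   <dbl> <int>    <dbl>   <dbl> <int>
#> 1  0.931 TRUE     0.835 0.00580   680    0.429 0.00358   680

# the two-assay interference screen on a seeded 1,120-compound library
sim <- simulate_screen(seed = 42)
scr <- run_screen(sim$assay_a, sim$assay_b)
scr$summary[, c("assay", "n_excluded_fluor", "n_excluded_dual",
                "n_excluded_pan", "n_hits", "pct_excluded_total", "pct_hits")]
#> # A tibble: 2 × 7
#>   assay n_excluded_fluor n_excluded_dual n_excluded_pan n_hits pct_excluded_total pct_hits
#>   <chr>            <int>           <int>          <int>  <int> <chr>              <chr>
#> 1 A                   14               6              6     10 2.3%               0.89%
#> 2 B                   14               6              6      5 2.3%               0.45%
```

The fitted Kd reproduces the generating 35 nM within its confidence
interval; the Z′ of 0.93 marks an excellent assay window; and the screen
recovers exactly the seeded library composition — 14 fluorescent
interferers at stage 1, 6 excitation-shifted compounds at stage 2, 6
dual-assay quenchers at stage 3, and all true inhibitors as hits.

Each fitted object supports `tidy()`, `glance()` and `autoplot()`;
`plot_screen()` draws the per-compound inhibition scatter.

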