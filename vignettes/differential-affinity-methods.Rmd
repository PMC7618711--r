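---
title: "Differential-affinity translation shutdown: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-affinity translation shutdown: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntpshift)
```

When budding yeast growing rapidly by glycolysis loses its carbon source,
intracellular ATP collapses from about 2 mM to below 0.3 mM within half a
minute, and translation initiation stops on the same timescale — far too
fast for transcription-based stress programs. `ntpshift` implements the
quantitative machinery around a *differential affinity* explanation: the
DEAD-box ATPases required for initiation (eIF4A, Ded1) have half-saturation
constants in the 300–540 µM range and lose their nucleotide (and hence
their mRNA grip) as ATP falls, while the elongation GTPases bind GTP with
sub-micromolar constants and keep working, so initiated ribosomes run off
and polysomes collapse in an orderly way. This vignette documents the
models, the tunable parameters, the synthetic-data generators, and the
numerical and design choices, in that order.

## Unit conversions

HPLC quantification reports nucleotide recoveries in pmol per 10^8 cells.
Concentrations follow by dividing by the soluble volume of a haploid cell,
estimated from wet mass minus dry mass (60 and 15 pg) at a density of
1 g/mL, i.e. 4.5 × 10⁻¹⁴ L per cell:

```{r}
soluble_volume(cell_model())
pmol_to_mM(9000)   # ~2 mM ATP during growth on glucose
```

One deliberate reading: the source protocol's phrase about a "1 g/L"
conversion is treated as a slip for 1 g/mL, because only the latter
reproduces the stated 4.5 × 10⁻¹⁴ L volume. Note also that the
independently stated 1.7 × 10⁻¹⁶ mol ATP per cell divided by this volume
gives ≈ 3.8 mM rather than 2 mM; the basis of the mol-per-cell figure is
not recoverable, so the package exposes both computations
(`molecules_per_cell()`, `pmol_to_mM()`) and does not force consistency
between them.

Headline numbers are reported at one significant figure (`report_signif()`,
and `sig_figs` arguments), matching the convention in which 2.67 × 10⁶
molecules/s is quoted as 3 × 10⁶; raw precision is always retained.
Depletion fractions round to the nearest 5 percentage points (26.7% → 25%)
and fold changes to whole folds (6.7 → 7); neither rounding rule is claimed
to be the original authors' — they are this package's declared conventions
that reproduce the printed values. Concentrations reported as zero are
carried as censored-at-zero flags so fold changes refuse to divide by them.

## Occupancy model

Factor saturation uses the hyperbolic form $[NT]/(K + [NT])$, and, for
eIF4A where an ADP constant (27 µM) is known, classical competitive
inhibition:

$$\theta = \frac{[ATP]/K_{ATP}}{1 + [ATP]/K_{ATP} + [ADP]/K_{ADP}}.$$

Binding constants are treated as generic half-saturation constants; the
literature mixes $K_m$ and $K_d$ language for these factors and nothing
downstream depends on the distinction. The shipped table holds exactly the
four published constants (eIF4A ATP 540 µM, Ded1 ATP 300 µM, eIF4A ADP
27 µM, eEF1A GTP 0.14 µM); users can extend it with `factor_kinetics()`.
The inhibition scheme is a choice: the source observation is only that ADP
dominance "blocks further mRNA binding", so competitive inhibition is
implemented as the default pluggable rule. Cooperative ATP+RNA binding is
represented solely through the occupancy → release mapping in
`classify_factors()`; no explicit RNA-binding equilibrium is modelled.

`classify_factors()` offers two rules. `km_threshold` marks a factor
released unless its nucleotide strictly exceeds its constant; the boundary
case (e.g. Ded1 at exactly 0.3 mM ATP) counts as released, consistent with
the biological reading that concentrations *at* the constant no longer
sustain full function. `occupancy_half` instead thresholds the competitive
occupancy at 0.5.

```{r}
classify_factors(default_factors(),
                 nucleotide_state(ATP = 0.3, ADP = 0.45, GTP = 0.089))
```

## Energy budget

`translation_budget()` encodes the arithmetic linking 10⁵ engaged
ribosomes × 2.6 aa/s × 3 NTP/aa to ~8 × 10⁵ NTP/s, about 25% of the
observed 3 × 10⁶ molecules/s ATP depletion. The minimum of three NTPs per
amino acid is the default; `ntp_overhead` adds unquantified
initiation/termination/synthesis costs.

## NTP pool dynamics and the set point

Post-shift ATP dynamics are modelled as residual production against a small
hierarchy of Michaelis–Menten sinks:

$$\frac{d[ATP]}{dt} = r - \sum_i v_i \frac{[ATP]}{k_i + [ATP]},$$

with $r$ a fixed residual fraction of the calibrated pre-shift production.
The stable concentration where the two sides balance is the *set point*;
`find_set_point()` solves it by bracketed root-finding and
`simulate_ntp()`'s long-time limit agrees with it to solver tolerance.
Hierarchical inhibition is realised two ways, both available because the
source account implies both without choosing: intrinsic $K_m$ differences
(sinks with low constants keep consuming at low ATP) and explicit
`shutoff_atp` thresholds (regulated deactivation when ATP first crosses a
level, detected by the integrator's root-finding and latched off to avoid
chattering at the crossing).

The default scenarios use three sinks: a Pma1-like plasma-membrane ATPase
carrying 30% of the pre-shift budget, a moderate-affinity bulk sink
($k = 0.5$ mM, translation and similar ATPases) and a high-affinity
maintenance sink ($k = 0.05$ mM). Calibration solves three constraints:
the wild-type set point sits at 0.3 mM; the same residual production with
the Pma1-like sink inactivated balances at 1.0 mM (the hxk2Δ scenario,
where that sink carries `shutoff_atp = 1` mM — encoding the hypothesis
that a major sink is inactivated at higher ATP in the mutant, with Pma1 as
the plausible candidate); and the overall rate scale brings ATP within 10%
of the set point by 30 s, the kinetic anchor of the measured time course.
The calibration is computed in `ntp_scenario()` from `scenario_config()`
values, not hard-coded. Two consequences worth knowing: the implied
residual production is ≈ 59% of pre-shift production, which is large — a
direct consequence of insisting that pure Michaelis–Menten sinks alone
(without wild-type shutoffs) produce a 0.3 mM set point from 2 mM; and the
resulting time course plateaus like the measurements but is not a fit to
full trajectories. The residual source itself is biologically unidentified
and `residual_fraction` is exposed as a free parameter.

With `conservation = TRUE`, consumed ATP transfers to ADP, production
draws on ADP saturably, and an adenylate-kinase-like step
(2 ADP ⇌ ATP + AMP, mass action, $k = 0.5$ /mM/s, $K_{eq} = 1$) exchanges
within the adenylate pool, whose total is conserved to solver tolerance
(lsoda, atol 10⁻⁹ / rtol 10⁻⁶). GTP, CTP and UTP are slaved pools that
follow the relative ATP trajectory with species scale factors — the GTP
default 0.9489 maps 0.46 mM to 0.089 mM as ATP falls 2 → 0.3 mM —
because GTP depletion is attributed to the ATP requirement of GTP
recycling and no independent GTP production is modelled. The simulated ADP
rise overshoots the measured 0.45 mM somewhat; the adenylate bookkeeping
is structural, not calibrated.

## Ribosome run-off

`simulate_runoff()` is an exclusion process (TASEP with extended
particles): ribosomes occupy a 10-codon footprint (~30 nt, a standard
convention, configurable), initiation attempts arrive at the mRNA-specific
baseline rate multiplied by the competitive eIF4A occupancy and are
blocked while the first footprint is occupied, and each ribosome advances
at 2.6 codons/s times the eEF1A GTP occupancy. eIF4B and Ded1 are taken as
co-limiting with eIF4A rather than separately rate-setting. Termination is
instantaneous by default; run-off at low ATP may in reality proceed
through slower or non-canonical ribosome release, which is why an optional
slow-splitting mode (retaining post-termination 80S) exists but is off by
default.

Deterministic mode advances all ribosomes uniformly (exact for
piecewise-constant gates, so step size only controls gate refresh and
initiation granularity, with initiation fired from a rate accumulator);
stochastic mode draws exponential waiting times per copy with a single
seeded generator, copies being independent. Nucleotide-state timelines are
treated as piecewise constant between rows. `polysome_histogram()` bins
copies by ribosome load into free/80S/n-some classes, `render_trace()`
draws Gaussian peaks weighted by ribosome mass per class (free mRNA
carries no peak), and `align_profiles()` zeroes starting absorbances and
shifts traces so monosome peaks coincide — the monosome peak being the
first local maximum above 5% of the trace maximum.

## CRAC / RNA-seq binding pipeline

The quantification chain follows the written rules exactly, in this order:
RPM normalisation to total mapped reads; detection per condition iff RPM ≥
0.5 in ≥ 2 replicates (the threshold is inclusive, reading "RPM < 0.5
applied" as the removal rule; an `require_all_replicates` option covers
the stricter phrasing used alongside it); median of replicate RPMs;
pseudocount imputation at 0.5 RPM for features detected in the glucose
reference but lost under stress, with reference-undetected features
dropped; biotype filter on "protein_coding; exon"; and an inclusive
RNA-seq RPKM ≥ 10 expression filter. Expression normalisation divides
binding RPM by the RPKM of the time-matched RNA-seq, with the 30-s
condition mapped to the glucose RNA-seq because mRNA populations cannot
re-equilibrate in seconds. The chain is idempotent and its survivors equal
brute-force reapplication of the written rules (tested).

Differential-expression *computation* is out of scope — DE tables are
inputs — but for fully self-contained synthetic runs `nb_exact_test()`
provides a clearly-labelled stand-in: a conditional exact negative-binomial
test at the generator's known dispersion, cross-checked in the tests
against an established exact-test implementation. `cpm_filter()` applies
the CPM > 15 per-sample / > 20 overall thresholds with the
smallest-group-size convention for "enough samples", documented here
because the original delegates that rule to a package default.

`estimate_binding_loss()` recovers the global binding-loss factor from an
imputed binding table. Its default is the expression-weighted mean fold
change (ratio of summed median RPMs over non-imputed features): the
unweighted per-feature mean is biased upward — features are excluded
exactly when their stress draws fall below detection, and the per-feature
ratio inherits Jensen bias from the noisy denominator — by around +10%
relative at default generator conditions, which matters because the
feature bootstrap CI is much tighter than that. The per-feature variant
remains available as `method = "per_feature"`.

## Nascent-proteome stage

Proteins are kept only if quantified in *all* labelled eluate samples of
at least one condition; normalisation is per-sample median centring to the
first sample's median — a declared stand-in for variance-stabilising
normalisation (the affine-noise model is not re-derived, and results are
not claimed identical to a VSN fit). Missing values are treated as
left-censored (missing-not-at-random): `minprob_impute()` draws each
missing cell from a Gaussian at the sample's 1% observed quantile with sd
equal to the median per-protein sd (q = 0.01, scale = 1 — the cited
method's common defaults, since none are stated). `differential()` is a
Welch-t + Benjamini–Hochberg stand-in for the original moderated /
local-FDR statistics (whose shrinkage is package-version dependent), with
the |FC| > 1.5, FDR ≤ 0.05 gates; both FDR flavours used in the original
are collapsed onto BH here, deliberately. Degenerate-variance proteins are
marked untestable, never silently passed. `zscore_kmeans()` row-z-scores
class medians and runs k-means (k = 4) with 50 k-means++-seeded restarts,
because k = 4 on z-scored rows is sensitive to initialisation; flat rows
z-score to zero vectors rather than NaN.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (config, seed) and write provenance
headers that round-trip through the TSV readers. Their defaults encode the
study conditions: triplicates; library size 2 × 10⁶ so that the 0.5 RPM
threshold is ~1 count; NB dispersion 0.05 (typical bulk RNA-seq);
expression lognormal with sdlog 1.5, spanning the three-to-four decades of
mRNA abundance and placing roughly an eighth of transcripts below CRAC
detection at the 30-s loss factor; global binding loss λ = 0.05 at 30 s
persisting to 16 min; a re-binding boost of 1.5 on the induced set at 16
min, a purely phenomenological encoding of newly synthesised mRNAs
escaping sequestration (the mechanism is unknown in the source system);
transcriptional |log2FC| = 2 on 100 induced and 100 repressed transcripts;
and, for the proteome, four planted archetypes at ≥ 4 noise-sd separation
with logistic left-censoring below 21.5 (log2 scale). CRAC libraries keep
a fixed total-mapped-reads denominator while mRNA-derived reads shrink
with λ, so global loss is visible in RPM — mimicking the role of
non-mRNA background in real libraries.

Passing tests on these generators show that the pipeline recovers known
structure under the stated statistical model; they say nothing about
protocol-level artifacts (crosslinking bias, PCR duplicates, peptide
inference, batch effects), and the deposited-data headline counts
(4,377 / 902 / 4,165 / 524) are not desk-reproducible and are not targets.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 5,000-gene CRAC
experiments over 10 seeds; a 10⁴-copy run-off pool (deterministic, 5 s
gate refresh over 10 simulated minutes); 10⁴ stochastic replicates of a
20-codon, footprint-7 construct against an exhaustively enumerated
continuous-time Markov chain; 100 null proteome simulations of 1,000
proteins; and 20 proteome-cluster seeds at 400 proteins. These sizes give
stable Monte-Carlo margins (3σ binomial bands at 10⁴, 5% mean-field
tolerance) while keeping a full run in minutes. All randomness flows
through explicit seeds; seeded helpers save and restore the caller's RNG
state.

## Known limitations

- The dynamics module is a minimal sink hierarchy, not a metabolic model:
  no glycolysis/TCA mechanism, no AMPK/Snf1 signalling, no pH effects.
- The run-off simulator has uniform elongation (no codon-specific rates,
  tRNA competition, collisions or condensate sequestration).
- Median centring and Welch/BH are stand-ins; results will differ in
  detail from VSN- and moderated-statistics pipelines.
- The adenylate bookkeeping reproduces the qualitative ADP/AMP behaviour
  only; its rate constants are structural defaults.
- Western quantification assumes strictly positive Pab1 control bands.
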