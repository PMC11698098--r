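---
title: "Methods: quantifying purine/pyrimidine cross-feeding and its niche partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying purine/pyrimidine cross-feeding and its niche partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## Scope and scientific setting

*Prochlorococcus*, the most abundant photosynthetic organism in the
oligotrophic ocean, exudes pyrimidines (chiefly thymidine) and purines
(adenine, guanine) as by-products of deoxyribonucleotide recycling after
nightly genome replication. Co-occurring heterotrophs — SAR11, SAR86, and
SAR116 — differ systematically in whether and how they consume these
compounds: as intact building blocks, or as catabolic sources of energy
(NADH), carbon (glyoxylate), or nitrogen (ammonia/urea). `crossfeedr`
implements the quantitative machinery for this analysis:

1. **Exometabolite budgets**: how much of each compound leaves the cell,
   relative to what is incorporated into DNA.
2. **Genome trait analysis**: which usage genes occur in which genomes,
   corrected for the incompleteness of MAGs and SAGs.
3. **Metagenomic gene frequencies**: what fraction of cells in the field
   carry each gene, and how that co-varies with nutrients.
4. **Diel expression phasing**: when putative donor and recipient genes are
   expressed over the day–night cycle.
5. **Culture assays**: how adenine amendments affect SAR11 growth, DNA
   content, and recovery from washing stress.

All field and laboratory inputs are emulated by seeded generators
(`gen_*()`) that record their planted ground truth, so every estimator in
the package is validated by parameter recovery rather than by fixtures.

## Metabolite budgets

**Extraction correction.** Solid-phase extraction recovers only a fraction
EF% of a dissolved compound, so the concentration in the spent medium is
back-calculated as `conc_media = 100 * conc_extract / EF%`. Efficiencies at
or below 1% are too uncertain to invert: those compounds are left
uncorrected and flagged (`corrected = FALSE`). For display, the
`hypothetical_100x` mode scales uncorrectable compounds by exactly 100 (the
factor that an EF% of exactly 1 would imply), which is how the *scale* of
adenine and guanine exudation can be judged even when their true EF% is
unknown below the floor. The boundary is strict: EF% = 1 is not corrected.

**DNA base incorporation.** Exudation is meaningful relative to
biosynthetic demand, so extracellular pools are normalized to the moles of
the matching base incorporated into DNA over the experiment. For a genome
of `L` bp with GC fraction `g`, the default *duplex* convention counts
`L * (1 - g) / 2` thymidines per chromosome copy (A=T pairing forces the
symmetric split between the complementary identities, so the four bases sum
to `L`), multiplied by net cells produced (final minus initial count — the
production integral, not the standing stock) and divided by Avogadro's
number. A `per-strand` switch omits the division by two for workflows that
count both strands of every pair. One chromosome per cell is the default,
the standard assumption for *Prochlorococcus*.

**Intracellular molarities.** Extract concentrations (ng/mL) are converted
to fg per cell via the extract volume and cells captured, then to molarity
via the molar mass and the cell volume (µm³ → L). Cell volumes missing from
the literature are estimated by dry-mass scaling,
`scale_cell_volume(ref_volume, ref_mass, target_mass)`; with the published
MED4 reference (0.2 µm³, 66 fg) this yields 0.18 µm³ at 60 fg and 0.28 µm³
at 91 fg.

**Replicate handling.** Replicates are summarized as mean ± SD (SD, not
SEM, matching how biological replicate scatter is conventionally shown).
The tri-state detection flag (`quantified` / `detected` in a single
replicate / `nd`) propagates as missing values, never as zeros: a
non-detection is not evidence of a zero concentration at these detection
limits.

## Genome trait analysis

**Quality filter.** Genomes with `completeness - 5 * contamination < 30`
(both in percent) are excluded; the score exactly at the threshold is
retained, since the exclusion rule is a strict inequality. The filter is
idempotent and order-preserving.

**Completeness-aware universality.** In a collection of incomplete
genomes, a truly universal gene is observed at a frequency near the mean
completeness, not near 100%. `classify_universality()` therefore calls a
trait near-universal when its observed frequency reaches within a tolerance
band (default 10 percentage points) of the mean completeness. The band is a
free parameter: 10 points cleanly separates the regimes that matter in
practice (observed ~72% at mean completeness ~72% → near-universal;
observed ~3% → subgroup; observed ~49% against ~75% completeness →
subgroup) while being insensitive to a few points of completeness error.
`corrected_frequency()` provides the point estimate `observed / mean
completeness`, which is unbiased under the dropout model below.

**Category aggregation.** Per-category frequencies default to the mean of
member-gene frequencies, because curated per-gene counts in real
collections differ by a few percent even within one operon (partial genes,
assembly edges). An `intersection` mode (fraction of genomes carrying
*every* member gene) is provided for operon-completeness questions; both
modes are reported since published per-category figures do not state which
convention they use.

**Phylometabolic matrices.** Presence/absence rows are ordered by the leaf
order of a supplied phylogeny (`ape` reads the newick), with genes grouped
in catalog-category order. Reconciliation is explicit: tips lacking a
genome record and genomes missing from the tree are listed in an attached
report, never silently dropped. Clade labels are matched exactly after
whitespace trimming — no fuzzy matching, since silent label coercion is a
classic source of phantom clades.

## Metagenomic gene frequencies

The estimator converts per-sample HMM hit counts into a gene-per-genome
frequency:

```
frequency(gene) = (count[gene] / aa_length[gene]) /
                  median_over_14_cores(count[core] / aa_length[core])
```

The 14 single-copy ribosomal proteins occur once per genome in essentially
all members of the taxon, so their length-normalized count density proxies
genome (cell) abundance. The median over an even count of 14 is the
midpoint of the 7th and 8th order statistics. Two numerical decisions are
worth noting:

* Core counts are length-normalized **before** the median, since the cores
  span ~85–280 aa and a raw-count median would carry that length bias into
  every frequency. A `raw_core_median` switch restores the raw convention
  for comparability.
* Frequencies are reported unclipped. Values slightly above 1 are real
  signals (multi-copy genes, cross-mapping) and clipping belongs in the
  presentation layer, not the estimator.

The estimator is exactly invariant under a common rescaling of all counts
(sequencing depth cancels) and linear in the focal gene's count. Surface
biogeography aggregates the arithmetic mean of per-sample frequencies over
samples in the upper 100 m per station; stations with no qualifying sample
are omitted with a notice. Associations with nutrients use Spearman rank
correlation (average ranks for ties), dropping missing environmental values
pairwise; fewer than three complete pairs or a zero-variance vector yields
`NaN` with a warning rather than a fabricated coefficient.

**Gene grouping.** Genes are grouped by single-linkage over the gene–gene
Pearson correlation matrix of their frequencies: connected components of
the graph linking pairs with r at or above a threshold. The threshold
(default 0.7) is a configuration knob — correlation grouping is one
criterion among several in practice, so the `overrides` argument lets a
curated decision force a gene into another gene's group (e.g. a deaminase
whose frequency correlates with its functional partners even though its
nutrient correlation does not). Components are deterministic: genes sort
lexicographically within groups, groups are numbered by first member, and
constant columns become flagged singletons.

## Diel expression phasing

Counts are first normalized to the taxon's total transcripts per timepoint
(removing shared variation in abundance and depth), then z-scored per gene
(sample SD, n−1 denominator by default, with an `n` switch) for
cross-gene comparison. `peak_time()` is the grid argmax with ties resolved
to the earliest timepoint, and is quantized to the sampling interval by
construction.

`phase_lag()` therefore defaults to a **cosinor** estimate: a least-squares
fit of cosine/sine regressors at the diel frequency, with the acrophase
read off the fundamental. Two refinements matter numerically:

* The fit runs on the log scale when the series is strictly positive
  (falling back to the identity scale otherwise). Transcript noise is
  multiplicative, so the log transform stabilizes the variance — in
  simulation at SNR 3 it reduces the lag SD from ≈0.45 h to ≈0.33 h — and
  leaves the acrophase of a peak-symmetric waveform unchanged.
* Three harmonics are fitted by default (`harmonics = 3`). The phase comes
  from the fundamental alone; the extra harmonics absorb non-sinusoidal
  waveform shape which, on a finite grid whose endpoints duplicate a phase,
  would otherwise leak a few hundredths of an hour of bias into the
  fundamental.

Lags are wrapped into `(-12, +12]` hours for the 24-h cycle (so a raw 23-h
difference reports as −1 h), making `phase_lag(a, b) = -phase_lag(b, a)`
except exactly at the 12-h boundary. A `method = "peak"` option retains the
argmax convention. Genes whose summed counts fall below a floor
(`min_total_counts`, default 50) are reported as "insufficient depth"
rather than phase-analyzed: sparse transcript series produce phases that
are noise, and real low-abundance catabolism transcripts are exactly this
case.

## Culture assays

Growth rates are the least-squares slope of `ln(density)` versus time
inside an explicitly supplied phase window — the window is an experimental
input read off the curve, not inferred. A washed culture is classified as
lagged when its density fails to rise at least 50% (`resume_factor = 0.5`)
above the post-wash baseline within 2 days (`lag_days = 2`): a doubling
threshold would misclassify slow resumers, while a few-percent threshold
would fire on counting noise; 50% sits comfortably between typical
counting noise (~5–15%) and the ≥100% rise of one doubling.

Lag incidences between conditions are compared by a two-tailed Fisher exact
test, enumerated directly: with margins fixed, the hypergeometric
probabilities of all admissible tables no more probable than the observed
one (with 1e-7 relative slack against floating-point ties) are summed. At
the six-replicate scale of these experiments the full support is at most 13
tables, so exact enumeration is both feasible and the only defensible
choice. Growth-rate contrasts use the pooled-variance Student t test by
default (Welch as an option), two-tailed.

## The synthetic generators

Each generator emulates the statistical structure the estimators assume,
with all randomness derived from one integer seed (identical seed and
parameters give identical output):

* `gen_genomes()`: completeness ~ Uniform(50, 95) percent (mean ≈72%,
  the genus-level average the trait heuristics are calibrated against) over
  186 genomes by default; a truly present gene is observed with probability
  completeness/100, independently across genes; contamination is a small
  exponential. Default true frequencies emulate a SAR11-like profile:
  assimilation genes universal (1.0), the catabolism operon ~0.25,
  allantoin transport 0.17, urease 0.07, pyrimidine genes 0.04. Dropout is
  independent across genes by default; operon-linked dropout would violate
  that and is deliberately not the default, since the estimators assume
  per-gene recovery.
* `gen_metagenome()`: gene counts ~ Poisson(depth × frequency × length) and
  core counts ~ Poisson(depth × length), the model under which the
  length/core-median estimator is unbiased; a negative-binomial
  overdispersion knob exists for robustness checks. The default transect
  spans 30 stations across a 0.05–8 µmol/kg surface nitrogen gradient with
  nitrogen-harvesting gene frequencies declining (~0.50 → ~0.15) and
  energy/carbon-harvesting frequencies rising (~0.12 → ~0.55) along it,
  plus a 15% lognormal biological jitter per sample.
* `gen_diel()`: raised-cosine expression (relative amplitude 0.8) sampled
  every 2 h over 72 h with lognormal noise at SNR 3, DNA polymerase genes
  peaking at 19 h and the SAR11 transporter at 22 h — a planted 3-h lag.
  Taxon totals are flat by default (a whole transcriptome averages out the
  rhythms of its parts); a `total_amplitude` parameter plants a residual
  community rhythm when needed.
* `gen_growth()` / `gen_wash_experiment()`: logistic growth at µ = 0.4/day
  with 5% multiplicative counting noise; adenine scales µ (and the
  simulated per-cell DNA signal) by a Hill-type factor
  `1/(1 + dose/K)`, with K = 5 µM in balanced and 0.2 µM in
  glycine-depleted medium so inhibition sets in at lower doses when glycine
  is scarce. Washed cultures lag with probability 0.7 (control) versus 0.15
  (adenine-treated), flat for 3 days before resuming.
* `gen_metabolites()`: works backwards from planted
  exudation-to-incorporation ratios (thymidine 0.45 — extracellular
  production near half of DNA incorporation; adenine 0.40 and guanine 0.30
  with EF% below the 1% floor; methylthioadenosine 0.05) through the strain
  context to extract concentrations, with 10% lognormal measurement noise.

**What the generators do not emulate** — and hence what passing recovery
tests do not establish about real data: operon-linked gene dropout and
assembly chimerism; read cross-mapping between paralogs (frequencies > 1
from mis-mapping); non-Poisson overdispersion from community structure
(available only via the knob); irregular field sampling and missing diel
timepoints; death phases, co-limitation, and flask effects in growth; and
matrix effects on extraction efficiencies. Estimator behavior under those
violations must be judged separately.

## Problem sizes and test design

The validation suite runs recovery at the scales the analyses are designed
for: 186-genome collections over 200 replicate sets for
completeness-corrected frequency coverage (exact binomial intervals,
≥90% coverage required); 500 Poisson samples at core depth 1000 for
estimator unbiasedness within Monte-Carlo error; 200 transects with a
199-permutation null for correlation sign recovery; 200 diel series at
SNR 3 for lag recovery within ±1 h; exhaustive Fisher enumeration for all
2×2 tables with margins ≤ 12 plus 2,000 null experiments for type-I
control (≤6% at α = 0.05); and 1,000 random vectors for the normalization
invariants at 1e-10.

## Known limitations

* The budget path normalizes purines to DNA incorporation only; adenine
  flowing into RNA is not in any denominator, so ratios for purines are
  upper bounds relative to a total-nucleic-acid accounting.
* EF% values are taken as given per compound; no attempt is made to
  estimate them or their uncertainty, and the 1% floor is a hard rule.
* The universality tolerance and the correlation-grouping threshold are
  heuristics with exposed defaults, not estimated quantities.
* The cosinor assumes a single dominant 24-h component; strongly bimodal
  expression would need harmonic-specific phase reporting.
* `growth_rate()` requires the caller to supply the exponential window;
  automated changepoint detection is out of scope.
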