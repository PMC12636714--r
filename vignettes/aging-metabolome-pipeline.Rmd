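---
title: "Organ-resolved aging metabolome analysis with thermoshift"
author: "thermoshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-resolved aging metabolome analysis with thermoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshift)
```

# The problem

Comparing the metabolomes of old and young animals organ by organ asks a
simple question of thousands of features at once: which metabolites change
with age, in which direction, and in which tissue? `thermoshift` implements
the full desk-side workflow for such a study, from validated post-annotation
intensity tables through cleaning, nonparametric differential statistics,
and a set of biology-facing summaries centred on mitochondrial lipid
remodeling: cardiolipin maturity pools and the nascent-CL/PG synthase proxy,
acyl-chain remodeling of neutral lipids, free fatty acids and
acylcarnitines, named metabolite panels and product/precursor stress
ratios, and residue-level regulation profiles of small peptides.

The data model is a `MetaboStudy`, a `SummarizedExperiment` with metabolite
features as rows, samples as columns, a single nonnegative `intensity`
assay with `NA` for undetected cells, sample metadata (tissue, age group,
sex, QC flag) in `colData` and the annotation catalog (display name, RefMet
superclass, acquisition platform, QC relative standard deviation) in
`rowData`.

# The cleaning chain

Four stages run in a fixed order (`preprocessStudy()`):

1. **Cross-platform duplicate merge.** Features sharing a canonical display
   name across acquisition platforms are collapsed to the one with the
   lowest relative standard deviation in QC pool samples; ties break by
   platform order then feature id.
2. **Presence filter.** A feature is kept when it is observed in at least
   `ceiling(fraction * n)` biological samples of at least one tissue, with
   `fraction = 28/32` by default. QC samples are dropped here; they inform
   only the duplicate merge.
3. **Imputation.** Missing cells become the feature's minimum observed
   intensity across the whole study divided by 10; features observed
   nowhere are set to the constant 100. The study-wide minimum follows the
   view that a detection limit is a property of the analyte on the
   instrument rather than of a tissue; a per-tissue variant is a
   configuration switch away.
4. **Median normalization.** Each sample is rescaled so its median
   intensity equals the grand median of the per-sample medians — a
   multiplicative, rank-preserving correction aimed at per-sample loading
   and drift, which assumes the biology leaves the per-sample median
   essentially untouched.

Log transformation and Pareto scaling (`logParetoScale()`: per-feature
log2, centre, divide by the square root of the sample standard deviation)
are applied only on the way into the two-way ANOVA. Rank tests and fold
changes use the normalized intensities directly: a monotone per-sample
scaling would not change within-sample ranks, and scaling per feature
would distort ratios.

# Differential statistics

For each metabolite in a tissue, old vs young is summarised by:

* a **signed fold change**: with $r = \bar{x}_{old}/\bar{x}_{young}$, the
  statistic is $r$ when $r \ge 1$ and $-1/r$ otherwise, so the magnitude is
  never below 1 and the sign encodes direction; `log2fc` is $\log_2 r$.
  Means (not medians) are the default centre, switchable in configuration.
* a **two-sided Mann–Whitney U test**, exact by null enumeration when the
  pooled sample size is at most 20 without ties, otherwise the normal
  approximation with tie and continuity correction. Two identical constant
  groups return $p = 1$ by convention.
* a **Benjamini–Hochberg q-value** within the tissue.

The per-tissue *census* (`tissueCensus()`) counts metabolites with raw
$p < 0.05$ as a descriptive summary of direction (increased vs decreased),
deliberately on raw p-values — with a thousand features per tissue the raw
count is a stable descriptive statistic, while any single-metabolite claim
goes through q-values. Sex dependence is read from the age-by-sex
interaction term of a per-metabolite two-way fixed-effects ANOVA on
log/Pareto-scaled data (Type II sums of squares for unbalanced designs,
which coincide with the classical decomposition when balanced), with BH
control per term within tissue.

Kernel density summaries of signed fold changes (`fcDensity()`) use a
Gaussian kernel with Silverman's rule-of-thumb bandwidth, reported as `w`,
on a grid spanning the data plus three bandwidths each side.

# Cardiolipin remodeling

Cardiolipins (CL) are tetra-acyl phospholipids of the inner mitochondrial
membrane. They are synthesised from phosphatidylglycerol (PG) as *nascent*
species with shorter, more saturated acyl chains and remodeled into
*mature* species with longer, more unsaturated chains — tetralinoleoyl
cardiolipin, CL 72:8, being the canonical mature species; dilyso and
monolyso cardiolipins (DLCL/MLCL) are degradation/remodeling intermediates.

`classifyCardiolipin()` encodes this as a threshold rule: a CL is mature
iff its total acyl carbons reach 72 **and** its total double bonds reach 8;
DLCL/MLCL are intermediates; everything else in the family is nascent. The
thresholds are configuration, chosen so that CL 72:8 sits exactly at the
mature boundary; the classification is exhaustive and mutually exclusive
over the family. Pool sums per sample, the species fold-change tables, and
the **nascent-CL/PG ratio** — a product/precursor proxy for cardiolipin
synthase (Crls1) activity, compared old vs young per tissue with BH across
tissues — are produced by `clPoolSums()`, `clSpeciesTable()` and
`clPgRatioComparison()`. The proxy numerator is the nascent pool only; a
total-CL numerator is available as a sensitivity switch. The q-value family
for species tables is the whole detected CL family within a tissue.

# Acyl-chain remodeling and panels

Lipid names are parsed by a deliberately narrow grammar
(`parseLipidName()`): summed notation (`"TG 52:3"`) and chain-resolved
notation (`"CL(18:2/18:2/18:2/18:2)"`) in both parenthesised and
space-separated dialects, with internal-standard suffixes (`-d5`, `-13C6`)
stripped and flagged, and ether/oxidised decorations parsed to an `other`
class that the analysis stages skip. Chain-resolved totals are checked
against the class arity (CL 4 chains, TG 3, DG 2, ...).

Free fatty acids and acylcarnitines are bucketed by total carbons into
SC/MC/LC/VLC with closed-open boundaries at 6, 13 and 22; TG/DG/MG species
into short/medium/long at 48 and 54 total acyl carbons. All boundaries are
configuration with these defaults; the TG boundaries are a pragmatic
reconstruction of the field's short/medium/long convention, and within
buckets saturated (zero double bonds) and unsaturated species are
reported separately.
`bulkSums()`, `tgRemodelingTable()` and `bucketFcMatrix()` reuse the
differential records exactly — a matrix cell either equals the
corresponding record or carries an absent marker (the feature was never
observed in that tissue before imputation).

Named panels (oxylipins with sex stratification, hexosamine biosynthesis,
central carbon and amino-acid metabolism, the four omega-oxidation
dicarboxylic acids, 18-HODE) and the stress ratios (inosine/IMP,
hypoxanthine/xanthine, GSSG/GSH) ship as configuration, with
case-insensitive, synonym-aware name resolution. Ratio metrics divide
normalized intensities per sample and are invariant to per-sample scaling.

Di- and tri-peptides are recognised as hyphen-separated three-letter
residue codes and virtually digested: for each canonical residue,
`residueProfile()` reports the percentage of detected peptides containing
that residue (at least once — multiplicity is ignored) that are
significantly up- or down-regulated at raw $p < 0.05$.

# The synthetic atlas generator

The study's deposited data are raw spectra, so the package validates its
stages on a fully synthetic multi-organ atlas with known truth
(`buildCatalog()`, `simulateStudy()`, `generateStudy()`). The generator's
defaults *are* the study conditions the pipeline is tested under; they are
not tuned per run.

**Design.** Seven tissues (BAT, VAT, SAT, quadriceps, heart, jejunum,
feces), 8 animals per (age, sex) cell — 16 per age group, 32 per tissue,
matching the 28-of-32 presence rule — and a 1,000-feature catalog: a fixed
cardiolipin family of 66 species (60 CL spanning 62:2–80:12, constructed so
the default thresholds label 36 nascent and 24 mature, plus 6 DLCL), 20
PGs, a TG/DG/MG grid, FA and CAR series covering every chain bucket, the
named polar metabolites behind all shipped panels, 80 seeded di-/tri-
peptides covering all 20 residues, and unnamed filler.

**Model.** Log2 intensity is baseline + tissue offset + effect terms +
Gaussian noise (sd 0.35), with multiplicative age, sex and age-by-sex
effects per tissue and a per-sample drift factor (sd 0.25 log2) that the
median normalization is meant to remove. Missingness is
missing-not-at-random — cells below the feature's pooled 2% intensity
quantile — plus 1% missing-completely-at-random. Five per cent of features
are emitted on a second platform with a noisier QC profile, and five QC
pool replicates provide the RSDs that drive the duplicate merge.

**Effects.** Each tissue has a configured number of affected features and
a directional split: 375 affected in BAT with 70% decreased, 380 in VAT
(75% increased), 520 in feces (76% increased), 350/320/300/350 in SAT,
quadriceps, heart and jejunum. These fractions follow the proportions the
atlas-scale census reports per tissue. Named ("pinned") effects anchor the
headline biology: the nascent-CL depletion behind the CL/PG proxy (BAT
1/2.8, jejunum 1/1.7, heart 1.1), the cardiac CL 72:8 loss (1/1.6), the
quadriceps ketone-body rise (beta-hydroxybutyrate 2.1) and aromatic
amino-acid increases (1.3), omega-oxidation dicarboxylic acids (1.8), the
tissue-divergent 12,13-DiHOME pattern, BAT oxylipin and hexosamine
declines with a male-only PGE2 effect, BAT TG size-class remodeling, and
LC/VLC shifts in fatty acids and acylcarnitines. Unpinned effects draw
|log2 FC| uniformly from [0.6, 1.5].

**Structural choices worth knowing about.**

* *Median-safe effect placement.* Median normalization removes each
  sample's median shift, so a generator whose effects move the per-sample
  median would make the configured effects unrecoverable by construction.
  Random effects are therefore placed only on features whose expected
  level in that tissue cannot cross the tissue median under the effect
  (margin 0.7 log2), and pinned species near the median are nudged out of
  the crossing zone on their own side. This keeps per-sample medians
  effect-free — exactly the regime in which median normalization is the
  right correction and the census is interpretable.
* *Detection floors for pinned species.* A printed fold change implies the
  analyte was comfortably quantifiable in its reporting tissue. Pinned
  species are therefore placed above the feature's expected pooled
  low-quantile threshold (plus a three-sigma cell margin) in their pinned
  tissue; without this, the MNAR masking plus min/10 imputation
  systematically inflates exactly the anchored fold changes.
* *Lipid-family structure.* Species of one lipid class share a class-level
  abundance band and class-level tissue offsets with tighter species-level
  dispersion (0.8 log2). This keeps family pool sums genuinely
  multi-species; without it a pool behaves like its single most abundant
  member.

**What the generator does not emulate.** Chromatography, spectra,
retention times, batch drift beyond a scalar per-sample factor,
correlation between metabolites of one pathway beyond the family
structure, heavy-tailed or feature-specific variance, and compositional
constraints of real tissues. Passing recovery tests therefore shows that
the pipeline's stages are correct and well-calibrated under the stated
model — not that the model captures every property of real LC-MS tables.

# Validation and reproduction

`acceptanceMetrics()` regenerates the default atlas for a set of seeds
(20 by default), runs the full cleaning and analysis chain, and
re-estimates every pinned quantity. Fold changes are aggregated across
seeds on the log2 scale and the geometric-mean ratio is converted back to
the signed convention — the signed fold change is discontinuous at
$r = 1$, so a plain mean of signed values is unstable for near-null
effects; census percentages are arithmetic means. The same computation
backs `scripts/acceptance.R` and the acceptance test suite. Problem sizes
were chosen as the defaults above (20 seeds, 7 tissues, 1,000 features);
a full run takes well under two minutes on one core.

# Numerical conventions and degenerate inputs

* Boundaries of all bucket/size schemes are closed-open on the lower edge.
* Zero-variance features map to all-zero under Pareto scaling; a
  zero-median sample is an error naming the sample.
* Constant pooled data yield $p = 1$; empty groups are domain errors.
* Duplicate groups with no QC RSD keep their first member by tie-break
  order, with a warning.
* All randomness flows from explicit seeds through one internal helper
  that restores the caller's RNG state; identical (configuration, seed)
  pairs reproduce byte-identical study files.

# Known limitations

* The nascent/mature thresholds are a reconstruction anchored at CL 72:8;
  studies using different criteria should set them in configuration.
* Fold changes are ratios of arithmetic means on the normalized scale; a
  median-based variant exists as a switch but is not the default.
* The census's raw-p convention is descriptive by design; its counts
  should not be read as FDR-controlled discoveries.
* Ether and oxidised lipids parse to `other` and are excluded from the
  lipid stages.
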