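# thermoshift

Organ-resolved analysis of aging metabolomics studies in R: old versus
young animals across many tissues, from post-annotation LC-MS intensity
tables to the biology-facing summaries that matter for mitochondrial
thermogenesis — cardiolipin remodeling, acyl-chain composition shifts,
lipokine and stress-ratio panels, and peptide residue-regulation profiles.

The package is aimed at metabolomics analysts who have a cleaned,
annotated samples-by-metabolites peak-height table (plus sample metadata
and an annotation catalog) and want a tested, reproducible implementation
of the whole downstream workflow, including a ground-truthed synthetic
multi-organ atlas generator for validating every stage without any raw
data.

## The statistics at the core

For each metabolite within a tissue, old vs young is summarised by a
signed fold change and a two-sided Mann–Whitney U test with
Benjamini–Hochberg FDR control within tissue:

* signed FC: with *r* = mean(old)/mean(young), report *r* if *r* ≥ 1 and
  −1/*r* otherwise (so FC = −2.8 means a 2.8-fold decrease);
* Mann–Whitney U: exact enumeration for pooled n ≤ 20 without ties,
  normal approximation with tie and continuity correction otherwise;
* sex effects: per-metabolite two-way ANOVA (age × sex, Type II for
  unbalanced designs) on log2, Pareto-scaled intensities.

Upstream, tables pass a fixed cleaning chain: cross-platform duplicate
merge by lowest QC RSD → presence filter (≥ 28 of 32 samples in at least
one tissue) → imputation with the feature minimum / 10 (fallback 100) →
per-sample median normalization. Downstream, cardiolipins are classified
as nascent / mature / remodeling intermediates (mature ⇔ total acyl
carbons ≥ 72 and double bonds ≥ 8, so tetralinoleoyl CL 72:8 anchors the
mature class), and the per-sample nascent-CL / PG pool ratio serves as a
product/precursor proxy for cardiolipin synthase activity.

## Worked example

Generate the default synthetic atlas (7 tissues × 32 sex-balanced
samples, 1,000 metabolites), clean it, and re-estimate the headline
quantities:

```r
library(thermoshift)

cat  <- buildCatalog(seed = 1)
sim  <- simulateStudy(cat, generatorConfig(), seed = 1)
sim$study
#> MetaboStudy: 1050 metabolites x 229 samples
#>   tissues: BAT, VAT, SAT, quadriceps, heart, jejunum, feces
#>   QC pool samples: 5

clean <- preprocessStudy(sim$study)
clPgRatioComparison(clean, c("BAT", "heart", "jejunum"))
#>    tissue fc_signed log2fc u_stat    p_raw    q_fdr
#> 1     BAT     -2.73 -1.450      0 1.54e-06 2.32e-06
#> 2   heart      1.10  0.141    207 3.09e-03 3.09e-03
#> 3 jejunum     -1.73 -0.788      0 1.54e-06 2.32e-06
```

The BAT cardiolipin-synthesis proxy drops almost threefold with age while
heart is essentially unchanged — the generator pinned these effects at
1/2.8, 1.1 and 1/1.7, and the pipeline recovers them from noisy,
missingness-ridden tables. The per-tissue census and a metabolite panel:

```r
tissueCensus(differentialTable(clean, "BAT"))[, c("n_detected",
    "n_dysregulated", "pct_up", "pct_down")]
#>   n_detected n_dysregulated pct_up pct_down
#> 1       1000            395   31.4     68.6

cc <- panelReport(clean, "quadriceps", defaultPanels()$central_carbon)$overall
cc[cc$name == "beta-hydroxybutyrate",
   c("name", "fc_signed", "p_raw", "q_fdr", "direction")]
#>                   name fc_signed    p_raw    q_fdr direction
#> 2 beta-hydroxybutyrate      2.32 1.54e-06 1.12e-05        up
```

About 69% of the significantly changed BAT metabolites decrease (the
configured split is 70% down), and the quadriceps ketone body
beta-hydroxybutyrate comes back around its pinned 2.1-fold increase.
`runPipeline(outDir, seed = 1)` chains every stage — ingest/simulate,
preprocess, differential + census, cardiolipin report, remodeling
matrices, panels, residue profiles — and writes per-stage CSVs plus a
JSON manifest.

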