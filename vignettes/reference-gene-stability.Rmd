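---
title: "Screening and evaluating qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and evaluating qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Relative quantification by qRT-PCR divides a target gene's signal by that
of one or more reference ("housekeeping") genes to cancel sample-to-sample
differences in RNA input, reverse-transcription yield and loading. The
whole construction stands or falls with the references: a reference whose
own expression responds to organ, developmental stage or stress silently
distorts every target-gene fold change computed against it. `refstab`
implements the now-standard screening workflow for organisms without
curated reference genes: prescreen candidates from RNA-Seq abundance
tables, measure them by qPCR, score their expression stability with four
independent algorithms, integrate the rankings into a consensus, and
finally demonstrate — with a real target gene — that the chosen references
matter.

# Data model and conventions

All algorithms consume a genes × samples matrix. Three scales appear:

* **Ct** (quantification cycles): the instrument output; lower Ct = more
  template. BestKeeper and the comparative ΔCt method work directly on Ct.
* **Relative quantities** `Q = E^(minCt − Ct)`: efficiency-corrected
  expression, anchored so each gene's most-expressed sample has Q = 1.
  geNorm and NormFinder work on `log2 Q`. The anchor is a pure per-gene
  rescaling: replacing the minimum Ct by, say, the mean Ct changes no
  geNorm, NormFinder or ΔCt output (shift invariance is part of the test
  suite).
* **Amplification efficiency** `E`: fold amplification per cycle,
  estimated per gene from a standard curve as `E = 10^(−1/slope)` with the
  slope of the OLS regression of Ct on log10 template amount. Efficiencies
  are accepted as percent (91.3) or fold (1.913); values above 2.2 are
  interpreted as percent. When no efficiency is attached, perfect doubling
  (E = 2) is assumed with a warning.

Technical replicates are averaged to one Ct per gene × sample before any
stability analysis; the replicate-level values are retained on the
`ct_matrix` because the validation ANOVA needs within-sample degrees of
freedom.

# The four stability algorithms

**geNorm.** The pairwise variation `V_gk` is the sample SD (n−1) across
samples of `log2(Q_g/Q_k)`; a gene's stability `M_g` is the mean of its
pairwise variations against all other candidates. The least stable gene
(highest M) is excluded and M recomputed until two genes remain; those are
reported as the best pair with their mutual V as a shared M. Ties at the
maximum M are broken by excluding the lexicographically last gene id, so
the ranking never depends on input order. The pairwise-variation series
`V(n/n+1)` is the SD across samples of `log2(NF_n/NF_{n+1})`, where `NF_n`
is the per-sample geometric mean of the `n` most stable genes; the
conventional cutoff of 0.15 decides how many references are needed, and
when no `V` falls below it the full panel size is reported with an
explicit flag rather than a silent default. Genes with M above 1.5 (the
conventional usability cutoff) are flagged.

**NormFinder.** A model-based score that, unlike geNorm, separates random
within-group scatter from systematic between-group shifts. Published
reimplementations differ in the exact bias-correction constant, so this
package fixes one estimator as its contract: log2 quantities are centred
per sample (removing loading artifacts exactly); per group the intragroup
variance is bias-adjusted by subtracting the mean of the other genes'
variances divided by (G−1), floored at 1e-8; intergroup differences are
shrunken by `γ²/(γ² + σ²/n)` with `γ²` the across-gene variance of the
group differences; the stability value is the mean over groups of
`|d̃| + sqrt(σ²/n)`. With a single group the score reduces to the adjusted
intragroup SD. Samples with any missing gene are dropped listwise, because
the per-sample centring needs complete columns. With very small panels
(G ≈ 3) the centring mixes a noisy gene's variance into every gene's
residuals and the bias adjustment floors the quiet genes — the noisiest
gene is still identified reliably, but quiet genes may tie; the test suite
documents both behaviours.

**BestKeeper.** Descriptive statistics of raw Ct: arithmetic and geometric
mean, extrema, SD and the mean absolute deviation (MAD) that the original
tool reports, with CV% for both. The conventional rule flags genes with
dispersion below 1 cycle as stable; the SD variant drives the ranking by
default and MAD is always reported alongside. The BestKeeper index (the
per-sample geometric mean of candidate Ct values) is computed with each
gene's Pearson correlation against it (p from the t transform with n−2
df, via `cor.test`). Because BestKeeper works on raw Ct, it is the one
algorithm that is *not* invariant to per-sample loading: loading noise
inflates every gene's Ct SD equally. The generator's loading-invariance
tests document this known methodological difference.

**Comparative ΔCt.** The mean over partners of the sample SD of pairwise
Ct differences. With all efficiencies at 2 it is algebraically identical
to the first-round geNorm M (log2 Q differences equal negative Ct
differences up to a per-gene constant, and constants drop out of an SD);
the suite asserts this identity to 1e-12, which cross-validates the two
implementations against each other.

# Consensus

Per-algorithm scores are converted to average ranks (ties share the mean
of their positions; missing scores rank last with a warning) and combined
as the geometric mean of each gene's ranks — a comprehensive value in
[1, G] that is 1 only for a gene ranked first by everyone and G only for a
gene ranked last by everyone. The web tool that popularised this
integration applies an undocumented internal weighting; `refstab`
deliberately implements the plain geometric mean, which is the documented
definition. Agreement sets (intersections of every algorithm's top-k and
bottom-k) mirror the Venn-diagram style summaries common in this
literature.

# Validation of chosen references

`normalized_expression()` computes efficiency-corrected target expression
`E_t^(ΔCt_t) / geomean_r E_r^(ΔCt_r)` against a named reference set,
either calibrated to a chosen sample (its value becomes 1) or anchored at
the minimum Ct. `compare_normalizers()` asks whether the *choice* of
reference set changes the result: each set's log2 profile is mean-centred
(two normalizers always differ by an arbitrary scale factor — their
anchors are measured with error, so comparing uncentred levels would flag
that measurement error, not a real discordance) and a classical one-way
ANOVA (via `stats::lm`/`anova`) is run across reference sets within each
sample group, at α = 0.01 by default. Per-sample comparisons use
technical replicates for the within-group degrees of freedom; metadata
groupings (e.g. treatment) use per-sample means. The degenerate case of
numerically identical values is reported as F = 0, p = 1.

A type-I-error property of this design is tested on "null" data with
technical noise only. That is deliberate: sample-level biological noise in
a reference gene produces *genuine* normalizer discordance — detecting it
is the purpose of the method — so a false-positive experiment must
exclude it.

# The synthetic-data generator

`simulate_ct_dataset()` emulates the measured inputs of a 14-sample
organ × stage × treatment study: leaves and fruits at stages 3/4/7 and
flowers, each under control and drought. Log2 expression is
`δ_g,group + L_i + ε_gi` with loading `L ~ N(0, τ²)` shared by all genes
of a sample and per-gene noise `ε ~ N(0, σ_g²)`; Ct follows as
`a_g − x·log(2)/log(E_g)`, plus technical-replicate noise. Defaults,
chosen once as the study conditions: ten genes with noise SDs
(0.05, 0.05, 0.4 … 1.0) — two clearly stable candidates among eight
mediocre-to-poor ones — baseline Ct spread over 18–25 cycles (the range
typical of reference-gene panels), loading SD 0.5 log2 units (realistic
cDNA input variation), three technical replicates with SD 0.1 cycles,
perfect efficiency, and no group effects unless injected. Fragment counts
for the prescreen are negative binomial with the same loading substream;
dilution series follow the standard-curve model exactly.

One master seed spawns four fixed substreams (loading, gene noise,
technical replicates, counts), so raising τ changes *only* the loading
draws: the suite exploits this to show exactly which statistics are
loading-invariant (geNorm, NormFinder, ΔCt) and which are not
(BestKeeper).

What the generator does *not* emulate: amplification inhibitors and
pipetting outliers, Ct censoring at the instrument's cycle limit,
between-run batch effects, and correlated biological noise between genes.
Passing recovery tests therefore shows the algorithms behave correctly
under the stated noise model, not that any particular real panel is
stable.

# Numerical choices and edge cases

* Sample SDs use the n−1 denominator throughout; this reproduces the
  printed CV columns of published per-gene summary tables from their
  printed means and SDs to ≤ 1e-3 relative error.
* Prescreen thresholds are strict inequalities (mean > 500, CV < 0.3);
  boundary-equal transcripts fail, and a zero-mean transcript fails with
  reason "zero mean" rather than raising.
* Missing Ct is `NA` end to end, never zero; geNorm drops samples
  pairwise per gene pair, NormFinder listwise, and a sample missing any
  gene of a normalization subset gets a missing NF.
* The variance floor (1e-8), the geNorm cutoffs (M 1.5, V 0.15), and
  α = 0.01 are exposed as arguments with these conventional defaults.
* Test and recovery experiments use 14–50 samples, up to 10 genes and
  50–100 simulation seeds per property — sizes chosen so each property is
  measured with enough replication to be stable across seeds while the
  whole suite stays interactive.

# Worked example

```{r, eval = FALSE}
library(refstab)

# prescreen the shipped published abundance table
ab <- goji_abundance_summary()
screened <- screen_candidates(ab[!ab$is_target, ])
sum(screened$pass)   # 12 transcripts survive mean > 500 & CV < 0.3

# simulate the study design and evaluate stability
sim <- simulate_ct_dataset(simulation_config(), seed = 42)
ev <- evaluate_stability(sim$ct, sim$meta)
ev$table
write_report(ev, "report")

# validate reference choices for a target gene
compare_normalizers(sim$ct, "gene10",
                    list(best = c("gene01", "gene02"), poor = "gene09"),
                    grouping = "treatment", meta = sim$meta)
```

# Known limitations

* The NormFinder estimator is one of several published variants; scores
  are comparable within this package, not numerically identical to other
  implementations (rank orders agree on well-separated panels).
* BestKeeper's per-gene regression on its index (slope/intercept output
  of the original spreadsheet) is not implemented; ranking uses
  dispersion only.
* The consensus is the plain geometric mean of ranks; numbers from the
  RefFinder web service, which weights ranks internally, will differ.
* No Excel input, no reading of instrument-native files; CSV/TSV only.
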