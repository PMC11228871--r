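---
title: "Scoring and classifying two-temperature genetic-interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying two-temperature genetic-interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldscreen)
```

## The experimental design being modeled

An arrayed genetic-interaction screen crosses a query mutant into a
genome-wide deletion library and pins the resulting double (or triple)
mutants as a colony grid — here 32 × 48 positions per plate — in technical
triplicate. Two copies of every plate set are grown, one at the permissive
temperature (30 °C) and one in the cold (19 °C). The biological question is
directional: which library deletions rescue a cold-specific growth defect
of the query (suppressors), which make growth worse at the permissive
temperature (synthetic sick), and which abolish a suppressor's rescue
without being sick on their own (reverters).

Colony size on an agar plate is dominated by multiplicative nuisance
factors shared across a plate — media batch, incubator position, pinning
pressure. The entire scoring scheme exists to remove them.

## The model

**Normalized growth.** For colony size $s$ on a plate whose measured
colonies have median size $m$, $\mathrm{NG} = s/m$. Dividing by the plate
median (rather than the mean) is robust to the strong right tail of colony
sizes and to the hits themselves; with ~1,500 colonies per plate a handful
of true interactors cannot move the median, which is why the median is
taken over *all* measured colonies, hits included. By construction the
median NG per plate is 1 (exactly so for odd colony counts), and scaling
every size on a plate by any $k > 0$ leaves NG unchanged to floating
rounding — both properties are asserted in the test suite.

**Replicate aggregation.** Per gene and temperature, the replicate NG
values are combined by their median — robust to a single failed pinning.
The order is fixed: NG per colony, then the replicate median, then the
ratio. Genes seen in fewer than `min_replicates` (default 2 of 3)
replicates are flagged `LOW_REPLICATES`, not dropped.

**The cold-specificity ratio.**
$$\mathrm{NGR} = \frac{\mathrm{NG}(19\,°C)}{\mathrm{NG}(30\,°C)}$$
Any interaction present at both temperatures cancels; NGR isolates the
cold-specific component. NGR > 1 is the suppressor direction, NGR < 1
cold-specific sickness. Interactions at the permissive temperature are
read from $\log_2 \mathrm{NG}(30\,°C)$ directly. A gene with missing or
zero 30 °C growth has no NGR (flags `MISSING_REF`/`ZERO_SIZE`) but keeps
its 30 °C statistic; a zero 19 °C size is a legal numerator
(measured-but-dead).

**Outlier calling.** Hits are outliers of the log2 distribution, assigned
two ways:

* *top 25th percentile*: the $k = \lceil 0.25 n \rceil$ most extreme genes
  of the requested tail, rank-based. Quantile interpolation dialects vary
  across software; sort-and-slice does not. Ties at the boundary are all
  included when that enlarges the list by at most $\lceil 0.01 n \rceil$
  genes, otherwise ties break by gene id — deterministic either way.
* *2 SD*: genes at least two sample standard deviations from the
  distribution median. The center is the median (robust); the SD is
  mean-centered by default, with a median-centered option
  (`summarize_distribution(center = "median")`) since either reading of
  "median and SDs" is defensible. Under Gaussian noise the two-tailed
  expectation is ≈4.6% of genes, which the null simulation reproduces.

## Cross-screen classification

**Query-specific filtering.** "Similar interaction" in the comparison
screen is operationalized as: same direction and at least
`similarity_fraction` (default 0.5) of the primary effect's magnitude, or
an outright same-direction hit there. The fraction is a free parameter the
source protocol leaves unspecified; it is recorded in every output.

**Reverters.** A reverter must be a negative log2 NGR hit in *both* the
double- and the triple-query screens (the intersection — either screen
alone admits genes acting through the wrong pathway) and quiet in both
single-mutant screens. "Quiet" means: not an outlier there, and
$|\log_2 \mathrm{NGR}|$ within `single_mutant_tolerance` SDs of that
screen's distribution. The default tolerance is 2 SD, deliberately aligned
with the outlier definition itself: a band of 1 SD would reject
$P(|z|>1) \approx 32\%$ of genuinely null genes per single screen —
whatever the noise magnitude — capping true-reverter recovery near
$0.68^2 \approx 47\%$ across two single screens. A gene lacking a finite
score in any required screen is reported `unclassifiable`, never silently
dropped.

**Enrichment.** Over-representation uses the one-sided (upper-tail)
hypergeometric test with Benjamini–Hochberg correction — the standard
over-representation analysis, chosen here because the original web-tool
statistics are not specified. The universe is the set of genes actually
scored (post-QC) in the relevant screen, not the whole genome:
conditioning on testability. Unannotated genes stay in the universe; the
annotation is treated as flat (pre-slimmed), with no ontology-graph
propagation.

## The synthetic-data generator

`simulate_screen()` draws colony sizes as
$$\log s = \mu + g_i + p_j + \log f_i(T) + \varepsilon,$$
with $\mu$ the baseline log size, $g_i \sim N(0, \sigma_g)$ a per-gene
growth offset shared across temperatures (it cancels in NGR),
$p_j \sim N(0, \sigma_p)$ one multiplicative effect per physical plate —
exactly the nuisance the plate median removes — planted fitness factors
$f_i(T)$, and log-normal colony noise $\varepsilon \sim N(0, \sigma_c)$.
Colonies drop out independently (absent rows, not zeros). Noise is
log-normal because colony growth is multiplicative and sizes are positive.

Defaults emulate the screen design: 2,000 genes on 32 × 48 plates,
technical triplicates, two condition labels ("30C", "19C"),
$\sigma_c = 0.35$ (≈0.5 on the log2 scale), $\sigma_p = 0.2$,
$\sigma_g = 0.25$, 2% dropout. No replicate-variance figures exist for the
real screens, so these magnitudes are chosen to be realistic for pinned
colony arrays while keeping planted log2 effects of ±3 (fitness factors 8
and 1/8, `planted_study_design()`) clearly recoverable; they are stated
once here and not tuned per analysis. An optional edge-row penalty exists
but is off by default, and no edge correction is applied in scoring.

What the generator does *not* emulate — spatial gradients within a plate,
neighbor competition, pinning-order artifacts, batch drift between
replicates — bounds what passing tests show: they validate the statistics
and the classification logic under the stated noise model, not robustness
to spatially structured artifacts in real plate images.

Determinism: every (query, temperature, replicate) stream is seeded by a
fixed hash of the master seed and those labels, so adding a query screen
never changes another's data, and standard-normal draws are always
consumed (then scaled) so that setting one SD to zero never shifts another
parameter's stream. Identical configurations are bit-identical.

## Numerical and degenerate-input choices

* Plate median 0 or all-missing plate: the plate is excluded with a
  warning (scoring errors only if nothing remains).
* Degenerate outlier distribution (SD = 0): `call_hits_two_sd()` errors —
  except inside `classify_reverters()`, where a zero-spread single-mutant
  screen simply has no outliers (the noise-free construction case).
* Distribution summaries require ≥2 finite values; non-finite entries are
  excluded and counted.
* log2 fields are carried alongside linear ones and asserted consistent to
  1e-12 relative; ranking by NGR and by log2 NGR coincide.
* All file formats are plain TSV with `#` comments, 1-based (row, col)
  coordinates, and temperatures as opaque labels — the pipeline never does
  arithmetic on temperature.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance script run five-screen studies
of 2,000 genes in triplicate (≈12,000 colonies per screen); repeated-seed
measurements use 20 seeds. These sizes give stable recovery estimates
(binomial SE ≈ 1% on a 20 × 20-gene class) while keeping a full run in the
tens of seconds on a single core.

## Known limitations

* Thresholds the source protocol leaves open (`similarity_fraction`,
  `single_mutant_tolerance`) have defensible defaults but genuinely change
  hit lists; both are mandatory entries in the run report.
* The percentile caller always returns a quarter of the screen — on a
  null screen those are not interactions. It mirrors the published
  hit-compilation rule; the 2-SD method is the conservative default in
  classification.
* Enrichment p-values inherit the usual over-representation caveats
  (annotation bias, non-independence of terms); no graph-aware method is
  attempted.
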