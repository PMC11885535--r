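---
title: "Methods: differential essentiality across growth environments"
author: "screendiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential essentiality across growth environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendiff)
library(SummarizedExperiment)
```

## The problem

Pooled CRISPR/Cas9 loss-of-function screens measure how knocking out each
gene changes a cell population's fitness, by tracking the relative
abundance of integrated single-guide RNAs (sgRNAs) across selection. When
the same library-infected population is split between parallel growth
environments — continued cell culture ("in vitro") and xenograft tumours
in mice ("in vivo") — a gene can be essential in one environment and
dispensable, or even growth-suppressive, in the other. The AP2 clathrin
adaptor complex in pancreatic cancer cells is the motivating example of
such a sign-reversing phenotype: its guides drop out in culture and
enrich in tumours. `screendiff` implements the full analysis chain that
detects these environment-dependent genes, plus a generative simulator so
every stage can be validated against ground truth.

## Screen design

Each cell line is independently infected in `R` replicate cultures at low
multiplicity of infection. Per replicate, genomic DNA is harvested from:

* one **initial** sample (before selection) — the paired denominator for
  all fold changes,
* one **in vitro** sample after continued passaging,
* `M` **in vivo** samples, one per xenograft seeded from that replicate.

The default design mirrors a five-cell-line screen in quadruplicate with
two mice per replicate: 20 initial, 20 in vitro and 40 in vivo samples,
so each per-cell-line contrast compares `n = 4` in vitro against `n = 8`
in vivo samples. Each xenograft is treated as its own sample because the
engraftment bottleneck makes tumours the dominant source of in vivo
variance.

## The scoring chain

For guide $g$ in sample $s$ with read count $c_{gs}$ and total sample
reads $N_s$ (assigned plus unassigned):

1. **Depth normalisation**: $r_{gs} = 10^6 \, c_{gs} / N_s$ (reads per
   million).
2. **Paired fold change**: with pseudocount $\epsilon$ and paired initial
   sample $i(s)$,
   $\mathrm{lfc}_{gs} = \log_2\!\big[(r_{gs} + \epsilon) / (r_{g,i(s)} +
   \epsilon)\big]$.
3. **Gene score**: $y_{Gs} = \tfrac{1}{|G|}\sum_{g \in G}
   \mathrm{lfc}_{gs}$, the mean over the gene's (by default five) guides.
4. **Control centering**: $c_s$ is the mean $\mathrm{lfc}$ of the
   non-targeting control guides in $s$; centred scores are $y_{Gs} - c_s$.
5. **z-score**: $z_{Gs} = (y_{Gs} - c_s)/\mathrm{sd}_s$, where
   $\mathrm{sd}_s$ is the sample standard deviation (denominator $n-1$)
   of the centred scores across all genes and control pseudo-genes in
   $s$.
6. **Contrast**: per (cell line, gene), the replicate $z$ vectors of the
   two environments are compared by a two-sided Welch $t$-test (sign
   convention: $t > 0$ when the in vivo mean exceeds the in vitro mean),
   and p-values are adjusted by Benjamini–Hochberg FDR across targeting
   genes within the cell line.
7. **Classification** at thresholds $(z^\ast, q^\ast)$, defaults
   $(1, 0.05)$: `opposite_suppressor` when $q < q^\ast$,
   $\bar z_\mathrm{vitro} < -z^\ast$ and $\bar z_\mathrm{vivo} >
   +z^\ast$; `opposite_essential` is the mirror image;
   `in_vitro_depleted` / `in_vivo_enriched` when only one environment
   clears $|z| > z^\ast$.

### Read processing

Pooled reads are demultiplexed by an inline barcode at a user-supplied
offset (the barcode position depends on the amplicon's primer
architecture, so it is a required parameter rather than a guess).
Barcode matching defaults to zero mismatches; one mismatch can be allowed,
with reads matching two or more barcodes within tolerance routed to the
unmatched stream. Guide assignment is exact string matching of the 20-nt
protospacer: with a library of unique 20-mers and zero mismatches
allowed, exact hashing is equivalent to ungapped alignment and needs no
external aligner. The default "scan" mode searches every 20-mer window of
the read (robust to variable vector flanks); a fixed-offset mode is
available for speed. Reads matching no guide are tallied as unassigned;
in scan mode, reads matching two or more guides are discarded as
ambiguous. Reads shorter than the window are unassigned, never an error.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pseudocount` | 1 | RPM | guarantees finite fold changes for dropout guides; 1 RPM is small against the ~1500 RPM median guide |
| `space` | log2 | — | makes enrichment and depletion symmetric and the guide mean robust; linear ratios available for inspection |
| `zPopulation` | all | — | the within-sample scale is estimated from all genes plus control pseudo-genes; `targeting` excludes controls |
| `zThresh` | 1 | z units | one within-sample standard deviation in each environment, opposite signs |
| `fdrThresh` | 0.05 | — | conventional FDR level |
| `ttest` | welch | — | the bottleneck makes in vivo variance exceed in vitro variance by design |
| `poolCellLines` | FALSE | — | each cell line is its own family of 112 tests; a pooled variant is available |
| `maxMismatch` (barcode) | 0 | nt | strictness avoids barcode collisions; 1 allowed with ambiguity protection |

Control guides are grouped, in manifest order, into **pseudo-genes** of
`guidesPerGene` guides so that control gene scores have the same
averaging depth — hence the same sampling variance — as targeting genes.
The grouping is a package design choice (nothing in the experimental
protocol dictates one) and is recorded in the output metadata; since the
centering constant is the mean over all control guides, it is invariant
to how controls are blocked.

## The simulator

`simulateScreen()` draws one library representation
$a_g \sim \mathrm{LogNormal}(0, \sigma_0)$ for the plasmid pool (default
$\sigma_0 = 0.5$ in natural-log space, a realistic spread for a cloned
pool: ~1.9-fold interquartile range). Each guide's selection effect is
the planted gene effect plus a per-guide efficacy jitter
$\sim N(0, 0.2)$ in lfc units, drawn once per guide and applied
identically in both selected environments, so neutral genes stay null in
the environment contrast. Expected selected abundance is
$a_g 2^{\mathrm{effect}}$; in vivo samples first draw a multinomial
engraftment bottleneck of $10^5$ cells from the library abundances, then
apply effects. Observed counts are negative-binomial with mean
`depth × relative abundance` (default depth $10^6$) and dispersion 0.05
— pooled screens are overdispersed relative to Poisson. Non-targeting
controls have zero effect by construction. One master seed reproduces
every artifact bit-identically.

What the simulator does **not** emulate: guide-specific off-target
effects, copy-number artefacts, PCR jackpotting beyond the NB
dispersion, clonal dynamics or tumour micro-environmental heterogeneity
beyond the single engraftment bottleneck, and sequencing error inside
the protospacer (available separately in `simulateFastq()` via
`corruptFraction`). Passing recovery tests on this generator therefore
demonstrates that the statistical chain is implemented correctly and has
the expected operating characteristics under its own assumptions — not
that those assumptions exhaust real screens.

## Calibration of the environment contrast

A property of the paired design worth understanding: the in vitro sample
and both xenografts of one replicate are all compared against the *same*
initial sample. That initial sample's measurement noise therefore enters
all three fold changes with the same sign, correlating same-replicate
z-scores across environments (correlation ≈ 0.5 under the default noise
settings, as the test suite measures). Because the design is balanced —
each replicate contributes equal weight to both environment means — this
shared term cancels exactly in the numerator of the $t$-statistic, but it
still inflates the within-group variance estimates in the denominator.
The unpaired Welch test is therefore *conservative* on this design: the
realized fraction of null genes with $p < 0.05$ (computed by the
acceptance suite over 50 simulated screens) falls well below the nominal
0.05, roughly threefold. The direction is safe — type-I error and FDR
control are preserved — at some cost in power. A test that modelled the
shared denominator explicitly (e.g. a mixed model with a replicate random
effect) could recover that power, but lies outside the scoring chain this
package implements; the published analysis uses the plain t-test, and so
does `screendiff`.

Hit classification is much stricter than the t-test alone (it also
demands opposite-signed means beyond $\pm z^\ast$), so the realized
false-opposite rate among neutral genes is essentially zero.

## Numerical choices and degenerate inputs

* Zero-total samples are a named hard error at normalisation (a sample
  with no reads carries no information and would otherwise divide by
  zero).
* A sample whose centred gene scores have zero dispersion is a named
  hard error at z-scoring rather than an Inf/NaN cascade.
* Both-constant t-test inputs degenerate to $t = 0, p = 1$ on equal
  means and $|t| = \infty, p = 0$ otherwise.
* BH adjustment is order-stable and propagates `NA` p-values as `NA`
  with a warning; control pseudo-genes are excluded from the FDR family
  but reported.
* Guides with zero initial-sample counts are retained (the pseudocount
  keeps them finite) rather than silently dropped, which would bias gene
  means; they can be filtered explicitly upstream if desired.
* Generated inline barcodes are chosen greedily in lexicographic order
  at pairwise Hamming distance ≥ 3, growing the barcode length until the
  design is accommodated, so single-mismatch demultiplexing can never
  produce ambiguous assignments among design barcodes.

## Problem sizes used by the test and acceptance suites

Unit tests run on reduced libraries (5–30 genes) at depths of
$10^3$–$10^5$ reads. The calibration study simulates 50 independent
null screens at the full default design (5 cell lines × 660 guides × 12
samples each, depth $10^6$), pooling 28,000 per-gene p-values; the
recovery study plants five opposite-suppressor genes at ±1.5 lfc units
and runs 20 independent screens. Read-processing oracles run on pooled
FASTQ of roughly $10^4$ reads. These sizes give Monte-Carlo standard
errors comfortably below the margins being tested while keeping the
whole suite in the minutes range.

## A worked example

```{r example, eval = FALSE}
genes <- sprintf("GENE%03d", 1:112)
cfg <- simConfig(effects = plantOppositeEffects(genes, nSuppressor = 5,
                                                effectSize = 1.5),
                 seed = 1)
sim <- simulateScreen(cfg)
gs <- scoreScreen(sim$counts, sim$library, sim$design)
res <- contrastEnvironments(gs, sim$design)
subset(res, hit_class == "opposite_suppressor")
```

## Known limitations

* No guide-efficacy weighting, copy-number correction or
  MAGeCK-style rank aggregation / maximum-likelihood modelling — the
  scoring chain is deliberately the mean/z chain described above.
* The unpaired t-test ignores the replicate pairing structure
  (conservative; see above).
* Exact matching cannot rescue reads with sequencing errors inside the
  protospacer; at typical error rates this costs a few percent of reads
  uniformly across guides.
* The engraftment bottleneck size in real xenografts is unknown; the
  default $10^5$ is a plausible order of magnitude and
  `recoveryExperiment()` is the tool for sensitivity analyses over it.
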