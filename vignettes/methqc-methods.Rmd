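---
title: "Methods and design notes for methqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for methqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methqc)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of the methods sections of the mature
omics QC packages. Everything stated here is either a definition or a
design decision; empirical behaviour is demonstrated only through the
package's own test suite and acceptance script.

## Input model

The pipeline consumes the three tab-delimited files exported by the
GenomeStudio Methylation Module. The Average Beta table carries four column
groups per sample — `<sample>.AVG_Beta`, `<sample>.Detection Pval`,
`<sample>.Signal_A`, `<sample>.Signal_B` — and the Control probe profile
carries `<sample>.Signal_Grn` / `<sample>.Signal_Red` pairs. Files are read
as UTF-8 (a leading BOM is tolerated) with `.` as the decimal separator;
readers are invariant to row order; missing numeric cells (`NA`, `NaN`,
empty) propagate as missing — never as zero, which would corrupt log-ratios
downstream — and are excluded pairwise from all summary statistics.

The two BeadChip generations use identical signal column *names* but swap
their meaning: on the 27K panel `Signal_A` is the methylated intensity,
while the 450K export puts the methylated intensity in `Signal_B`. Because
the headers are indistinguishable, header sniffing cannot decide the panel;
the `panel` argument ("450K" default in the pipeline) selects the mapping
explicitly, and both dialects are covered by round-trip tests.

Detection p-values and Beta-values are consumed as computed by
GenomeStudio; the package deliberately does not re-derive them from raw
bead-level data (that is the scanner software's contract), and it does not
read binary IDAT files.

## Control-probe metrics

The negative control probes are randomly permuted sequences that should not
hybridize; their per-sample, per-channel mean signal defines the *system
background*. Each control category is then scored as

$$\mathrm{pct}\_\mathrm{bg} = 100 \cdot
  \frac{\text{mean negative-control signal}}
       {\text{mean category signal}}$$

per channel, restricted to a subcategory where the category has one
(extension and non-polymorphic per nucleotide, hybridization per
concentration level, specificity separately for perfect-match and mismatch
probes). This percentage-of-background-on-signal definition was fixed
because it makes "low percentage = good performance" hold for every
signal-bearing category while staying scale-free: multiplying all of one
sample's intensities by a constant leaves every percentage unchanged, a
property the test suite checks.

Two categories invert the reading: target-removal probes (stripping worked
if they sit at background) and mismatch specificity probes (non-specific
extension is absent if they sit at background). The summary therefore
carries an `orientation` column (`low_good`, `high_good`, `background`) so
plots and flags never mislabel them, and target removal additionally gets a
secondary metric, its mean signal relative to the low-concentration
hybridization controls, because "low" for this category is defined relative
to the weakest genuine signal. Bisulfite conversion is monitored on the
green channel, where the conversion chemistry of the type-I design reads
out. A category whose mean signal is non-positive is reported as an
`undefined_high` flag rather than an infinity, and for the `low_good`
categories a percentage at or above 50 raises `very_high_ratio` — the
signature of a failing array, whose signals collapse to background.
Control rows whose type string cannot be mapped onto the eight categories
are retained but flagged unrecognized and excluded from metrics, since
newer panels introduced control types the original chip lacked.

## Detection filtering

"Not detectable" is strict: a probe fails detection at cutoff $c$ when its
detection p-value satisfies $p > c$, and a sample passes overall when its
*mean* detection p-value is strictly below the pass cutoff (0.05 by
default). Strict inequalities were pinned deliberately so that boundary
behaviour is testable and consistent between the per-sample percentages,
the pass flag and the undetected-CpG lists. Percentages are computed over a
sample's non-missing probes.

The undetected-CpG lists (one per cutoff, 0.01 and 0.05 by default) contain
probes failing detection in strictly more than 5% of the samples. They are
computed *after* sample filtering: a removed array should not be able to
push a probe onto the list, which is also why the pipeline recomputes the
detection summary on the retained set for reporting. Optional
chromosome-X filtering (off by default, matching the pipeline's default
configuration) takes an external probe-to-chromosome mapping; probes absent
from the mapping are retained with a warning rather than silently dropped.

## Normalization and methylation scales

Quantile normalization operates at the probe level on the *pooled*
intensities: for each sample the methylated and unmethylated vectors are
stacked into one 2N-vector, ranked, and each value is replaced by the
cross-sample mean of the order statistics at its rank; the meth/unmeth
split is then restored by position. Pooling rests on the assumption that
the pooled intensity distribution is similar across samples even when
global methylation differs — normalizing the two channels separately, or
normalizing summarized Beta-values as one would for expression arrays,
would force equal methylation distributions across biologically different
samples and was rejected. The mean (not the median) of order statistics is
used as the reference, the conventional choice, and it is what makes the
equalized sorted vectors bit-identical across samples.

Numerical conventions, chosen once and pinned by tests: ties receive the
mean of the tied order-statistic targets (stable and
permutation-invariant); missing intensities are excluded from ranking and
restored as missing, with incomplete samples mapped through linear
interpolation of the reference quantile function rather than imputed; a
single-sample input is returned unchanged with a warning. Quantile
summaries elsewhere in the package (dye-bias diagnostics) use linear
interpolation between order statistics (R's type-7 rule) for
cross-implementation determinism.

M-values are $\log_2((M+\varepsilon)/(U+\varepsilon))$ with
$\varepsilon = 1$ intensity unit by default, and Beta-values are
$M/(M+U+\alpha)$ with $\alpha = 100$; both offsets guard division and log
at zero intensity, follow common practice for these arrays, and are
exposed as arguments. At zero offsets the two scales are linked by
$\mathrm{Mval} = \log_2(\beta/(1-\beta))$, which the tests verify to
$10^{-9}$. M-values are used for PCA and clustering because their
log-ratio scale is closer to homoscedastic than the bounded Beta scale.

## Sample similarity

PCA is computed on samples after probe-wise mean centring, without
scaling — M-values already share a unit — and on complete-case probes (a
probe with any missing M-value is excluded from both PCA and clustering;
the simplest deterministic missing-data contract). Component signs are
fixed by forcing each component's largest-magnitude loading positive, so
scores are reproducible across BLAS implementations and sample orderings.
Clustering defaults to Euclidean distance — the pipeline's standard
setting — with average linkage; the linkage is a declared default, not a
value inherited from any reference configuration, since only the distance
is standard. `ward` maps to the Ward D2 criterion, and `pearson` means
$1 - r$. Non-finite distances (e.g. a zero-variance sample under the
correlation metric) raise an error naming the offending pair. Trees export
as Newick strings with merge heights as branch lengths.

## Synthetic data: what it emulates and what it does not

The generator's default design is a three-group control experiment — native
Jurkat DNA (target Beta 0.50), artificially methylated Jurkat (0.85) and
whole-genome-amplified unmethylated DNA (0.05) — each group processed with
two bisulfite kits in two biological replicates, plus one poor-quality
brain sample, 13 arrays in all. The intensity model is

$$M = (b + \beta\,R)\,f + e, \qquad U = (b + (1-\beta)\,R)\,f + e,$$

truncated at zero, with background $b = 100$, dynamic range $R = 10{,}000$,
batch factor $f$ (1.1 for the second kit), and Gaussian noise
$e \sim N(0, 80^2)$. Per-probe true Betas are drawn once per group around
the target (sd 0.08, clipped to $[0,1]$) and shared by the group's
samples, which is what makes replicates correlate: the expected Beta
correlation between replicates is
$\sigma_b^2 / (\sigma_b^2 + \sigma_e^2) \approx 0.97$ with these defaults,
comfortably above the 0.95 replicates of a well-behaved experiment show.
The noise sd was fixed at 80 from that closed-form calculation. Good
samples draw detection p-values uniformly on $[0, 0.005]$; the poor sample
has 98% of its probes at background intensity with $p \sim U(0,1)$, giving
a mean detection p-value near 0.5 — ten times the 0.05 cutoff — more than
90% undetected probes, and control probes at background (hence
very-high background-on-signal ratios), the canonical failing-array
signature. A 1.2× green-channel factor plants a visible dye bias in the
control profile. All randomness flows from the single `seed` field, so a
fixed seed reproduces the written files byte for byte.

What the generator does *not* emulate: bead-level replicates and their
variance structure, the bimodal Beta distribution of real genomes, probe
type I/II chemistry differences, genomic covariates (CpG islands, SNPs
under probes), or spatial chip artefacts. Passing tests on this synthetic
model therefore demonstrate the pipeline's arithmetic, contracts and
decision rules — not that any particular biological dataset is clean.

## Problem sizes and runtime

The bundled tests run the full pipeline on 13 samples × 150–5,000 probes
and the oracle comparisons on up to 50 × 1,000 matrices; the acceptance
script uses the full 13 × 5,000 default design. These sizes keep the whole
suite under a minute on one core while exercising every code path; all
algorithms are vectorized over probes and scale linearly in probe count,
so 450K-scale inputs are limited by memory, not algorithmic cost.

## Known limitations

- Beta and detection p-values are trusted from the export; inconsistent
  upstream settings (e.g. different GenomeStudio versions per batch) are
  not detectable here.
- The control-category classifier is regex-based over the control-type
  text; exotic manifest labels fall into the flagged-unrecognized pool.
- The workbook export is SpreadsheetML 2003 XML (a single plain-text file
  Excel and LibreOffice open natively); tab-delimited mirrors are always
  written alongside for toolchains that do not read it.
- Differential methylation is out of scope by design: the M-value export
  is the hand-off point to modelling packages.
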