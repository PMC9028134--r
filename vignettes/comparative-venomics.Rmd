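---
title: "Methods: comparative venom-gland analysis at small n"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative venom-gland analysis at small n}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdelta)
```

## The problem

Venom-gland studies of closely related snake species (here modeled on a
two-species *Bothrops* design) typically sample very few individuals — two
per species is common — which rules out replicate-based differential
expression models. At the same time, the quantities of interest are
relative: TPM expression, spectral-count proteomes and small-RNA libraries
are all compositions. venomdelta implements a coherent pipeline for this
regime: compositional normalization, an empirical nontoxin null for calling
divergent toxins, codon-level selection statistics on ortholog pairs,
coexpression modules, miRNA target scanning, and proteome integration.
Every stage is validated against a synthetic cohort generator that records
the ground truth it plants.

## Compositional normalization

TPM columns are mapped to clr space, $x \mapsto \ln x' - \overline{\ln x'}$,
where $x'$ is the zero-replaced column. The default zero policy is
multiplicative replacement (half the smallest nonzero value in that sample);
a pseudocount alternative is available. clr columns sum to zero, are
invariant to per-sample rescaling, and preserve ranks — properties the test
suite checks over random compositions. All downstream geometry (outlier
bands, omics correlations, translation efficiency) lives in clr space, so
the results do not depend on sequencing or MS depth.

Nontoxins are filtered before the null distribution is built: a transcript
must exceed 1 TPM in *every* individual of the analysis (strictly greater —
a transcript at exactly 1 TPM in one individual is removed).

Small-RNA count libraries are normalized by TMM. Trimming here is by value
quantiles of the M and A distributions rather than by ranks: miRNA libraries
are small and heavily tied, and rank-based trimming can split a tie group of
identical M-values arbitrarily (in the worst case discarding the entire
consensus mass and returning a factor of 1). With value-quantile trimming an
M tie group survives or is trimmed as a unit; on tie-free heterogeneous
libraries the factors agree with the rank-based implementation in edgeR to
within 2%, which the test suite verifies.

## The nontoxin null band

With two individuals (or two species means) as axes, the cloud of nontoxin
clr pairs defines the null expectation for expression divergence. We fit a
total-least-squares line — the first principal axis of the 2×2 covariance,
through the centroid — because both axes are noisy measurements of the same
quantity; an ordinary regression would attenuate the slope. The band
half-width is the 99th percentile (linear interpolation between order
statistics) of the absolute orthogonal residuals of the nontoxins. A toxin
whose perpendicular residual exceeds the half-width is called an outlier;
the residual sign gives the direction (which individual or species is
higher). A symmetric band over absolute residuals was chosen over two
one-sided quantiles (a signed option exists) because the band is described
and plotted as a single interval around the fit.

Design choices worth stating:

* The per-species summary for interspecific comparisons is the arithmetic
  mean of clr values over individuals, i.e. the geometric mean of
  abundances.
* The clr geometry is computed on the full annotated composition (filtered
  nontoxins plus toxins), not on toxins alone; a caller can subset before
  transforming if desired.
* Degenerate isotropic clouds break the fit tie toward slope 1 with a
  warning; truly collinear nulls give a zero-width band, so only exact
  departures are flagged.

On null cohorts (no planted effects) the flag rate of toxin-labeled null
transcripts matches the nominal 1% within binomial error, and a single
ortholog planted at 6-fold between species (log-scale noise sd 0.3) is
flagged with the correct direction in essentially every seeded run — both
properties are exercised by the acceptance tests.

## Orthology and selection

Cross-species ortholog pairs are inferred by reciprocal best hit over global
protein alignments (BLOSUM62, gap open 10 / extend 1), scored within the
toxin and nontoxin partitions separately; ties break lexicographically and
unpaired sequences are surfaced as putative duplication/loss candidates.
RBH gives exactly the bijective pairing the per-pair analyses consume.
Codon alignments are protein-guided: the protein alignment is back-threaded
onto the nucleotides and every codon column containing a gap is dropped.

Pairwise dS, dN and ω use Nei–Gojobori counting with Jukes–Cantor
correction. Per codon position the synonymous site fraction is the number
of synonymous single-nucleotide changes divided by the number of changes
that do not create a stop codon, so every sense codon contributes exactly
3 sites. Differences are averaged over all mutational pathways between two
codons (1, 2 or 6 orderings), excluding pathways through stop codons and
falling back to including them if all are blocked. Proportions are
corrected by $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; results with
$p \ge 3/4$ or $dS = 0$ are flagged undefined rather than raising errors.
Counting was chosen over maximum-likelihood codon models deliberately: it is
self-contained, exhaustively verifiable against enumeration (the test suite
checks all 61×61 sense codon pairs), and in the retained dS window
(0.001–0.10; pairs outside are flagged `ds_too_low`/`ds_too_high`)
counting and ML agree closely.

Toxin and nontoxin distributions of each metric are compared with a
two-sample Wilcoxon rank-sum test. The original description of this
comparison names the signed-rank variant, but the design is structurally
two independent samples; `paired = TRUE` is available for users who pair
pathways explicitly. The 95th-percentile flags are computed on the nontoxin
distribution by default (pooled optionally).

## The sequence evolution simulator

`evolve_ortholog_pair()` controls ω with an acceptance filter rather than a
full codon substitution model: uniform random single-nucleotide proposals,
stop codons rejected, nonsynonymous proposals accepted with probability
$\min(1, \omega)$ and synonymous with $\min(1, 1/\max(\omega, 1))$. A
branch runs until its target number of accepted synonymous events — chosen
from the JC-inverted target dS and the ancestor's synonymous site count —
is reached. Because proposal opportunity is proportional to site counts,
the accepted nonsynonymous/synonymous ratio matches ω in expectation.
Realized event counts and realized ω are recorded in the truth record, and
recovery tests compare estimates against realized, not nominal, values;
with 500-codon ancestors at dS ≈ 0.05 the median NG86 estimate sits within
15% of the realized ω for planted ω between 0.2 and 2.4. Targets implying a
synonymous proportion ≥ 0.74 are refused, since the distance correction
degenerates there.

## Coexpression modules

The module stack is a deliberately transparent reimplementation of the
CEMiTool-style workflow at its stated parameters: log2(TPM+1) transform, a
lowess variance-vs-mean trend filter, unsigned adjacency $|r|^{\beta}$ with
β = 10 and Pearson correlation, topological overlap, average-linkage
clustering of 1 − TOM with a static cut (default height 0.25), and minimum
module size 1 (smaller modules would be merged into the module with the
most correlated eigengene). A static cut replaces dynamic tree cutting to
keep the procedure deterministic and testable; perfect planted blocks are
recovered exactly, and five planted profiles among noise transcripts are
recovered with adjusted Rand ≥ 0.9.

When the variance filter is given a count cap it keeps the top-k
transcripts by trend residual, which makes the filter idempotent; with no
cap it keeps everything above the trend (not idempotent, since the trend is
refit). The pipeline caps the filter at 200 transcripts so the network
stays at the size this workflow is designed for. Four samples make
correlation estimates coarse — a warning is emitted below eight samples —
so module detection is validated on synthetic designs with 12 samples.
Within-module member noise in those designs is sd 0.1 around unit-spread
profiles (correlations near 0.99), representing tightly co-regulated
transcription.

## miRNA toolkit

Quantification is genome-free: collapsed reads are assigned to a mature
reference when they match full-length with at most one mismatch and ±2 nt
of end flexibility; ambiguous reads go to the best match and exact ties are
split fractionally, so assigned plus unassigned counts always equal the
total. Novel-miRNA candidates come from the Dicer duplex signature among
abundant unassigned reads: reverse-complement pairing with exactly 2-nt 3'
overhangs on both strands and at least 14 paired positions, G:U allowed.

Target sites are canonical seed matches on toxin 3'UTRs: a perfect
Watson–Crick match to miRNA positions 2–7 defines the core, extended to
7mer-m8 / 7mer-A1 / 8mer by the position-8 match and the A anchor. The
duplex score (+5 per WC pair, +2 per G:U over the gapless full-length
duplex) is reported for ranking but not thresholded; thermodynamic folding
is intentionally out of scope, since downstream integration consumes only
the presence of plausible sites. Regulatory candidates are the conjunction
of three conditions: miRNA log2 species ratio ≥ 1 (TMM-normalized), toxin
translation efficiency in the lowest quartile, and ≥ 1 seed site. Both
thresholds are explicit parameters echoed into the report.

## Proteome integration

Spectral counts (EUSC) are normalized to per-sample fractions and compared
to transcript abundances in clr space: Spearman's ρ (average ranks),
Pearson's R, and an OLS best-fit line of protein on transcript (the
identity line is the reference; an orthogonal fit is available by flag).
Translation efficiency is the clr difference, protein minus transcript, per
toxin and species; it is invariant to depth on either side, and a constant
added to one side shifts all values equally without changing the low-TE
ranking. Proteomes are species-level pooled tables, BPP-family transcripts
excluded (their processed peptides escape shotgun proteomics).

## The synthetic cohort generator

`generate_cohort()` emulates the study design: 2 species × 2 individuals,
~50 toxin orthologs in named venom families plus 3,500 nontoxin orthologs.
Expression baselines are log-normal with a shared ortholog baseline across
species (which reproduces the strong cross-sample correlation of real
venom-gland scatter plots), a +4 natural-log bonus for toxins (venom glands
are toxin-dominated), and independent per-individual log-normal noise.
Within-species biological noise is not reported in the kind of study being
emulated; the default sd of 0.3 on the natural-log scale (~35% coefficient
of variation) was chosen once as a realistic venom-gland value and is a
documented free parameter. Planted interspecific shifts multiply one
species' mean; realized effects are recorded on the pre-closure log scale,
since clr analyses are invariant to the TPM closure. Ortholog CDS pairs are
evolved at class-specific dS/ω (toxin mean ω 0.67, nontoxin 0.2, dS drawn
from 0.01–0.09) unless a plan row overrides them. Proteomes are multinomial
draws from exp(clr + offset) at a configurable depth; miRNA libraries are
mature-sequence counts (no hairpin simulation — the genome-free setting is
part of the design). Planted seed sites are written into target 3'UTRs,
and chance occurrences of a planted miRNA's seed core are scrubbed from all
non-target UTRs so the planted target map is the complete ground truth —
recovery tests can then demand zero false positives instead of modeling
background site frequency.

What the generator does not emulate: read-level sequencing noise, assembly
artifacts and chimeras, UTR annotation errors, mass-spectrometry
identification bias, paralog interference beyond simple duplications, and
between-family sequence similarity. Passing tests therefore demonstrate
correctness and calibration of the statistical machinery, not robustness to
upstream data-quality failures.

## Problem sizes and numerical choices

The test and acceptance workloads use deliberately chosen sizes: all
61×61 codon pairs for the counting oracle; 200 replicates of 500-codon
pairs for ω recovery (60 replicates of 400 codons in the acceptance
script); calibration and power cohorts with 3,500 nontoxins; module
recovery over 20 seeds (10 in the script); 100-seed Spearman recovery at
n = 50 toxins (60 in the script). Quantiles are everywhere the
linear-interpolation definition; determinism is guaranteed by a single
cohort seed from which all stage randomness derives; and the pipeline
report is serialized without timestamps so reruns are byte-identical.

## Known limitations

* n = 2 per species is the design constraint, not a recommendation; the
  null-band approach calibrates the false-positive rate but cannot separate
  individual variation from species divergence with this sampling.
* NG86 counting saturates above dS ≈ 0.3 and mildly underestimates large ω;
  within the retained dS ≤ 0.10 window this bias is small (the recovery
  tests bound it at 15%).
* RBH assumes one-to-one orthology; lineage-specific duplications are
  reported but not resolved into gene trees.
* Seed-site presence is a weak predictor of repression on its own; the
  candidate list is a screen, not an inference of regulation.
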