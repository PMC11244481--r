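---
title: "Models and design of the candidate-gene funnel"
author: "gwasFunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the candidate-gene funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasFunnel)
```

This vignette is the package's own account of the statistics it
implements, the choices made where the design was genuinely open, and
what the synthetic-data generator does and does not emulate.  It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## Trait model

Replicated measurements are modeled as
$$y_{ir} = \mu + u_i + r_r + e_{ir},\qquad
u_i \sim N(0,\sigma^2_{s}),\; r_r \sim N(0,\sigma^2_{rep}),\;
e_{ir} \sim N(0,\sigma^2_e),$$
fitted by REML through `lme4::lmer(content ~ (1|sample) + (1|rep))`.
The reported per-sample trait is $\mu + \hat u_i$, not the centered
BLUP, so downstream group contrasts and impact rates stay on the mg/g
measurement scale.  An independent grid-search REML oracle (dense search
over the two variance ratios with $\sigma^2_e$ profiled out) verifies
the fit in the test suite to 1e-4.  Degenerate inputs are handled
explicitly: a constant response returns zero components and constant
BLUPs; a single replicate level drops the replicate term with a warning.
Note that the replicate factor typically has very few levels (three by
default), so $\sigma^2_{rep}$ is estimated with ~2 degrees of freedom;
its single-dataset estimate is intrinsically noisy, which the recovery
tests acknowledge by averaging estimates over seeds and assessing the
component mean.

Normality of the BLUPs is checked with a one-sample Kolmogorov–Smirnov
test against $N(\bar x, s^2)$.  Parameters are estimated from the data
and no Lilliefors correction is applied — matching common
statistics-package behavior — so the test is conservative; the result
object carries a `parametersEstimated` flag saying so.

## Single-locus association

Kinship is the centered cross-product (VanRaden) estimator
$K = WW^\top / c$, $W_{ij} = x_{ij} - 2\hat p_j$,
$c = 2\sum_j \hat p_j(1-\hat p_j)$, with a 1e-6 diagonal ridge for
numerical positive semidefiniteness.  Population structure enters as
genotype principal components; the "Q" models of the six-model battery
use PCs as well (a standard surrogate for STRUCTURE ancestry fractions,
which are out of scope), differing from the "PCA" models only in the
number of components (`qQ = 2` vs `qPCA = 3` by default).

The GLM scan is per-marker OLS with a 1-df partial F test and partial
$R^2$ as PVE, complete-case per SNP.  The MLM scan is EMMA-style: the
null model $y = X\beta + u + e$, $u \sim N(0, \sigma^2_g K)$, is fitted
once by REML over the spectral decomposition of $K$, and every marker is
then tested by GLS at the fixed variance ratio
(population-parameters-previously-determined).  Two deliberate choices:

* the marker test uses a $t^2$/F reference with $n - q - 1$ denominator
  degrees of freedom rather than an asymptotic $\chi^2$ Wald form, so
  that as $\hat\sigma^2_g \to 0$ the MLM p-values collapse *exactly* to
  the GLM F-test (a limiting identity the tests assert to 1e-6);
* markers are mean-imputed for the mixed model (the rotation is shared
  across markers), while the GLM keeps per-SNP complete-case handling.

LD pruning is greedy within windows of 50 SNPs (step 50): of any pair
with $r^2 \ge 0.2$ the lower-MAF SNP is dropped (tie: the later
position), until no retained within-window pair violates the cutoff.
The pruned panel feeds kinship and PCs; all markers are scanned.  The
Bonferroni threshold is FWER$/m$ with FWER = 0.01 — the arithmetic that
reproduces the conventional 2.54e-7 (−log10 = 6.59) at m = 39,327; note
that this constant corresponds to 0.01/m, not 0.05/m.

## Multi-locus association

One representative two-stage model stands in for the
multi-locus random-SNP-effect family; the five published variants are
not re-implemented (the funnel consumes only the set of LOD-significant
loci).  Stage 1 retains markers with mixed-model $p \le 0.01$ (capped at
$n/2$ markers).  Stage 2, on the whitened scale, fits
$y = X\beta + \sum_k z_k b_k + e$ with $b_k \sim N(0, \sigma^2_k)$ and
estimates the marker-specific variances by EM (iteration cap 1000,
relative tolerance 1e-8, variance floor 1e-10); variances driven to the
floor zero out their effects — automatic-relevance-determination
shrinkage.  Surviving markers enter a final joint fit and each is scored
$\mathrm{LOD}_k = n \ln(\mathrm{RSS}_{-k}/\mathrm{RSS})/(2\ln 10)$;
markers at LOD ≥ 3.0 are reported (for a single marker,
$\mathrm{LRT} = 2\ln(10)\,\mathrm{LOD}$, so LOD 3 sits near a $\chi^2_1$
tail probability of 2e-4).  Reported effects are the EB posterior means,
which are shrunken relative to the stage-1 marginal effects — a property
the tests check on null markers.

Loci are merged by single-linkage chaining: consecutive hits at most
20 kb apart on one chromosome are one locus, represented by the
best-scoring member.  Chaining makes merging idempotent and
order-invariant.

## QTN intersection and gene windows

A locus becomes a QTN when a locus within the merge distance exists in
every model of at least one required set — all six single-locus models,
or the multi-locus set.  Because this package implements one
representative multi-locus model, the multi-locus required set has a
single member, so any LOD-significant locus qualifies on that route;
occasional extra QTNs at the multi-locus null rate are the accepted
consequence.  Cross-model matching reuses the 20 kb chaining distance so
there is a single distance semantics throughout.  Genes qualify for a
QTN window by overlap (not containment) with ±500 kb, boundaries
inclusive — the permissive standard reading.

## Co-expression analysis

Genes zero in strictly more than 70% of samples are dropped.  Outlier
samples are flagged by average-linkage clustering of Euclidean profile
distances when their leaf merge height exceeds median + 8 MAD; 8 (not a
smaller multiplier) is calibrated so homogeneous data are essentially
never flagged while genuine profile outliers, whose merge heights sit
one to two orders of magnitude above the null spread, always are.
Flagging more than 20% of samples requires an explicit override.

The network is unsigned, $a_{ij} = |\mathrm{cor}|^\beta$ (a signed
variant is available).  $\beta$ is chosen as the smallest power whose
signed scale-free fit $R^2$ — the squared correlation of
$\log_{10} p(k)$ on $\log_{10} k$ over ten equal-width connectivity
bins, negated for a positive slope — reaches 0.85, else the argmax over
the grid.  The function's grid is 1–20 in half steps (half-integers
because a fractional published power like 8.5 must be reachable); the
*pipeline* default grid stops at 12, because on the few dozen genes of
a QTN-window panel the binned fit is essentially noise, its argmax
drifts to the top of the grid, and $|r|^{20}$ collapses every adjacency
below the 0.4 hub-edge cutoff.  Modules come from average-linkage
clustering of $1 - \mathrm{TOM}$ with a *static* cut at 0.995 of the
maximum merge height (branches under 5 genes go grey); a static cut
replaces the dynamic hybrid tree cut for desk-scale determinism, at the
cost of occasionally merging strongly inter-correlated planted modules —
both positively trait-correlated modules can fuse, which the integration
tests accept.  Module eigengenes are first principal components of
standardized member expression, sign-anchored to the module mean
profile; module–trait p-values use the t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ (verified against the incomplete-beta
evaluation).  Hubs are the top five members by weighted degree on the
within-module subgraph thresholded at adjacency > 0.4, ties broken by
gene id.

## SNP effects and dominance classes

The per-SNP trait contrast compares the two homozygote dosage classes
with an equal-variance t-test (heterozygotes excluded by default; a
pooling option exists), and the impact rate is
$(\mathrm{High} - \mathrm{Low})/\mathrm{Low} \times 100\%$ with "High"
the larger group mean, making the rate non-negative and invariant to
trait rescaling.  Significance is raw $p \le 0.05$, uncorrected, as the
stage is a screen rather than an inference.

ORFs are found on the provided, already-oriented mRNA: the longest
ATG-initiated, stop-terminated frame of at least 150 nt (stop included,
ties to the earliest start), verified against an exhaustive start/stop
scan.  Substitutions are classified through the standard genetic code
(synonymous / non-synonymous; stop gain or loss counts as
non-synonymous); InDels inside the ORF are frameshift when the length
difference is not a multiple of 3, in-frame (classified non-synonymous)
otherwise.

The seven dominance classes place the heterozygote mean against the
favorable homozygote mean, the unfavorable one, and their midpoint.
Sample means are never exactly equal, so the equality cases (CD, AD,
NCD) are operationalized as "not significantly different" at
$\alpha = 0.05$ — a one-sample t of the heterozygote values against the
observed midpoint for AD, two-sample tests against the relevant
homozygote for CD/NCD — checked outward from the midpoint; an
exact-arithmetic mode ($\varepsilon$ = 1e-9) exists for unit tests and
grid sweeps, and singleton groups degrade to it automatically.  The
classes are exhaustive and mutually exclusive, which a fine grid sweep
asserts.

## Correlation networks against the enzyme panel

All pairwise Pearson correlations within the node set, edge kept iff
the two-sided t-transform p is at or below the threshold; constant
genes are flagged and excluded from edges; isolated nodes stay listed.
"Confirmed" candidates keep at least one edge to an enzyme-panel gene
at p ≤ 0.05; "key" candidates still do at p ≤ 1e-6 — edge-connectivity
is the minimal operationalization of a "tight" network, chosen over any
denser criterion to keep the call reproducible.  The High/Mid/Low
comparison ranks samples by trait (ties by sample id, deterministic),
takes the top/middle/bottom `groupSize` samples, builds one network per
group, and reports node counts under both conventions (with and
without isolated nodes), edge counts, and per-group unique genes and
edges.

## The synthetic generator

The generator emulates the data *structure* the funnel assumes, at desk
scale: 344 samples; 4,000 SNPs over 24 chromosomes (the published-scale
panel is one flag away, `simConfig(nSnps = 39327)`) in LD blocks of 20
markers at 25 kb spacing; two subpopulations at Balding–Nichols
divergence 0.05; two planted additive QTNs (PVE 0.20 and 0.15)
mid-chromosome on chromosomes 3 and 17; a trait with mean 0.632 mg/g
and CV 55.77% measured in three replicates (non-negative by clipping at
zero — the published SD and CV are mutually inconsistent, so the
generator targets the CV); 2,400 genes tiled uniformly; three planted
expression modules (sizes 10/26/15, factor–trait correlations
0.85/0.60/−0.50, echoing a 5–26 module-size range with a 10-gene key
module) seeded inside the QTN windows so the association and
co-expression funnels converge on the same genes by construction; a
15-transcript key-enzyme panel driven by the strongest module's factor;
and one known ORF per gene so every variant's consequence class is
analytic truth.

Within an LD block the two gamete indicators per sample come from
thresholding exchangeably correlated latent Gaussians (a Gaussian
copula rather than a coalescent — controllable $r^2$, no external
simulator), and the block shares one ancestral allele frequency: with
per-SNP frequencies the phi-coefficient bound for unequal margins caps
attainable dosage correlation well below what tight LD requires.
Non-negative expression uses an exponential link on the latent scale
with slope 0.3, mild enough that Pearson correlations are essentially
preserved.  Module genes carry latent noise SD 0.25 (within-module
correlations near 0.94) — tight modules are required for any hub edge
to clear the 0.4 adjacency cutoff at realistic soft powers, as they
evidently did in the study data.  Gene extents are 2× the marker
spacing so each gene carries a realistic number of variants from the
deliberately thinned panel, and the single ORF spans the gene so most
in-gene variants are classifiable.

What the generator does **not** emulate: recombination-map realism,
allele-frequency spectra beyond uniform-by-block, expression
count-noise (values are log-normal-like, not negative binomial),
genotype missingness (available in the containers but not planted), or
any sequence homology.  Passing tests therefore demonstrate that the
machinery recovers planted structure under idealized noise — not that
it would produce the same candidate lists on real field data.

Determinism: every stage seeds base R's Mersenne-Twister at
`seed + stage offset` (genotypes 0, trait 1, expression 2, gene models
3), so stages are individually reproducible and a full pipeline run is
byte-identical under a fixed seed — asserted in the test suite by
hashing stage outputs.

## Problem sizes in the test and acceptance runs

The suites exercise the stages at sizes chosen for tight feedback:
toy fixtures (3–12 samples) for the closed-form oracles; 100–200
samples and a few hundred markers for the calibration suites (type-I
error pooled over 20 seeds, genomic control under two-subpopulation
structure); the full default 344 × 4,000 for planted-QTN recovery over
20 seeds; 100-sample, 45-gene panels for module recovery (ARI against
planted truth); and 120 × 600 × 150 for the end-to-end funnel tests.
`scripts/acceptance.R` additionally runs one full default-scale
pipeline.

## Known limitations

* One multi-locus model represents a five-model family; intersection
  on the multi-locus route is correspondingly weaker.
* The static tree cut can fuse correlated planted modules; the key
  module is then the fused one.
* The ORF search is forward-strand only, on the provided transcript.
* The equality tolerance of the dominance taxonomy is a modeling
  choice ($\alpha = 0.05$); the class boundaries CD/AD/NCD are
  test-dependent by construction.
* InDel dosages are treated like SNP dosages everywhere except
  consequence classification.
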