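---
title: "Methods: signature reversal screening, enrichment and synergy"
author: "sigrev authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reversal screening, enrichment and synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

# Scope and rationale

`sigrev` implements the in-silico arm of a tumor drug-repurposing study
as a reusable, testable pipeline. The motivating setting is an aggressive
pediatric brain tumor (pineoblastoma) modelled in mice: tumor-versus-normal
expression contrasts define disease signatures, a library of drug
perturbation profiles (Connectivity-Map style) is screened for drugs whose
transcriptional effect *reverses* those signatures, enrichment analyses
characterize the tumors and cluster them against human cohorts, and
candidate drug pairs are evaluated for synergy in dose-response assays.
Because the original microarray cohorts and the commercial perturbation
library are not redistributable, every stage is validated against a
synthetic-data module that plants known ground truth.

# Differential expression and signatures

## Model

For each gene $g$ a two-group linear model is fit by ordinary least
squares: the reported log fold change is the difference of group means
(contrast $A - B$), with pooled residual variance $s_g^2$ on
$d = n_A + n_B - 2$ degrees of freedom.

Variances are then moderated by the classical empirical-Bayes hierarchy
for gene variances: $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$
with the conjugate scaled-inverse-chi-square prior
$\sigma_g^2 \sim d_0 s_0^2 / \chi^2_{d_0}$. The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

shrinks each gene toward the ensemble prior, and the moderated
$t_g = \widehat{\Delta}_g / (\tilde s_g \sqrt{1/n_A + 1/n_B})$ is referred
to a t distribution on $d + d_0$ degrees of freedom (capped at the pooled
residual degrees of freedom of the ensemble). Hyperparameters come from
closed-form moment matching on $\log s^2$: with constant $d$,

$$\mathrm{E}[\log s^2] = \log s_0^2 + \psi(d/2) - \log(d/2)
  - \psi(d_0/2) + \log(d_0/2), \qquad
  \mathrm{Var}[\log s^2] = \psi'(d/2) + \psi'(d_0/2),$$

so $d_0$ solves a trigamma equation, inverted by Newton iteration to
tolerance $10^{-8}$.

## Numerical conventions

* If the observed spread of $\log s^2$ does not exceed the sampling
  variance $\psi'(d/2)$, $d_0 = \infty$ and $s_0^2$ is the arithmetic
  mean of the sample variances. This makes moderation an exact no-op on
  $t$ for an equal-variance ensemble (only the degrees of freedom
  change), and matches the behaviour of the standard implementation of
  this estimator, against which the package is cross-checked in the test
  suite.
* Exact zero variances are offset to $10^{-5}$ times the median variance
  for the log-moment fit; an all-zero ensemble degenerates to
  $d_0 = \infty$, $s_0^2 = 0$ with infinite t on any non-zero fold
  change.
* Multiple testing uses Benjamini–Hochberg step-up FDR.

## Signature extraction

A disease signature of size $n$ takes the $n/2$ most positive and $n/2$
most negative genes by moderated t among genes with $q < 0.01$ (strict
threshold). Supported sizes follow the screening design (100, 200, 300,
500). Ranking is by the t statistic rather than fold change or p-value:
the statistic the pipeline computes and moderates is the natural ordering
criterion, and the choice is recorded here because the selection rule
among "equal numbers of significant up- and down-regulated genes" is
otherwise underdetermined. Ties in t break lexicographically by gene id,
so signatures are deterministic. If either direction lacks $n/2$
significant genes the constructor errors with the attainable maximum —
an undersized signature would silently change the screen's null
behaviour.

Classifier gene lists (e.g. the 75- and 95-gene lists used for
cross-species tumor comparison) take the top $n$ genes by $|t|$ with
recorded direction; balance is deliberately not enforced. Projection
z-scores each classifier gene across samples and scores a sample by the
mean z of A-up genes minus the mean z of B-up genes, making calls by
sign; the score is invariant to per-gene affine rescaling.

# Connectivity scoring

## Two-set KS score

The drug's genes are ranked by its signed statistic, descending. For the
signature's up and down sets separately, the unweighted
Kolmogorov–Smirnov running sum rises by $1/k$ at set members and falls by
$1/(N-k)$ elsewhere; the enrichment score is the extremum of largest
magnitude. The connectivity score follows the classical Connectivity-Map
convention:

$$s = \begin{cases}(ES_{up} - ES_{down})/2 & \text{if } ES_{up}, ES_{down}
\text{ have opposite signs}\\ 0 & \text{otherwise.}\end{cases}$$

A drug mimicking the disease scores $+1$; a perfect reverser scores
$-1$; discordant profiles score 0. Hits are drugs below $-0.5$ by *both*
scoring methods, the screen's published filter.

Two numerical points matter. First, for the unweighted statistic the
running sum takes exact rational values with denominator $k(N-k)$, so the
implementation evaluates it in integer numerators; magnitude comparisons
between the positive and negative extremum are then exact. Second, an
exact magnitude tie between the two extrema leaves the sign of the ES
genuinely ambiguous; `sigrev` reports 0 in that case, the only convention
under which the score is exactly antisymmetric under profile negation
(any fixed-sign tie-break produces scores that do not negate when the
ranking is reversed). The weighted running statistic
($|stat|^p$ increments, exponent `p` exposed as a switch, default
unweighted) uses the same rule with a $10^{-12}$ relative tolerance.

## Genome-wide weighted Spearman (GWC)

Over the shared gene universe, both statistic vectors are converted to
average ranks and correlated with per-gene weights

$$w_i = \tfrac12\left(-\log_{10} p^{dis}_i - \log_{10} p^{drug}_i\right),$$

rescaled to mean 1. With all p-values equal the score reduces exactly to
Spearman's rank correlation (verified against the closed form to
$10^{-12}$). The weight combines both sides' significance so that genes
confidently measured in *both* the disease contrast and the drug profile
dominate; the arithmetic mean is the simplest symmetric combination and
is recorded here because the published description of the method does
not fix the formula. GWC is genome-wide by construction, so in the
multi-size screen it is computed once per drug and repeated across the
per-size rows; only the KS score varies with signature size.

## Permutation significance

P-values permute the gene labels of the drug profile (statistics and
p-values jointly), keeping the signature fixed:
$p = (1 + \#\{|s^{perm}| \ge |s^{obs}|\})/(n_{perm}+1)$, two-sided with
+1 smoothing, so the smallest attainable p is $1/(n_{perm}+1)$ and no
p-value is ever exactly 0. The default is 1000 permutations. Inside the
screen the unweighted KS null depends only on $(N, k_{up}, k_{down})$,
not on the profile, so one null ensemble per signature size serves all
drugs — a pure speed optimization with identical distribution. GWC
permutations are drug-specific because the weights travel with the
profile.

Calibration checks use the GWC score: the two-set KS score places a point
mass at 0 (whenever the two enrichment scores share a sign), so its
two-sided permutation p is conservative by construction and cannot be
uniform under the null; the GWC score is continuous and its null p-values
are uniform, which the test suite verifies by a Kolmogorov–Smirnov test
across 50 noise drugs.

## Ortholog mapping

Cross-species screening translates gene ids through a source→target map.
Unmapped genes are dropped with a logged count; when several sources
collide on one target the source with the largest absolute statistic
wins, and a source mapping to several targets keeps the
lexicographically smallest target — both rules chosen for determinism.
Fewer than 50% mappable genes is an error rather than a silent loss of
power.

# Enrichment analyses

## PreRanked GSEA

The weighted running-sum ES (exponent 1 by default, 0 supported) is
normalized by the mean magnitude of same-sign permutation-null scores to
give NES; nominal p-values are two-sided with +1 smoothing. Nulls permute
gene labels of the ranking — PreRanked mode has no phenotype labels to
permute, so gene permutation is the only null available without raw
arrays, and this choice is recorded as such. FDR follows the
sign-stratified ratio convention: for a set with given NES, the smoothed
fraction of pooled same-sign null NES at least as extreme is divided by
the fraction of observed same-sign NES at least as extreme, clamped to
$(0, 1]$. Because of the smoothing, a reported FDR is never exactly 0.

## ssGSEA

Per sample, genes are ranked by expression (largest value gets rank $N$;
value ties break by gene id), and the score is the summed difference
between the weighted in-set ECDF (weights $rank^\alpha$, $\alpha = 0.25$,
the canonical published exponent) and the unweighted out-of-set ECDF.
Only within-sample ranks enter, so the score is invariant under any
strictly monotone per-sample transform — log-scale and linear-scale
expression give identical scores. Matrix-level normalization by the
global score range is an on/off switch (default on); downstream rank
assembly is invariant to it, so the choice is cosmetic but documented.

## Rank matrix and PCA

Per gene set, samples are ranked by ssGSEA score (average ranks on
ties). The samples-by-sets rank matrix is column-centered (no scaling —
ranks are already commensurate) and decomposed by SVD; the embedding is
the projection onto the top-$k$ right singular directions ($k = 3$ by
default, matching the 3-D visualization the design targets), with each
component's sign fixed so its largest-magnitude loading is positive.
Explained-variance fractions are $d_i^2 / \sum d^2$.

# Synergy analysis

Viability readings convert to fraction affected
$f_a = 1 - \mathrm{OD}_{treated}/\overline{\mathrm{OD}}_{control}$,
clipped into $(10^{-4}, 1 - 10^{-4})$ so the logit stays finite;
replicates average per dose. The median-effect model
$f_a/(1-f_a) = (D/D_m)^m$ linearizes to
$\log_{10}(f_a/(1-f_a)) = m \log_{10} D - m \log_{10} D_m$ and is fit by
least squares; $D_m$ is the IC50 and $r$ the correlation of the
linearized regression. Readouts sitting at the clipping bounds are
excluded before the fit (with a message): a clipped well carries no
quantitative effect information, and on the logit scale it becomes a
high-leverage outlier that visibly biases $D_m$ — with the exclusion,
noisy 8-point curves (noise sd 0.02 on the $f_a$ scale) recover $D_m$
with a median relative error of about 5%.

The combination index at an observed effect level is the mutually
exclusive (two-term) form

$$CI = \frac{d_1}{D_{x,A}(f_a)} + \frac{d_2}{D_{x,B}(f_a)},
\qquad D_x(f_a) = D_m \left(\frac{f_a}{1-f_a}\right)^{1/m},$$

the classical default; the non-exclusive three-term variant is available
behind a flag. $f_a$ comes from the observed combination wells by
default (a fitted-combination option exists), because the alternative
conventions cannot be distinguished from the published analysis.
Classification uses the study's bands — CI < 0.85 synergistic,
0.9–1.0 additive, > 1.1 antagonistic — with the gaps
$[0.85, 0.9)$ and $(1.0, 1.1]$ labelled *borderline* rather than forced
into a class, since the quoted bands are non-exhaustive.

The combination generator inverts this machinery: for each dose pair it
solves $d_1/D_{x,A}(f_a) + d_2/D_{x,B}(f_a) = \kappa$ for $f_a$ by
monotone root finding (the left side decreases from $+\infty$ to 0 on
$f_a \in (0,1)$, so the root is unique; tolerance $10^{-12}$). Under
Loewe additivity $\kappa = 1$ and recomputing CI returns 1 to within
$10^{-6}$; generating with $\kappa = 0.5$ returns CI = 0.5, classified
synergistic. With one dose zero the generator reduces exactly to the
single-drug curve.

# The synthetic-data module

The generators define the study conditions under which the pipeline is
validated:

* **Expression**: gene baselines $\mathcal{N}(8, 1.5^2)$ in log2 units
  (typical microarray dynamic range), iid within-group noise
  (sd 0.5), two groups of 5 samples, 2000 genes, 200 planted
  differential genes shifted by $\pm 2$ log2 units (half up, half down;
  an odd count rounds the extra gene up). These are the default
  conditions for the screening tests; clustering tests use 1000 genes,
  6 + 6 samples and 150 planted genes, sizes chosen to keep the full
  suite fast while leaving the planted structure unambiguous.
* **Perturbation library**: reverser profiles are
  $-\rho \cdot t^{dis} + \varepsilon$, null profiles pure noise
  ($\varepsilon \sim \mathcal{N}(0, 1)$ in statistic units), 200 drugs
  with 5 reversers at $\rho = 0.8$ in the recovery tests. Per-gene
  p-values derive from the normal z-scores of each profile — the GWC
  statistic needs drug-side significance weights.
* **Gene sets**: random sets plus coherent sets drawing 80% of their
  members from planted up- or down-genes, alternating direction, with
  composition recorded.
* **Dose-response**: median-effect curves with known $(D_m, m)$ plus
  Gaussian noise on the $f_a$ scale, clipped as above.

Identical seeds reproduce every artifact bit-exactly; the pipeline
derives one seed per stage from the master seed through a polynomial
hash, so stages are reproducible independently.

What the generators deliberately do **not** emulate: probe-level array
structure and normalization (the pipeline starts from gene-level log2
values), batch effects, correlated gene-gene noise, dose-dependent
perturbation profiles, and plate-layout artifacts in viability data.
Passing tests therefore demonstrate the correctness and calibration of
the statistical machinery under clean planted-truth conditions, not
robustness to the technical artifacts of real cohorts.

With 200 planted differential genes, roughly 100 genes per direction
reach $q < 0.01$, so under the default conditions the 100- and 200-gene
signatures are constructible while 300- and 500-gene signatures
correctly error; the screen skips such sizes with a warning, and tests
exercising the larger sizes plant 600 differential genes.

# Known limitations

* The classifier builder emulates a portal-style "top differential
  genes" list; the exact criteria behind published 75/95-gene lists are
  not recoverable, so only the construction rule, not the gene
  identities, is reproducible.
* The hit filter is applied per signature size, with a cross-size
  consensus reported additionally; whether the published −0.5 filter was
  per-size or consensus is not stated.
* The GSEA FDR convention (sign-stratified pooled-null ratio) matches
  the de facto standard but other implementations differ in smoothing
  details; reported q-values are comparable, not bit-identical, across
  tools.
* Empirical-Bayes log-odds (B) is not computed: it requires a prior on
  the coefficient variance outside the moment-matching procedure used
  here; the column is carried as `NA` for interface compatibility.
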