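---
title: "Linking chemical descriptors to genome-wide drug response: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chemical descriptors to genome-wide drug response: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccalink)
```

## The problem

A drug rarely acts through a single target. When a library of compounds is
profiled on cell lines at genome-wide scale, the response of the
transcriptome to each compound is a high-dimensional readout of everything
the molecule does. `ccalink` asks a symmetric question: which *patterns* of
chemical structure, as encoded in a numeric descriptor table, co-occur with
which *patterns* of biological response, as encoded in gene-set activation
profiles? The tool of choice is regularized canonical correlation analysis
(rCCA), which extracts paired directions — one in descriptor space, one in
activation space — whose compound scores are maximally correlated.

The package implements the full path from raw batch-structured expression
profiles to characterized components, and ships synthetic-data generators
with planted ground truth so that every stage is testable without any
external data resource.

## Preprocessing expression batches

Expression compendia are organized in batches with a handful of vehicle
controls and many treatments. Three rules reduce them to one response
vector per compound:

1. **Control consolidation.** With three or more controls, the control
   with the largest *summed* Euclidean distance to the other controls is
   removed as an outlier and the rest are averaged. With one or two
   controls, the plain mean is used — with only two, "the other controls"
   is a single profile and outlier removal is ill-posed. At most one
   control is ever removed. The sum over pairwise distances was chosen as
   the aggregator because it is deterministic and robust; any monotone
   aggregator agrees on the dominant, all-gene-shifted outliers this rule
   exists to catch.
2. **Differential expression** is the difference of log2-scale treatment
   and consolidated-control profiles. (Whether a difference or a test
   statistic is intended is genuinely open for this kind of pipeline; the
   difference of already-normalized log2 values is the assumption here.)
3. **Control-variance filter.** The `ceiling(fraction * n_genes)` genes
   (default fraction 0.05) with the largest variance across the *pooled*
   control profiles are discarded: variation in untreated material is
   chemistry-independent noise. Pooling across batches, rather than
   per-batch variances, maximizes that interpretation. Variance ties at
   the cutoff are broken by gene id so the filter is deterministic.
4. **Strongest instance.** When a compound was profiled several times
   (cell lines, concentrations), the instance with the largest response
   norm is kept; exact ties go to the lexicographically smallest instance
   id.

## Signed gene-set activation

Gene-level responses are converted to the biological space by gene-set
enrichment. For each compound, genes are ranked by response and each set
receives a weighted running-sum enrichment score (weight `|response|`,
score = most extreme deviation between the weighted cumulative hit
fraction and the cumulative miss fraction). The null is gene-label
permutation, shared across sets of equal size; scores are normalized by
the mean null magnitude of their own sign (NES), and FDR q-values come
from the pooled permutation null of the NES. The scorer's exact ES agrees
with the independent `fgsea` implementation to machine precision on
shared inputs; permutation count and the weighting exponent are
documented defaults (`n_perm = 200`, exponent 1), not claims about any
external tool's settings. Precomputed `(set, es, q)` tables can be fed to
`build_activation_matrix()` to bypass the internal scorer entirely.

The activation value is `sign(ES) * (1 - q)`: 0 means no evidence of
coordinated movement, +1/-1 mean maximal positive/negative activation.
This keeps the biological space bounded in `[-1, 1]`, roughly unimodal
around zero, and sign-interpretable. An ES of exactly 0 is assigned the
positive sign (an arbitrary but deterministic convention).

## Regularized CCA

With `X` (n compounds x p descriptors, columns standardized by default)
and `Y` (n x q activations, centered only — they are already bounded),
the model maximizes the penalized correlation

$$\frac{w' C_{xy} v}
       {\sqrt{(w' C_{xx} w + \lambda_1 \lVert w\rVert^2)\,
              (v' C_{yy} v + \lambda_2 \lVert v\rVert^2)}}$$

where the `C` are feature-space covariances `X'X/(n-1)` etc. The solution
is computed as the singular value decomposition of the whitened
cross-covariance
$(C_{xx}+\lambda_1 I)^{-1/2}\, C_{xy}\, (C_{yy}+\lambda_2 I)^{-1/2}$;
the left/right singular vectors give both weight sets with consistent
pairing, and successive components are uncorrelated in the regularized
metric. This is numerically preferable to back-solving the second view's
weights from the first (`v = (C_{yy}+\lambda_2 I)^{-1} C_{yx} w`), which
inherits cross-covariance sampling noise of order $\sqrt{q/n}/\rho$ — in
simulations at n = 500 the back-solve route misestimated the biological
weight subspace by ~23 degrees where the SVD route achieved ~5.

Conventions:

* Training variates are rescaled to unit sample variance, matching the
  classical constraint var(Xw) = var(Yv) = 1.
* `correlations` holds the *sample correlation* of each variate pair —
  the quantity the model maximizes when the penalties vanish, and what
  ordering, permutation testing and reports use. The penalized singular
  values (which shrink under ridge) are kept in `penalized`; they are
  also what the independent `mixOmics::rcc` implementation reports, which
  the test suite uses as a cross-check.
* CCA signs are arbitrary, so each component is flipped to make the
  largest-magnitude chemical weight positive; the A/B subcomponent labels
  are therefore deterministic.
* At `l = 0` on well-conditioned data the fit matches `stats::cancor` to
  1e-8; with `p >= n` and no ridge the regularized covariance is
  reported as singular with advice to increase the penalty.

### Choosing the penalties

`select_regularization()` scores a grid of `(l1, l2)` pairs by k-fold
cross-validation (default 20 folds): fit on the training folds, project
everything, and compute mean average precision of retrieving functionally
similar compounds — using held-out compounds as queries — in the *fused*
component space (chemical and biological variates concatenated). The
fused space is the package's reading of "retrieval performance" for model
selection: it is the representation the pipeline ultimately reports, and
scoring it directly keeps selection aligned with the downstream use. Ties
prefer the smaller `l1`, then the smaller `l2`.

The useful scale of a ridge penalty is relative to its view's column
variances. Standardized descriptors have unit variance, while bounded
activations typically have variance below 0.05, so well-chosen penalties
are asymmetric by orders of magnitude: expect a large chemical-side and
a tiny biological-side penalty whenever the biological view is a bounded
activation matrix.

### Permutation significance

Component significance breaks the compound correspondence by permuting
the rows of `Y`, refitting with the *same* penalties (the test statistic
is held fixed; re-running CV inside the null would test a different
procedure), and comparing each component's correlation with its null
distribution. The estimator adds the +1 correction,
`p = (1 + #{null >= observed}) / (n_perm + 1)`, so a valid test never
reports exactly zero; the uncorrected proportion is reported alongside.
Under independence the type-I error at 5% is calibrated (checked over 200
null studies in the test suite). Components retained for reporting have
`p < 0.05`, capped at the top 10 by correlation.

### Subcomponents

Each component splits into subcomponent **A** (compounds with positive
canonical score) and **B** (negative); exact zeros belong to neither, and
a global sign flip exactly swaps the two sides. Which side's score to use
is open in principle; the default is the mean of the chemical and
biological variates, a symmetric choice exposed as the `side` argument.

## Retrieval validation

Functional similarity is validated by ranking: every annotated compound
queries the others, ranked by Pearson correlation of their representation
vectors (a scale-free choice usable across spaces of very different
dimension; ties broken by compound id), and retrieval of compounds
sharing at least one label is scored by average precision at depths 5 to
100. `AP@k` averages precision over the relevant items found in the top
k, and is 0 when none is found. Queries must have at least one label
shared with another compound; zero-variance rows get similarity 0 and are
flagged.

`random_baseline_map()` gives the exact expected `AP@k` of a uniformly
random ranking (hypergeometric hit count, uniform hit positions). This
exceeds the naive mean-relevant-fraction at small depths — AP is only
evaluated at ranks that hold a relevant item — and the exact form is what
null-alignment comparisons should use; the approximation error of the
naive baseline is around +0.1 at depth 10 on small pools, larger than
the effects being tested.

`compare_spaces()` assembles curves for the fused CCA space, the raw
descriptor space, the activation space, and the gene space. In the
synthetic studies with label structure aligned to the shared latent
signal, the fused space dominates both single spaces at every depth in at
least 90% of seeded runs, and with alignment 0 every curve sits at the
random baseline.

## Component characterization

* **Top gene sets**: sets ranked by |Pearson correlation| between their
  activation column and the component's biological variate ("association
  with the component"); the signed value is reported. The association
  measure is not canonical — correlation with the biological variate was
  chosen because the variate is the component's biological coordinate.
* **Top compounds**: per side, ranked by |canonical score|, default 20.
* **Significant genes**: candidates are the union of genes in the top 20
  positively and top 20 negatively associated sets; their responses
  across the subcomponent's top 10 compounds (per side) are tested with
  the moderated t-test below; genes with raw p < 0.05 are reported, the
  top 30 by p flagged for export. No multiplicity correction is applied
  at this step by design — the threshold is a screening rule feeding the
  enrichment stage, not an inferential claim.
* **Moderated t-test**: one-sample test of mean zero with
  `s2_tilde = (d0 * bg + (n-1) * s2) / (d0 + n - 1)` and
  `df = d0 + n - 1`, where the background variance `bg` is pooled from a
  sliding window of 101 genes ordered by mean response. At `d0 = 0` this
  is *exactly* Student's t; under the hierarchical model (gene variances
  drawn from a scaled inverse chi-squared prior with `d0` degrees of
  freedom and scale `bg`) the statistic is exactly t-distributed, which
  is how the calibration test is constructed. The `d0 + n - 2`
  denominator variant seen in some formulations does not reproduce
  Student's t in the zero-prior limit and was not used.
* **Term enrichment**: hypergeometric upper-tail p of the overlap between
  the significant-gene list and each term of a generic term collection
  (a stand-in for ontology categories; the real ontology graph is out of
  scope). Raw p-values, ranked ascending.
* **Target enrichment**: the number of targets annotated to at least two
  compounds of a top-20 list, compared with 1000 random draws of the same
  size from the annotated pool (`p` with the +1 correction). "Target
  sharing" is ambiguous between counting shared targets and counting
  sharing pairs; both statistics are implemented
  (`statistic = "targets_shared"` is the default, `"pairs_sharing"` the
  alternative), neither claimed canonical.
* **Component-pair similarity**: biological similarity is the Tanimoto
  overlap of top-30 gene lists, compound similarity the overlap of
  top-20 compound lists — the contrast that exposes component pairs
  sharing compounds while driving disjoint gene programs.

## The synthetic-data generators

`simulate_joint_data()` draws, per component s, a common mechanism factor
z_s observed noisily in both spaces (u_s chemically, t_s biologically)
with corr(u_s, t_s) equal to the planted value; loadings map the latents
into the observed features and isotropic noise is added. Three design
points matter:

* **Calibration.** The planted correlations are the *population canonical
  correlations of the emitted data*. Additive feature noise attenuates
  the latent correlation by `1/(1 + noise_sd^2)` (exactly, for
  orthonormal loadings), so the generator inflates the latent correlation
  by `1 + noise_sd^2` to cancel it. Classical CCA on a large sample
  (n = 5000) recovers planted values 0.9/0.6 within ±0.03.
* **Loadings** are QR-orthonormalized random-sign matrices: orthonormal
  (making the attenuation compensation exact and the planted weight
  subspace well-defined) with near-equal row norms, so all activation
  columns have comparable variance and the bounded squash treats them
  uniformly.
* **The bounded squash.** Activations are mapped into `(-1, 1)` by the
  error-function-style map `2 * pnorm(y / s) - 1` with per-column scale
  `s = 6 * sd`. The scale matters: a harsher squash (3 sd) injects a
  structured nonlinear residual, correlated across columns through the
  shared latents, that measurably tilts the recovered biological weight
  subspace (~29 vs ~12 degrees at n = 500 in the design experiments).

The default `noise_sd = 0.1` describes a high signal-to-noise regime —
descriptor tables are near-deterministic functions of structure — and is
the regime in which the recovery study (n = 500, p = 15, q = 20, planted
0.9/0.7/0.5, ridge 0.2/0.05 on the unstandardized fit) reproduces planted
correlations to ±0.05 on seed average and weight subspaces to under 15
degrees. Recovery statistics are reported as means over 20 seeds: the
sampling standard deviation of a single sample canonical correlation at
rho = 0.5, n = 500 is ~0.034, so per-seed bounds of ±0.05 would fail for
an oracle measuring the true latent correlation.

Optional space-specific confounder factors (`n_confounders`) add
structured variation to each space independently — descriptor families
without biological consequence, responses unrelated to chemistry. They
are what makes the retrieval comparison interesting: with only isotropic
noise, a high-dimensional raw space averages its noise away and the fused
space has little room to win; with structured irrelevant variation, CCA's
filtering is visible and the fused space dominates. The four-space
benchmark uses n = 200 compounds, p = 60 descriptors, q = 80 sets, 8
components (0.9 down to 0.55), noise 0.3, 8 confounders per space, 10
labels at alignment 0.9.

`simulate_expression_batches()` emulates the batch structure (log2
baselines, control replicates, planted per-compound gene-set effects,
optionally one control shifted on all genes — a shift that provably
maximizes the distance sum, so the outlier-flagging test is
deterministic). Weaker replicate instances make strongest-instance
selection verifiable. `simulate_shared_compound_data()` constructs the
two-component benchmark with an overlapping compound group but disjoint
gene blocks; anti-correlated extreme groups cancel the latent correlation
the shared group induces (uncorrelated CCA variates cannot align with
correlated planted components), and component-specific specialists
outrank the shared group so the differential-expression lists stay
component-pure while the top-20 lists still overlap.

What the generators do **not** emulate: probe-level microarray artifacts
and normalization, realistic gene-gene correlation beyond the planted
low-rank structure, compound-concentration series, annotation sparsity
patterns of real target databases, or any chemistry. Passing tests
demonstrate the statistical machinery — identifiability, calibration,
ordering of representations under known structure — not biological
validity on real compendia.

## Parameters at a glance

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `fraction` | 0.05 | variance filter | fraction of genes discarded by control variance |
| `n_perm` (enrichment) | 200 | `enrichment_scores` | gene-label permutations per profile |
| `exponent` | 1 | `enrichment_scores` | running-sum weight on \|response\| |
| `l1`, `l2` | data-driven | `select_regularization` | ridge penalties, CV over a grid |
| `folds` | 20 | `select_regularization` | CV folds |
| `n_perm` (significance) | 1000 | `permutation_significance` | row permutations of Y |
| `p_threshold` | 0.05 | `retained_components` | permutation significance cutoff |
| `max_components` | 10 | `retained_components` | cap on reported components |
| `ks` | 5..100 by 5 | `map_curve` | retrieval depths |
| `k_compounds` | 20 | reports | top compounds per subcomponent |
| `k_sets` | 10 | reports | top gene sets per component |
| `n_compounds` | 10 | DE test | compounds entering the moderated t |
| `prior_df` | 10 | moderated t | prior degrees of freedom |
| `window` | 101 | moderated t | background-variance pooling window |
| `n_draws` | 1000 | target enrichment | resampled compound lists |

## Problem sizes in the test suite

The suite runs the statistical checks at deliberately modest sizes chosen
so the whole suite completes in about a minute while keeping Monte-Carlo
error well inside the asserted tolerances: oracle equivalence at n = 50,
recovery at n = 500 over 20 seeds, permutation calibration over 200 null
studies with 199 permutations each, retrieval comparison over 20 studies
of 200 compounds, and the moderated-t calibration at 10^4 genes. The
pipeline demo (`run_pipeline()` with no input paths) uses 60 compounds,
150 genes and 25 gene sets end to end.

## Known limitations

* The enrichment scorer is a documented simplification: gene-permutation
  nulls only (no phenotype permutation), and no exact numeric agreement
  with any external GSEA tool is claimed beyond the ES statistic itself.
* rCCA weights for `p` close to `n` are stabilized by ridge but remain
  high-variance; weight-level interpretation should use the retained,
  significant components only.
* The moderated t-test's exact calibration holds under its hierarchical
  variance model; on arbitrary (e.g. equal-variance) nulls any finite
  prior makes it mildly conservative in the tails.
* Average precision follows the hits-within-k convention; items relevant
  but beyond the depth do not enter the denominator.
* The pipeline's file-based mode consumes already-normalized matrices;
  normalization, probe mapping and cross-platform harmonization are out
  of scope.
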