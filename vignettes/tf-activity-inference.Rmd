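---
title: "Inferring transcription factor activities from multi-ecotype heat-stress expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription factor activities from multi-ecotype heat-stress expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatnca)
```

## The problem

Transcription factor (TF) activity is the quantity cells actually
regulate — post-translational modification, localisation and cofactor
binding all change a TF's effect without changing its transcript
abundance. Arrays and sequencing measure transcript abundance only, so
TF activity must be inferred. This package implements that inference
for a specific experimental design: several natural accessions
(ecotypes) of a plant, each profiled in replicated control and
heat-stressed arrays, on log2-scale normalised expression values.

The analysis runs in three stages:

1. **Differential expression** per ecotype (heat vs control t-tests)
   plus a genotype-by-treatment interaction ANOVA, assembled into a
   unified cross-ecotype list with per-ecotype "unique" membership.
2. **Network construction**: a signed bipartite TF-to-target network
   built by thresholding expression-profile correlations.
3. **Network Component Analysis (NCA)**: the constrained decomposition
   `E = A P`, where `E` (genes x conditions) is expression, `A`
   (genes x TFs) holds control strengths whose zero pattern is fixed by
   the network, and the rows of `P` (TFs x conditions) are the hidden
   TF activities (TFAs).

A synthetic-data generator with known ground truth stands in for the
original arrays, so every stage is tested against planted truth.

## The decomposition model and its identifiability

NCA models each gene's log-expression as a weighted sum of the
activities of the TFs allowed to regulate it:

$$ E_{ij} = \sum_{l} A_{il} P_{lj} + \varepsilon_{ij}, \qquad
   A_{il} = 0 \text{ unless TF } l \text{ may regulate gene } i. $$

Unlike PCA or ICA, the factors are anchored to biology by the support
constraint. The decomposition is essentially unique — up to a per-TF
scale and sign, `A P = (A D)(D^{-1} P)` — exactly when three structural
criteria hold:

1. the connectivity pattern admits full column rank;
2. for every TF, deleting its column and the rows of its targets
   leaves a pattern that still admits full column rank on the rest;
3. there are at least as many conditions as TFs.

`check_identifiability()` evaluates the rank conditions *generically*:
the pattern is instantiated twice with random nonzeros drawn on
±[0.5, 1.5] at a fixed internal seed, and the numerical rank is taken
at tolerance `1e-8` times the largest singular value. A random
instantiation achieves the structural rank with probability one, so
this matches the combinatorial definition; the test suite verifies
exact agreement with an independent maximum-bipartite-matching oracle
on random patterns. `reduce_to_identifiable()` restores criteria 1–2
by greedily removing failing TFs, lowest degree first (lexicographic
tie-break), dropping orphaned genes along the way; it reports what it
removed and never raises.

## Fitting: alternating least squares with restarts

`fit_nca()` minimises
$\lVert E - AP\rVert_F^2 + \lambda\lVert P\rVert_F^2$ subject to the
support constraint, by exact alternating half-steps:

- **P-step**: `P = (AᵀA + λI)⁻¹ AᵀE` — all activities at once;
- **A-step**: each gene's strengths are solved over its allowed
  regulators only (genes sharing a regulator set share one
  least-squares system); minimum-norm solutions handle rank
  deficiency.

Both half-steps solve their subproblem exactly, so the recorded
objective `sqrt(||E - AP||² + λ||P||²)` is non-increasing — an
invariant the tests assert. Note the *plain* residual need not be
monotone when `λ > 0`; the trace deliberately records the quantity
actually minimised (they coincide at `λ = 0`). Iteration stops when
the relative objective change drops below `tol` (default `1e-6`) or
when the objective falls below `tol · ||E||`, i.e. the reconstruction
is exact to numerical noise; `max_iter` defaults to 500.

The joint objective is nonconvex and ALS can stall in local optima.
We observed this concretely: one unlucky initialisation on a routine
60-gene/5-TF noisy instance produced a residual ratio of 0.34 and one
activity correlation of 0.47 where the other starts reached the noise
floor. `fit_nca()` therefore runs `n_starts = 3` random
initialisations (nonzeros on ±[0.5, 1.5], seeds derived from `seed`)
and keeps the best final objective, skipping remaining starts once one
reaches an essentially exact reconstruction. When the pattern carries
edge signs, the first start is the sign-anchored initialisation
(`A₀ = sign pattern`), which also fixes the reported sign convention.

**Under-determined instances.** A 35-TF network observed over 10
ecotype fold-change conditions violates criterion 3: the P-step's
normal matrix is singular and the activities are not unique. Rather
than refuse, `fit_nca()` applies a Tikhonov ridge
(`1e-3 ·` mean diagonal of `AᵀA` at initialisation) to the P-step and
warns prominently. The returned activities are then the
minimum-energy representative of a solution family — usable for
qualitative comparison across conditions, but not unique estimates,
and the warning says so. Because convergence of the ridged problem is
slow in its flat directions, a looser `tol` (e.g. `1e-4`) is the
practical choice at this scale; the shape-level full-scale check in
the test suite uses exactly that.

**Conventions.** `normalize_model()` fixes the scale/sign ambiguity:
columns of `A` are scaled to unit Euclidean norm (inverse absorbed
into `P`), and each TF's sign is chosen to agree maximally with the
prior edge signs when available, else so the first nonzero control
strength is positive. The reconstruction `A P` is unchanged to machine
precision (asserted to `1e-10`). All-zero columns are left alone and
flagged indeterminate. `recovery_metrics()` compares a fit against
simulated truth; since the per-TF sign is inherently unidentified, it
aligns each TF's sign to the truth (flipping the `A` column and `P`
row together) before measuring support-sign agreement.

## Differential expression

`per_ecotype_t_test()` computes per-gene two-sided two-sample tests of
heat against control replicates. The default is Welch's
unequal-variance statistic — the safer choice for 3v3 array replicates
where variance heterogeneity between arms is common; the pooled
Student variant is available via `var_equal = TRUE`. P-values are raw
by default (a Benjamini–Hochberg switch exists but is off), and calls
use `p <= alpha` with `alpha = 0.01` as the working default.
Degenerate constant probes (zero variance in both arms, equal means)
get `p = 1` by convention so they stay in the pipeline without ever
being called.

A calibration subtlety worth stating explicitly: under a
*homoscedastic* Gaussian null at n = 3 per arm, Welch's test is
conservative — its realised type-I error at nominal 0.01 is about
0.006, because the Welch–Satterthwaite degrees of freedom are
estimated from two three-point variances. This is a documented
property of the statistic, not an implementation artefact; the pooled
variant is exactly t-distributed under that null and the suite's
calibration checks use it, while a separate property test pins Welch
to the conservative side of nominal. On real arrays, where
heteroscedasticity is the rule, Welch's robustness is worth its
conservatism — hence the default.

`interaction_anova()` fits `expression ~ ecotype * treatment` per gene
and returns the interaction p-value — the test for genotype-specific
stress response. Balanced designs use a vectorised cell-means
decomposition (identical to `lm`/`aov`, verified in the tests; the
sum-of-squares type is immaterial under balance). Unbalanced but
complete designs fall back to per-gene linear models with the
interaction fitted last (for the highest-order term this equals its
Type-II test). Empty cells are an error naming the offending
(ecotype, treatment) combination.

`assemble_union()` and `summarize_counts()` build the unified
significant list and the per-ecotype total/up/down table with
ecotype-unique splits. Genes with a log2 fold change of exactly zero
carry no direction: they count in totals but in neither the up nor
down split (a measure-zero case that needs a convention so up + down
accounts for every directed call).

## Network construction

`build_signed_network()` connects a TF to a target when the absolute
Pearson correlation of their profiles meets the threshold (default
0.8), with the edge sign taken from the correlation's sign —
activation for positive, repression for negative. Thresholding |r|
rather than r is deliberate: a signed regulatory network must admit
repressions, which a one-sided threshold would silently discard.

By default the pipeline correlates *per-ecotype log2 fold-change
profiles* (one coordinate per ecotype), which ties the network to the
differential response rather than to absolute expression; correlating
raw sample profiles is available via configuration. Ten-point profiles
make |r| ≥ 0.8 a demanding but attainable bar; note that with few
conditions, sampling noise in r is substantial, which is one reason
the network is treated as a support constraint for the decomposition
rather than as a finished result. Correlation flavour is Pearson
(Spearman via argument), matching the clustering distance used
elsewhere in the package. Constant profiles have undefined correlation
and are dropped with a warning. TF–TF and self edges are excluded:
the decomposition's data model keeps the regulator and target layers
disjoint, so targets also present in the TF list are removed from the
target side first.

`degree_table()` and `hub_summary()` tabulate per-TF connection counts
and the degree distribution (sorted, brute-force-verified); no
distributional fit (e.g. a power law) is performed or claimed.

## Reporting

`classify_responsive()` standardises each TF's activity profile with a
robust z-score (centre = median, scale = MAD) and calls a condition
responsive at `|z| >= 2` by default; TFs responsive in exactly one
condition are `unique`, in several `multi`, in none `none`. The MAD is
preferred over the standard deviation so that one strongly responsive
ecotype does not inflate the scale and mask itself. When the MAD is
zero but the row is not constant (a majority of tied values — common
in short, sparse activity profiles), the scale falls back to the
standard deviation; truly constant rows are `none`. The threshold is a
reporting choice, not a hypothesis test, and is configurable.

`hierarchical_cluster()` is UPGMA (average linkage) on the correlation
distance `d = 1 - r`, the standard choice for expression-profile
heat maps; `bootstrap_support()` resamples *conditions* (columns) with
replacement, re-clusters, and reports for each internal node the
fraction of replicates in which its leaf set recurs. Columns are
resampled, not rows, because the question of interest is whether the
grouping of genes/TFs is stable across conditions. Replicates whose
resample makes some profile constant are skipped and the denominator
adjusted. Everything is seeded; identical seeds give identical
supports.

`enrichment_test()` is the one-sided hypergeometric upper-tail test of
gene-set over-representation (sets intersected with the universe
first), Bonferroni-corrected over the number of sets tested —
Bonferroni rather than FDR to match the conservative convention common
in GO over-representation tools.

## The synthetic-data generator

The generator is first-class, tested code — it defines the conditions
under which every downstream claim is verified.

`simulate_ecotype_experiment()` emulates a multi-accession two-arm
array study: per-gene baselines `N(7, 1.5)` on the log2 scale (typical
of normalised array expression indices), `n_reps` replicates per
(ecotype, treatment) cell, Gaussian replicate noise, and a planted
minority of heat responders. A responder responds in 1, 2 or 3
ecotypes with probabilities 0.85/0.10/0.05 — mirroring the strongly
ecotype-specific architecture reported for this design, where ~85% of
differential transcripts were unique to a single accession — with
effect sizes drawn `N(0, effect_sd)`. The truth object records the
labels and effects for sensitivity/specificity scoring.

`generate_connectivity()` draws a Bernoulli(density) pattern, repairs
empty rows/columns, and rejection-samples (budget 100) until criteria
1–2 pass, erroring if the density/dimension combination is infeasible.
`simulate_nca_instance()` instantiates it with control strengths
uniform on ±[0.5, 1.5] — bounded away from zero so support recovery is
well-posed — activities i.i.d. standard normal, and additive Gaussian
noise on the product.

What the generator does *not* emulate: probe-level effects,
normalisation artefacts, correlated (batch) noise, heavy-tailed
expression, and TF transcript/activity decoupling beyond the planted
layer. Passing tests therefore demonstrate correctness of the
procedures and recoverability under the stated model, not performance
on any particular real dataset.

## Problem sizes and numerical choices

The test suite exercises: exact recovery on a 60-gene/5-TF/20-condition
noise-free instance (relative residual below `1e-6`, per-TF activity
correlations ≥ 0.999 after sign alignment); noisy recovery at
`noise_sd = 0.1` over 20 seeds (median per-TF |correlation| ≥ 0.95,
support signs ≥ 95%); checker-vs-matching-oracle agreement on 100
random patterns up to 20x6; null calibration on 10,000 genes x 10
ecotypes x 3v3 replicates; network-vs-double-loop equivalence on
instances up to 50x50; and a full-scale 1294x35x10 instance through
the auto-ridge path (shape-level check; uniqueness is not claimed
there). These sizes were chosen to make each property measurable with
comfortable statistical margins at interactive runtimes.

Key defaults, all configurable: DE `alpha = 0.01` (raw p); network
`|r| >= 0.8`; ALS `tol = 1e-6`, `max_iter = 500`, `n_starts = 3`;
auto-ridge `1e-3 · mean diag(AᵀA)`; robust-z threshold 2.0; rank
tolerance `1e-8 · σ_max`.

## Worked micro-example

```{r example, eval = FALSE}
pat <- generate_connectivity(n_genes = 60, n_tfs = 5, density = 0.2,
                             seed = 7)
truth <- simulate_nca_instance(pat, n_conditions = 20, noise_sd = 0.1,
                               seed = 11)
model <- fit_nca(truth$expression, pat, seed = 3)
recovery_metrics(model, truth)$tfa_abs_cor
#>   tf01   tf02   tf03   tf04   tf05
#> 0.9996 0.9997 0.9995 0.9996 0.9997
```

## Known limitations

- Under-determined instances (conditions < TFs) yield regularised,
  non-unique activities; the ridge path makes this explicit rather
  than solving it. Adding conditions (e.g. treating replicate arrays
  as separate columns) is the principled fix when the data allow it.
- The network stage inherits all the caveats of co-expression:
  correlation is not regulation, and with ~10 fold-change points the
  edge set is noisy. It is treated as a support hypothesis.
- Multi-start ALS reduces but cannot eliminate the risk of local
  optima; raise `n_starts` for hard instances.
- The hypergeometric enrichment assumes exchangeable genes; no
  gene-length or expression-level bias correction is attempted.
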