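---
title: "Primacy hulls and olfactory connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primacy hulls and olfactory connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primacyhull)
```

# The model

## Mass-action activation and primacy sets

A receptor type $r$ responds to a pure odorant $o$ at concentration $c_o$
according to the mass-action law

$$\frac{f_r}{1-f_r} = K_{ro}\,c_o,$$

where $K_{ro}$ is the affinity (inverse concentration units). The receptor
is half-activated exactly at $c_o = 1/K_{ro}$, so affinities can be read as
inverse threshold concentrations. For mixtures, independent binding gives
$f_r/(1-f_r) = \mathbf{K}_r\cdot\mathbf{c} = (\mathbf{K}_r\cdot\mathbf{q})\,c$,
with $\mathbf{q} = \mathbf{c}/\lVert\mathbf{c}\rVert$ the mixture direction
and $c$ the total concentration.

Under primacy coding, odor identity is carried by the $p$ receptor types
activated at the lowest concentration: the **primacy set** of the direction
$\mathbf{q}$. Because activation order along a fixed $\mathbf{q}$ is the
order of projections $\mathbf{K}_r\cdot\mathbf{q}$, the primacy set is the
top-$p$ projection set and is independent of the activation threshold
$\theta$ — `primacy_set()` therefore never consults $\theta$, and
`active_set()` uses a strict inequality $f_r > \theta$ (default
$\theta = 1/2$) so the zero-concentration ensemble is unambiguously silent.

If the affinity matrix factorizes as $K = R\,Q$ with $R$ ($N\times D$) and
$Q$ ($D\times M$), $D \ll N, M$, the same geometry lives in the
$D$-dimensional property space: $f_r/(1-f_r) = \mathbf{R}_r\cdot\tilde{q}$
with $\tilde q = Q\mathbf{c}$. $D$ is an assumption about the intrinsic
dimensionality of odor space, not a quantity the package fits.

## The primacy hull

Sweeping all mixture directions and collecting the primacy sets yields the
**primacy hull**: a simplicial complex whose vertices are receptors that
encode at least one odor identity. It contains every convex-hull extreme
point and possibly interior points. Receptors outside the hull never encode
an identity and are predicted to be pseudogenized. The $n$-vertex faces of
a $p$-vertex simplex — of which there are $\binom{p}{n}$, see
`face_count()` — are the "subprime" simplexes proposed as the unit of
representation of single Kenyon cells (KCs) or cortical cells.

### Numerical construction

`build_hull()` is a Monte-Carlo sweep: directions are drawn uniformly on
the unit sphere (Gaussian normalization), reflected into the nonnegative
orthant when the cone is `"nonnegative_orthant"`. That cone is the default
for raw affinity points, since mixture concentration vectors are
nonnegative; `"full_sphere"` is available for property-space points whose
loadings may carry signs. Draws are consumed one direction at a time, so
nested samples under a common seed produce monotonically growing hulls — a
useful convergence diagnostic is to compare hulls at increasing
`n_directions` and watch the new-simplex discovery rate.

In two dimensions the sweep is solved exactly (`build_hull_exact_2d()`):
projection rankings change only at directions orthogonal to pairwise
difference vectors, so enumerating the $O(N^2)$ critical angles and
evaluating one direction per interval recovers the complete hull with no
sampling. This serves as the oracle for the Monte-Carlo route in the test
suite. For $D > 2$ the corresponding arrangement enumeration grows
combinatorially, so only the sampled construction is offered.

Ties in projections are broken toward the lowest receptor index and
flagged; for continuous affinities they are measure-zero, and the
deterministic rule keeps every pipeline reproducible.

# The two connectivity analyses

## Cross-animal conservation

For each animal, the glomerulus–glomerulus similarity matrix is the Pearson
correlation between binary glomerulus→KC projection columns
(`glom_similarity()`). Conservation across animals is quantified by the
Pearson correlation of the strictly-upper-triangle entries of the two
similarity matrices (`offdiag_correlation()`), with a Mantel-style
permutation test: glomerulus labels of one matrix are permuted jointly on
rows and columns, and p-values carry a +1 pseudocount so they are never
zero. The test defaults to the one-sided alternative (conservation implies
positive correlation).

The null model throughout is the **degree-preserving shuffle**
(`shuffle_degree_preserving()`): a checkerboard-swap Markov chain that
exchanges $2\times 2$ submatrices $[[1,0],[0,1]] \leftrightarrow
[[0,1],[1,0]]$, preserving every row and column sum exactly. Proposals
draw two 1-entries uniformly at random (the classic edge-swap proposal,
symmetric and hence uniform over the margin-constrained state space);
rejected proposals keep the chain aperiodic. The default proposal count is
scaled by the fill density $d$ — an edge-pair proposal is accepted with
probability roughly $(1-d)^2$ — so that the *expected number of accepted
swaps* is ten times the number of ones regardless of sparsity. This
matters: a chain with too few accepted swaps produces a "null" that
silently retains real structure, which both weakens enrichment contrasts
and leaves cross-animal correlations artificially alive after shuffling.

Low-dimensional structure is probed by embedding the similarity matrices:
`pca_embed()` treats rows as feature vectors and reports eigenvalue
fractions; `isomap_embed()` runs classical Isomap (Euclidean row distances,
symmetrized k-nearest-neighbor graph, shortest-path geodesics, classical
MDS), reporting positive-eigenvalue fractions of the geodesic Gram matrix.
The neighbor count defaults to the smallest $k$ whose graph is connected —
the embedding is then defined for every input — and a user-supplied $k$
that disconnects the graph is an error naming that smallest $k$. The
distance between similarity rows was chosen to match the PCA feature-vector
convention; the source analyses do not pin down the metric, and this keeps
the two methods comparable.

`dimension_significance()` compares per-dimension variance fractions with
the same pipeline applied to a shuffle ensemble (empirical p with +1
pseudocount). Cross-animal agreement of embeddings is measured by
orthogonal Procrustes alignment *without scaling* (`embedding_rmsd()`):
rotations and reflections are free (embedding orientation is arbitrary) but
a scale factor is not, because a common scale across animals is part of
what conservation means. `embedding_rmsd_test()` compares the
per-glomerulus residuals against a shuffle ensemble with a two-sample
t-test; the exact test variant behind the published comparison is not
specified, so the package uses the two-sample form on per-point residuals
and documents it here.

## Affinity–connectivity overlap

From a masked receptor×odorant response table, `primacy_matrix()` marks the
$p$ strongest *observed* responders per odorant. Missingness is handled by
exclusion only: unobserved entries never rank, and odorants with fewer than
`min_observed` (default $\max(p, 8)$) measurements are dropped and logged
rather than imputed — imputation would manufacture primacy members out of
thin air. Every retained column sums to exactly $p$.

`overlap_table()` multiplies the binary connectivity and primacy matrices:
entry (KC, odorant) counts claws landing in that odorant's primacy set.
`topk_enrichment()` ranks KCs per odorant by overlap, keeps the top $k$
($k=1$ is the "grandmother-KC" readout; $k = 10$ or $50$ probe population
readout), histograms the kept overlaps by degree, and compares against
degree-preserving shuffles of the connectivity. Per (p, degree) cell it
reports observed − null-mean, a two-sided empirical p-value — the fraction
of shuffles whose deviation from the null mean is at least the observed
deviation, with a +1 pseudocount, so the attainable floor is $1/(S+1)$
rather than the $2/(S+1)$ of a doubled one-sided tail — and BH q-values
across the full grid (cells with degree
$> p$ are impossible and are not tested). The primacy-number sweep defaults
to $p = 1\ldots 8$. Two conventions are our own, made deterministic and
flagged where they bite: exactly $k$ KCs are kept per odorant with ties
broken by KC order, and the per-cell test is an empirical permutation
test (the published analysis states only the FDR threshold).

Glomeruli receiving multiple receptor types have no unambiguous affinity
row; comparisons against response data therefore restrict to single-receptor
glomeruli via a two-column glomerulus↔receptor map.

# The surrogate-data generator

`surrogate_world()` builds the full planted-truth bundle the analyses
assume:

* **Receptor points**: i.i.d. normal with unit spread, mean-shifted to 3 in
  each coordinate, i.e. essentially confined to the positive orthant so
  projections onto nonnegative directions are valid affinities.
* **Odorant properties**: unit vectors drawn from the nonnegative orthant —
  the same cone the hull sweep uses, and each odorant's vector is included
  among the sweep directions, so every planted primacy set is a hull
  simplex *by construction*.
* **Responses**: `clip(R·Q + noise, 0)`, rescaled to [0, 1], masked either
  by i.i.d. Bernoulli missingness or by a user-supplied template mask
  copied verbatim (for matching an empirical missingness pattern). The
  noise s.d. defaults to 0.2 on the raw projection scale, about 20% of the
  between-receptor spread — enough to perturb borderline ranks without
  erasing the planted order.
* **Connectivity**: each KC picks a hull simplex with probability
  proportional to sweep support, then a uniform $n$-subset of its vertices
  (a subprime face) as claws; each claw is rewired to a uniform random
  glomerulus with probability `claw_noise_fraction` (duplicates redrawn, so
  claw counts are exact). A second animal (`make_second_animal()`) is an
  independent KC sample from the same hull. The matched negative control
  (`make_null_world()`) replaces connectivity by its degree-preserving
  shuffle and flags the provenance.

Defaults are fly scale: 51 channels, 156 odorants, 1800 KCs, 5–6 claws per
KC, $p = 5$, 30% missing responses. Where the study conditions leave a
value open we fixed it once: $D = 4$ (a low dimension consistent with the
low-dimensionality premise while leaving the hull nontrivial), 20% claw
noise (wiring is noisy but hull-dominated), response noise 0.2.

**What the generator does and does not emulate.** It reproduces the
*structural* premises — low-rank responses, a shared hull, face-sampling
KCs, DoOR-like missingness — but not synapse counts, odorant chemistry,
correlated missingness by study provenance, receptor-specific response
gains, or temporal response structure. Passing the planted-recovery tests
shows the pipeline detects the hypothesized structure when present and
stays silent when absent; it does not certify that real fly data contains
that structure.

A residual worth knowing about: because KCs sample simplices in proportion
to hull support, glomerulus degrees are heterogeneous and *shared* between
the two surrogate animals. Degree structure survives the degree-preserving
shuffle by construction, so cross-animal similarity correlations computed
against a shuffled animal retain a small positive expectation (empirically
$r \approx 0.04$ at the default scale, versus $\approx 0.4$ for intact
animals); single-shuffle permutation p-values are typically, but not
always, far above 0.05.

# Problem sizes and determinism

The test suite exercises the pipeline at a reduced scale chosen to keep the
statistics honest while the suite stays quick: planted worlds of 30
receptors, 60 odorants and 300 KCs ($D = 4$, $p = 5$, $n = 5$ claws, 20%
claw noise, 30% missing), 200 shuffles per enrichment, 20 replicate worlds
for power/type-I assessment, and $10^5$ sweep directions when checking the
Monte-Carlo hull against the exact 2D construction.

Every stochastic operation takes an explicit seed; `run_pipeline()` derives
a distinct sub-seed per stage from one global seed (recorded in the
metadata log) so stages can be re-run independently and identical
config + seed reproduce byte-identical outputs.

# Known limitations

* The exact hull construction is 2D-only; in higher dimensions hull
  completeness is only asymptotic in `n_directions` (simplexes supported on
  very narrow direction cones can be missed at finite sampling).
* The mass-action model excludes antagonism and multi-site binding;
  primacy sets derived from it are only as good as the linear model at low
  concentration.
* `primacy_matrix()` treats normalized responses as affinity surrogates;
  rank agreement between the two is an assumption, not a guarantee.
* The enrichment test conditions on the observed missingness pattern; it
  does not model missingness that is informative about response strength.
* With few shuffles the empirical p-value floor ($1/(S+1)$) combined with
  BH across the (p, degree) grid can make single isolated cells
  undetectable; use at least 200 shuffles per the defaults.
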