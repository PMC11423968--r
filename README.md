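# primacyhull

Tools for the **primacy model** of concentration-invariant odor identity
coding, and for testing its connectivity predictions in olfactory circuit
data.

## The problem

As an odor's concentration rises, more olfactory receptor (OR) types
activate — yet its perceived identity stays put. Under primacy coding,
identity is carried by the *p* receptor types of highest affinity (those
activated at the lowest concentration): the **primacy set**. With
mass-action activation

$$\frac{f_r}{1-f_r} = \mathbf{K}_r \cdot \mathbf{c}
  = (\mathbf{K}_r \cdot \mathbf{q})\,c,$$

the primacy set of a mixture direction $\mathbf{q}$ is simply the top-$p$
set of projections $\mathbf{K}_r\cdot\mathbf{q}$, independent of the
activation threshold. If the affinity matrix is low-rank,
$K = R\,Q$ with $D \ll N, M$, the same geometry lives in a $D$-dimensional
property space. Sweeping all directions traces out the **primacy hull**:
the simplicial complex of all primacy sets, containing every receptor that
encodes at least one identity — receptors outside it are predicted to be
pseudogenized. The $\binom{p}{n}$ $n$-vertex faces of each primacy simplex
("subprime" simplexes) are the proposed unit of representation of single
mushroom-body Kenyon cells (KCs) or piriform cells.

The package is for systems neuroscientists who want to (a) build and
inspect primacy hulls from receptor affinity geometry, (b) test whether
glomerulus→KC connectivity carries conserved low-dimensional structure
across animals, and (c) test whether KC inputs are enriched for
high-affinity (primacy) receptor sets — with degree-preserving nulls,
permutation tests, and FDR control throughout, plus a surrogate-data
generator with planted ground truth.

## Worked example

Generate a fly-scale-down surrogate world with a planted hull, then run
the two analyses:

```r
library(primacyhull)
w <- surrogate_world(world_config(
  n_receptors = 30, dimension = 4, p = 5, n_odorants = 60,
  n_kc = 300, claws_per_kc = 5, claw_noise_fraction = 0.2,
  missing_rate = 0.3, n_directions = 1000, seed = 42), two_animals = TRUE)
w
#> Surrogate world (planted): N = 30 receptors, D = 4, p = 5, 60 odorants
#>   hull: 61 simplexes; KCs: 300 x 5 claws (noise 20%); missing 29%
#>   second animal present
w$hull
#> Primacy hull: p = 5, 30 receptors (D = 4), 61 simplexes, 15 hull vertices
#>   sweep: monte_carlo (1000 directions, nonnegative_orthant)
```

Fifteen of the 30 receptors belong to no primacy set — under the model,
pseudogenization candidates (`hull_membership(w$hull)`).

**Cross-animal conservation.** The two animals share the hull, so their
glomerulus–glomerulus similarity matrices correlate far above the
label-permutation null:

```r
S1 <- glom_similarity(w$connectivity)
S2 <- glom_similarity(w$connectivity_b)
offdiag_correlation(S1, S2, n_perm = 999, seed = 1)
#> Off-diagonal similarity correlation: r = 0.633 over 30 labels
#>   (p = 0.001, greater, 999 permutations)
```

Shuffling either matrix with `shuffle_degree_preserving()` (exact row and
column sums kept) collapses r to about zero.

**Overlap enrichment.** KCs sample faces of hull simplexes, so their claw
overlaps with primacy sets exceed the degree-preserving null:

```r
e <- topk_enrichment(w$connectivity, w$affinity, k = 10, p = 1:8,
                     n_shuffles = 200, seed = 43)
subset(as.data.frame(e), q_value < 0.05 & p == 5)
#>    p degree observed null_mean    diff     p_value    q_value
#> 18 5      3      138   175.945 -37.945 0.004975124 0.03127221
#> 20 5      5       66    29.660  36.340 0.004975124 0.03127221
```

At the generating primacy number (p = 5), top-ranked KCs show a deficit of
middling overlaps and a large excess of complete (degree-5) overlaps
relative to shuffled wiring — the planted hull detected at FDR < 0.05.
`make_null_world(w)` gives the matched negative control, on which the same
test reports nothing.

With real exports (hemibrain/FAFB-style connectivity matrices or edge
lists, a DoOR-style response table, and a glomerulus↔OR map), the same
statistics are computed by `run_pipeline()` or the `exec/primacyhull`
command-line wrapper (`simulate`, `hull`, `conn-compare`,
`affinity-compare`, `enrich` subcommands).

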