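---
title: "Triplet-based representation and reconstruction of herbal formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet-based representation and reconstruction of herbal formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccmm)
```

## The model

A materia medica (CMM) monograph records three label sets: properties
(natures) from a five-element vocabulary, flavors from a seven-element
vocabulary, and meridian tropisms from a twelve-element vocabulary. The
package represents each CMM by its **triplet set**: the Cartesian product of
the three label sets, so a record with $n_1$ properties, $n_2$ flavors and
$n_3$ meridians carries exactly $n_1 n_2 n_3$ property–flavor–meridian
triplets (here called PCCMMs). Over a pharmacopoeia the theoretical triplet
universe has $5 \times 7 \times 12 = 420$ elements, but only the observed
subset — the union over admitted records — forms the working space $J$ with
$m = |J|$; the admitted records form the CMM space $I$ with $N = |I|$.
Records with any empty label set are flagged incomplete and excluded from
both spaces rather than silently dropped.

The **measurement matrix** $P \in \{0,1\}^{m \times N}$ has column $j$ equal
to the indicator of record $j$'s triplet set. A formula is a set of CMMs,
encoded as $x \in \{0,1\}^N$. The forward map is quasi-linear:

$$y_w = P x \qquad y = \min(P x, \mathbf{1}),$$

where $y_w$ counts, per triplet, how many members of the formula carry it,
and $y$ is its 0–1 cap (the union of the members' triplet sets). The model
deliberately treats members as independent, additive carriers of their
triplets; interactions between herbs are outside its scope. $y_w$ is kept in
exact integer arithmetic so multiplicity statements are bit-exact.

The worked example shipped as `mahuang_fixture()` is a four-herb decoction
in which the Ephedra record expands to 4 triplets, the formula's 16 triplet
slots collapse to 13 distinct triplets, and exactly 3 triplets have
multiplicity 2 — facts the test suite recomputes from the bundle.

### Canonical ordering

The row order of $P$ follows a fixed lexicographic order on (property,
flavor, meridian) using the vocabulary orders returned by
`pccmm_properties()`, `pccmm_flavors()` and `pccmm_meridians()`. Any fixed
order gives matrices equal up to row permutation; choosing one makes every
artifact deterministic and diffable. Column order is the input record order.
External files always carry ids and triplet labels, never bare indices.

## The backward problem

Reconstruction asks: given a target vector measured from an unknown formula,
which candidate formulas $z \in \{0,1\}^N$ explain it best? Two
combinatorial programs are solved, both subject to covering constraints and
to contraindicated-pair constraints $z_a + z_b \le 1$:

* **unweighted** — minimize
  $\omega_1\lVert z\rVert_1 + (1-\omega_1)\lVert \min(Pz,1) - y \rVert_1$
  subject to $P z \ge y$;
* **weighted** — minimize
  $\omega_1\lVert z\rVert_1 + (1-\omega_1)\lVert Pz - y_w \rVert_1$
  subject to $P z \ge y_w$.

The first term favors parsimonious formulas, the second penalizes off-target
triplet coverage; $\omega_1 \in (0,1)$ balances them.

### Linearization and solving

The unweighted penalty is nonlinear in $z$; under the covering constraint it
equals the *count* of covered off-target rows, so the package introduces one
auxiliary binary $u_k$ per off-target row with the big-M constraint
$(Pz)_k \le M_k u_k$, $M_k$ being row $k$'s sum — the tightest valid
constant. In weighted mode the constraint makes the penalty affine
($\sum_j \mathrm{colsum}_j z_j - \lVert y_w\rVert_1$), so no auxiliaries are
needed; the constant is dropped internally and restored in reported
objective values. The test suite re-evaluates the published objective
verbatim on every pool member, so the equivalence of the linearization is
checked, not assumed.

The resulting integer programs are solved by HiGHS through a bundled
`scipy.optimize.milp` helper invoked as a subprocess (batched: one process
solves an entire catalog sweep). Alternate optima are enumerated with
no-good cuts
$\sum_{i \in \mathrm{supp}(z^*)}(1-z_i) + \sum_{i \notin \mathrm{supp}(z^*)} z_i \ge 1$
until the objective leaves the optimum (pool gap zero, tie tolerance
$10^{-6}$ — safe, since objective levels at the default grid are multiples
of $\min(\omega_1, 1-\omega_1)$) or the pool cap is reached. A pure-R
exhaustive backend enumerates all $2^N$ candidates for spaces up to 22
herbs; it exists so that solver results can be cross-validated without any
external process.

### Parameters

| parameter | default | rationale |
|---|---|---|
| `omega1` | 0.5 | conventional equal balance; recovery degrades as it approaches 1 because off-target coverage stops being penalized |
| `cap` (pool size) | 15,000 | large enough that synthetic pools are never truncated; capped pools are flagged because a truncated pool can understate the best achievable similarity |
| `tol` | 1e-6 | separates adjacent objective levels at any grid value with a wide margin |
| sweep grid | 0.1–0.9 by 0.1 | standard sensitivity sweep over the admissible open interval |

`rebuild_catalog()` measures each catalog formula, reconstructs it from its
own measurement, and scores the best pool member by Jaccard similarity
$\lVert\min(x,\hat z)\rVert_1 / \lVert\max(x,\hat z)\rVert_1$ against the
true membership vector. Because the true formula is feasible for its own
target, infeasibility cannot occur in this experiment; the per-formula
optimum is bounded by the true formula's objective. Degenerate
pharmacopoeias (two herbs with identical triplet sets) produce exchangeable
optima; the pool then contains every interchangeable variant, which is the
correct answer, not an error.

## Differentiation experiments

**Pseudo-formulas.** Random "formulas" are i.i.d. Bernoulli$(s/N)$ vectors,
so the member count is Binomial$(N, s/N)$ with mean $s$; the default
$s = 6.55$ is the catalog-wide mean formula size. All-zero draws are
rejected and resampled — the single deviation from raw Bernoulli sampling,
made because an empty formula has no triplet image; the resulting
conditioning on $\ge 1$ member is accounted for in the distributional test.

**Embedding.** `embed_2d()` is an exact $O(n^2)$ t-SNE on a precomputed
distance matrix (Hamming by default — the proportion of differing
coordinates, meaningful for both 0–1 and count vectors), with perplexity 30
and learning rate 500 as the experiment defaults, early exaggeration for
the first 100 of 1000 iterations, and a seed-controlled Gaussian initial
layout; given the seed the embedding is fully deterministic. It requires at
least $3 \times \text{perplexity} + 1$ points.

**Bootstrap classification.** For syndrome-labeled formulas the classifier
repeatedly draws 16 training cases per class, assigns each held-out vector
to the class with the smallest mean $\ell_1$ distance to its training
cases, and aggregates accuracy over 5,000 trials by default. Whether the
$\ell_1$ distances live in the 2-D embedded plane (`preembed = TRUE`, the
default, matching the stated preprocessing pipeline) or in the original
vector space (`preembed = FALSE`) is exposed as a flag, because the
source pipeline's wording does not pin the distance space down; both paths
are tested. Ties in the argmin go to the earliest class in factor-level
order, a deterministic convention. Accuracy summaries are means over
trials; the full accuracy vector is returned so other summaries can be
taken.

## Pattern mining

Formulas become transactions at two levels: herb ids, or the formula's
deduplicated triplet set. `item_frequency()` counts exact occurrences;
high-frequency selection is threshold-based (defaults 10 at the herb level,
50 at the triplet level) because the field has no unified cutoff — the
threshold is a parameter, not a constant. `mine_rules()` is a levelwise
apriori with single-item consequents and maximum rule length 10, pinned
because rule counts are only meaningful under a fixed convention; support
and confidence are $\ge$ filters while lift is a strict $>$ filter.
`binary_distance_matrix()` uses the asymmetric 00-ignoring convention
$d = (n_{10}+n_{01})/(n_{11}+n_{10}+n_{01})$ — equal to one minus the
Jaccard similarity of the items' transaction sets — with a symmetric
Hamming variant as an option; `phi_correlation_matrix()` is Pearson on the
0/1 indicator columns, identical to the phi coefficient of each pair's
2×2 table. Both identities are unit-tested, and the rule miner is tested
for exact agreement with a brute-force enumerator on small universes.

## The synthetic generator

`generate_pharmacopoeia()` draws label-count distributions of 1–2
properties, 1–3 flavors and 1–6 meridians with weights chosen once to put
the expected triplet-set size near 3.9 per record — the density regime of
real monograph tables (about 3.7 triplets per record, matrix density under
2%) — and skews label identities toward the commonly recorded ones.
`generate_catalog()` draws Binomial-sized member sets (mean 6.55,
conditioned non-empty) that never violate the supplied contraindicated
pairs. One master seed drives all child generators through fixed offsets,
so every bundle is bit-reproducible and round-trips exactly through the
package's delimited formats.

What the generator does **not** emulate: correlations between the three
label axes within a record, the long-tailed reuse of a few very common
herbs across formulas, batch-specific vocabulary drift, and dosage. Passing
tests on synthetic data therefore demonstrate the correctness of the
machinery and the qualitative behavior of the models (weighted targets
recover at least as well as unweighted ones; recovery does not improve as
$\omega_1$ grows past 0.5; triplet-level encodings classify shared-signature
classes that herb-level encodings cannot), not quantitative agreement with
any specific pharmacopoeia. Full-scale reference tables can be fed through
`supplement_checks()` when available.

## Problem sizes used by the shipped tests

Oracle-equivalence checks enumerate all subsets for spaces of 6–12 herbs
(200 random instances, both modes, $\omega_1 \in \{0.1, 0.5, 0.9\}$);
the synthetic suites use 25–300 herbs and 6–150 formulas; bootstrap checks
run 50–1,000 trials. These sizes were chosen so the whole suite documents
the package's behavior in about a minute while still exercising every code
path at meaningful scale; all defaults in the API remain the full-scale
values quoted above.

## Known limitations

* The measurement model is qualitative: multiplicities count herbs, not
  doses, and inter-herb interactions are out of scope by design.
* Reconstruction pools are exact optima only; near-optimal solutions are
  not reported (pool gap is fixed at zero).
* The default MILP backend requires a Python interpreter with scipy on the
  PATH; the exhaustive backend covers only small spaces.
* t-SNE coordinates are seed-dependent like any stochastic embedding;
  seeds are mandatory arguments rather than defaults for that reason.
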