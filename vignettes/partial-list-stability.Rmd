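---
title: "Comparing ranked lists of unequal length: the partial-list Canberra measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ranked lists of unequal length: the partial-list Canberra measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canberralists)
```

## The problem

Feature-selection procedures in molecular profiling emit *ranked lists*:
the probes or genes a classifier or filter considers most informative,
best first. Re-running the same procedure on resampled data yields a set
of lists that rarely agree, and quantifying that disagreement — the
*stability* of the signature — requires a dissimilarity between ranked
lists. When every run reports the same number of features, classical
metrics on permutation groups apply directly. In practice lists have
different lengths and different supports: one run may keep 25 probes,
another 60, out of tens of thousands. This package extends the Canberra
distance on permutation groups to exactly this situation.

## From permutations to partial lists

For full rankings, a list corresponds to a unique permutation $\tau$
sending each feature to its rank, and the Canberra distance

$$d(\tau_1, \tau_2) \;=\; \sum_{g} \frac{|\tau_1(g) - \tau_2(g)|}
                                        {\tau_1(g) + \tau_2(g)}$$

weighs disagreements near the top of the list far more than equal
displacements near the bottom — the property that matters when the top
of the list is what gets validated in the lab.

A partial (top-$k$) list of length $l$ over a universe of $p$ features
pins down only the first $l$ ranks; every assignment of the remaining
$p - l$ features to the bottom positions is a legal *completion*, and
there are $(p - l)!$ of them. We define the dissimilarity of two partial
lists as the **mean** Canberra distance over all pairs of completions.
The mean is the natural aggregator here: the Canberra distance on the
permutation group is asymptotically normal, so the mean is both
representative and well concentrated.

Writing $z$ for the number of shared features and $u$ for the features
in neither list, linearity of expectation splits the mean into three
terms (a uniform completion places each unlisted feature uniformly on
the bottom positions, independently for the two lists):

* **T1** — features in both lists, with ranks $\tau_1(g), \tau_2(g)$:
  the plain Canberra summand, no averaging needed;
* **T2** — features in exactly one list, at rank $r$ there: the average
  of $|r - j|/(r + j)$ over the other list's bottom positions
  $j = l_{\text{other}}+1, \dots, p$;
* **T3** — the $u$ features in neither list:
  $u \cdot \frac{1}{(p-l_1)(p-l_2)} \sum_{i>l_1}\sum_{j>l_2}
  \frac{|i-j|}{i+j}$, which depends only on $(p, l_1, l_2, u)$ — never on
  which features were selected or how they were ranked.

The **Complete** measure is $T1 + T2 + T3$; the **Core** measure drops
T3 and keeps only the part that reacts to the identity and ordering of
the selected features. When $l \ll p$ (a biomarker panel of dozens out
of thousands of probes) T3 dominates the Complete measure numerically —
it is essentially the background disagreement of two random orderings of
the unselected mass — so Core is the right lens for comparing short
lists, while Complete is preferable when $l$ is of the same order as
$p$. Empirically the two are nearly proportional while $l/p < 0.15$.

Two consequences worth internalising:

* the Complete measure is *not* a metric: a partial list has positive
  self-dissimilarity (its completions differ among themselves) whenever
  $l \le p - 2$. At $l = p - 1$ the completion is unique and the
  self-dissimilarity collapses to zero, exactly as for complete lists —
  a boundary case the tests pin down explicitly;
* the Core measure of identical lists is always zero.

## Normalization

All values are reported relative to the exact expected Canberra distance
between a random permutation and the identity,

$$E(p) \;=\; \frac{1}{p} \sum_{i=1}^{p} \sum_{j=1}^{p} \frac{|i-j|}{i+j},$$

which follows from the observation that each (rank, position) pairing
occurs in exactly $(p-1)!$ permutations. $E(p)$ is the *mean*, not the
maximum, so normalized values above 1 occur and are never clamped — the
maximally distant pair of complete lists at $p = 10$ sits around 1.42.
Asymptotically $E(p) \approx (2\ln 2 - 1)(p + 1) - 1$; the package
exposes this approximation for scaling intuition but always normalizes
with the exact value.

## Evaluation strategies and numerical choices

Three interchangeable strategies compute the same quantity:

1. `measure_bruteforce()` — literal enumeration of all
   $(p-l_1)!\,(p-l_2)!$ completion pairs (compiled code), refused above a
   cap of $10^6$ pairs. The ground truth oracle.
2. `measure_marginal()` — the per-feature expectation form above, with
   explicit inner sums. Quadratic in $p$ through T3; the readable
   reference semantics.
3. `measure_closed()` — the production path. T2 tail sums and the T3
   block sum are reduced to closed forms in harmonic numbers
   ($T(n,k) = \sum_{i\le n} i H_{i+k}$, $U(n) = \sum_{i \le n} i H_{2i-1}$
   and relatives, each a handful of table lookups), so a pair costs
   $O(l_1 + l_2)$ after one $O(p)$ harmonic table. $E(p)$ itself is
   evaluated in $O(p)$ by grouping the double sum by rank-sum $s = i+j$,
   whose numerators form a symmetric progression with a closed-form
   total.

Numerical decisions:

* harmonic numbers by cumulative double-precision summation (error
  $\sim p\,\varepsilon$, irrelevant at the 1e-9 agreement level enforced
  between strategies for $p$ up to $10^6$);
* the closed-form block and tail sums are differences of large terms;
  they are clamped at zero, where the exact value is zero and
  cancellation can leave $\sim 10^{-13}$ of noise;
* all integer products that can exceed $2^{31}$ (e.g.
  $(p-l_1)(p-l_2)$ at $p = 10^5$) are computed in double precision;
* cross-strategy agreement is asserted componentwise (T1, T2, T3, Core,
  Complete) at 1e-9 relative tolerance, not just on totals;
* ranks are 1-based, rank 1 is best; ties are not representable —
  lists are orderings, and duplicate tokens are a hard validation error;
* empty lists are accepted: Core is 0 and Complete equals the T3 term
  with $u = p$, which for two empty lists is exactly $E(p)$ — a useful
  self-check that the expectation form is wired correctly;
* the same exact grouped $E(p)$ is used as normalizer by every strategy,
  so normalized values are strategy-independent.

## Stability indicator

For a set of $B$ lists the package computes all mutual measures and
averages the $B(B-1)/2$ distinct unordered pairs. Self-pairs are
excluded from the mean: in complete mode a partial list's positive
self-dissimilarity would otherwise bias a set of identical partial lists
away from its intuitive value, and for random complete lists the
pair-mean convention is what concentrates at 1. Diagonal entries are
still computed and reported — for partial lists they mark the floor the
indicator cannot go below. Smaller indicator = more homogeneous set.

## Borda aggregation

To fuse a list set into one representative list, each feature gets its
*extraction count* (number of lists containing it) and its *mean
position* over those lists; features are ordered by decreasing
extractions, then increasing mean position, then universe order. On
complete lists this provably coincides with the classical Borda count
(ascending total rank), which the tests verify by brute force. Two
conventions the underlying theory leaves open, fixed here: mean position
averages only over the lists that contain the feature (no imputed bottom
rank for absences), and unextracted features are excluded by default
(`include_unextracted = TRUE` appends them last, in universe order,
keeping the output total and deterministic).

## Synthetic generators and what they do (not) show

The generators reproduce the settings used to characterise the measures:

* `random_complete_lists(n, p, seed)` — independent uniform
  permutations. The normalized indicator of such sets has expectation
  exactly 1 (right-invariance), with 10-replicate means scattering by
  $\pm 0.02$ at $(n{=}5, p{=}10)$ and far less at larger $p$;
* `random_partial_lists(n, p, l, seed, shared_support)` — either
  independent top-$l$ heads of uniform permutations, or independent
  orderings of one shared support (the setting of the reference tables'
  "random" rows, which are single draws, not expectations — the tests
  therefore check simulated 3-sigma bands rather than point equality);
* `max_distant_ordering(l)` — exhaustive search for the ordering
  maximizing the distance to the identity, capped at $l = 10$
  (3.6 million permutations, under a second in compiled code). By
  right-invariance this realizes the maximally distant shared-support
  pair regardless of which features form the support;
* `replicate_table1()` / `replicate_table2()` — the two reference
  experiments: replicated stability of random complete list sets, and
  the identical / random / maximally-distant pairs of length-10 lists at
  $p = 10^c$, $c = 2..5$ (the universe sizes at which the published
  reference values were computed).

These generators emulate *uniformly random* selection — the null
situation with no signal. Real resampled feature-selection lists are
correlated across runs and concentrated on informative features, so
passing the suite says the measures and their closed forms are computed
correctly, not that any particular biological pipeline is stable.
Problem sizes in the test suite (exhaustive oracles at $p \le 7$,
enumeration caps of $10^5$ pairs, 200 random cross-strategy instances,
$10^4$-draw empirical checks) were chosen to exercise every code path
exactly while keeping the default suite around twenty seconds.

## Known limitations

* No guidance on choosing the list length $k$; the measures take the
  lists as given.
* The maximal-distance search refuses $l > 10$ rather than implement the
  structural construction from the combinatorial literature.
* Weighted or $L_q$ variants of the Canberra sum, and other permutation
  metrics (footrule, Kendall), are out of scope.
* The stability indicator averages pairwise measures; it does not test
  significance. Calibrate against the null generators if a reference
  point is needed.
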