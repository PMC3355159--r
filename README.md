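# canberralists

Canberra dissimilarity, stability and Borda aggregation for partial
ranked lists.

## What problem this solves

Feature-selection runs in transcriptomics (and any resampling-based
molecular profiling study) each emit a ranked list of features — best
probe first — and the lists disagree from run to run, in content, order
*and length*. Assessing whether a signature is reproducible requires a
dissimilarity between ranked lists that (a) weighs the top of the list
more than the bottom and (b) copes with lists of unequal length over a
much larger feature universe.

`canberralists` implements the Canberra dissimilarity on partial
(top-k) lists. A list of length *l* over a universe of *p* features is
identified with its (p−l)! completions to full permutations; the
dissimilarity between two lists is the **mean Canberra distance**

d(τ₁, τ₂) = Σ_g |τ₁(g) − τ₂(g)| / (τ₁(g) + τ₂(g))

over all pairs of completions. That mean splits exactly into three
terms — T1 (features in both lists), T2 (features in exactly one), T3
(features in neither; independent of any ranking) — giving the
**Complete** measure T1+T2+T3 and the **Core** measure T1+T2. Values
are normalized by the exact expected Canberra distance E(p) between a
random permutation and the identity; they can exceed 1 and are never
clamped. On top of the pairwise measure the package provides the
**stability indicator** (mean over all distinct pairs of a set of B
lists; smaller = more homogeneous) and **Borda aggregation** (order by
extraction count, then mean position) to fuse a list set into a single
optimal list.

Three interchangeable evaluation strategies are provided and tested
against each other to 1e-9: exhaustive enumeration (compiled, capped),
the per-feature expectation form, and a harmonic-number closed form
that costs O(l₁+l₂) per pair after one O(p) table — universes of 10⁵
features are routine.

## Worked example

Two selection runs over a 5000-probe array returned overlapping panels
of 5 and 4 probes:

```r
library(canberralists)
u    <- feature_universe(size = 5000)
run1 <- ranked_list(c("f000042", "f000007", "f001871", "f000013", "f002301"), u)
run2 <- ranked_list(c("f000007", "f000042", "f000013", "f004110"), u)
measure_closed(run1, run2, u)
#> Canberra measure (p = 5000, l1 = 5, l2 = 4, strategy = closed)
#>   T1 = 0.809524  T2 = 2.969612  T3 = 1923.083228
#>   Core     = 3.779136  (normalized 0.001957)
#>   Complete = 1926.862364  (normalized 0.997930)
#>   E(p) = 1930.858549
```

Reading the numbers: the three shared probes disagree mildly in rank
(T1), the three exclusive probes add their expected displacement (T2),
and the 4992 unselected probes contribute a large ranking-independent
background (T3) that pushes the Complete measure to ≈ 1 — i.e.
indistinguishable from random — while the **Core** measure (0.002 after
normalization) shows the selected panels themselves agree closely. For
short lists in large universes, Core is the informative number.

The same logic at set level, and the aggregate list:

```r
S <- random_partial_lists(20, 5000, 25, seed = 101)   # 20 null runs
stability_indicator(S, "complete")   #> 1.000005  (background-dominated)
stability_indicator(S, "core")       #> 0.02515223

borda_list(list_set(list(run1, run2), u))
#> Borda list: 6 features
#>  feature extractions mean_position borda_rank
#>  f000007           2           1.5          1
#>  f000042           2           1.5          2
#>  f000013           2           3.5          3
#>  f001871           1           3.0          4
#>  f004110           1           4.0          5
#>  f002301           1           5.0          6
```

A command-line interface with `distance`, `stability`, `borda` and
`simulate` subcommands ships in `inst/cli/canberra-lists` (plain-text
list files, one ranked list per line; exit codes 0/2/3 for
success / invalid input / capability refusal).

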