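---
title: "Statistical-based database fingerprints: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-based database fingerprints: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdfp)
```

## The problem

A binary molecular fingerprint encodes one molecule as a fixed-length 0/1
vector — each position a structural feature. Comparing *sets* of molecules
(an activity class against another, or a query class against a screening
library) calls for a representation of the whole set. The modal answer, the
**database fingerprint (DFP)**, sets every bit present in at least half of
the set's molecules. Its weakness is a background bias: a few dozen features
are frequent in essentially all drug-like chemistry, so they appear in the
DFP of *any* set and carry no class-specific information, while genuinely
characteristic but less-than-majority features are dropped.

The **statistical-based database fingerprint (SB-DFP)** replaces the
absolute threshold with a relative one: a bit is kept only when its
frequency in the target set is *statistically higher* than in a large
reference collection that stands in for known chemical space.

## The decision rule

For bit $j$, let $p_t = c_t/n_t$ be its proportion among the $n_t$ target
molecules and $p_r = c_r/n_r$ among the $n_r$ reference molecules. The
pooled two-proportion statistic is

$$Z = \frac{p_t - p_r}
{\sqrt{P(1-P)\left(\tfrac{1}{n_t}+\tfrac{1}{n_r}\right)}},
\qquad P = \frac{n_t p_t + n_r p_r}{n_t + n_r},$$

and the bit is set iff the one-sided p-value $1-\Phi(Z)$ is **strictly
below** $\alpha$ (alternative: the target proportion is larger). The
one-sided form is the meaningful one — depletion relative to the reference
is not evidence that a feature characterizes the class.

Numerical conventions, all visible in `two_proportion_ztest()`:

* **Degenerate pooled proportion.** $P \in \{0, 1\}$ forces $p_t = p_r$;
  the statistic is defined as $Z = 0$, $p = 0.5$ (the continuous limit of
  the equal-proportion case) and the bit is not set.
* **Strict comparison.** $p < \alpha$, not $\le$; at the boundary the bit
  stays 0.
* **No multiple-testing correction.** $\alpha$ is not a family-wise error
  budget over the 166 or 2048 bits; it is a per-bit tuning parameter whose
  value is chosen by downstream performance (screening AUC), and the false
  positives it admits are part of the representation's character. The
  default $\alpha = 0.01$ (99% confidence) is the level that performs best
  in similarity searching; `sbdfp_alpha_sweep()` and
  `benchmark_alpha_sweep()` expose the grid
  $\{0.10, 0.05, 0.01, 0.005, 0.001\}$ for re-tuning on other data.

Because the p-value is monotone non-increasing in the target count (a
property the test suite asserts on exhaustive small grids), the smallest
significant occurrence count is well-defined and `min_significant_count()`
finds it by binary search, verifying the boundary and falling back to a
linear scan if the monotone assumption were ever violated numerically. For
a 350-molecule set against a reference bit at $p_r = 0.707$
($c_r = 10{,}892{,}579$, $n_r = 15{,}403{,}690$) that boundary is 268:

```{r}
min_significant_count(350, 10892579, 15403690, 0.01)
two_proportion_ztest(268, 350, 10892579, 15403690)$p_one_sided
two_proportion_ztest(267, 350, 10892579, 15403690)$p_one_sided
```

The large-reference limit is the one-sample normal test against a known
$p_r$; agreement to three decimals at $n_r = 10^9$ is part of the property
suite.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `alpha` | `build_sbdfp` | 0.01 | per-bit one-sided significance level |
| `threshold` | `build_dfp` | 0.5 | minimum occurrence fraction (`>=`, ties set the bit) |
| `zero_value` | `tanimoto` | 0 | value of the undefined 0/0 Tanimoto case |
| `query_size` | `benchmark` | 10 | actives drawn per query replicate |
| `n_reps` | `benchmark` | 100 | query replicates |
| `selection_size` | `recovery_rate` | #ADCs | RR cutoff |
| `k` | `evaluate_representations` | 10 | clusters at which partitions are compared |

The Tanimoto convention deserves a note: two all-zero fingerprints have an
undefined similarity (0/0). This package returns 0 by default — an empty
fingerprint shares no features with anything, and the choice prevents an
all-zero SB-DFP (a set with *no* significantly enriched bits) from
appearing maximally similar to every other set. Toolkits that return 1 can
be matched with `zero_value = 1`.

The recovery-rate denominator follows the "available ADCs" reading: in each
benchmark replicate the selection size and the denominator are the number
of actives actually hidden in the library (all actives minus the
`query_size` drawn as query), not the full active count. A
`selection_size` argument overrides this where the other convention is
wanted.

## Similarity, clustering, evaluation

Inter-set similarity is computed three ways (`similarity_matrix()`): the
median Tanimoto over all cross-set molecule pairs (**ACC**), and the
Tanimoto between condensed **DFP** or **SB-DFP** vectors. For ACC the
diagonal is the median over *distinct* intra-set pairs (self-pairs
excluded), so it is generally below 1 — sets of diverse molecules are not
perfectly self-similar under all-compound comparison; condensed
representations guarantee a unit diagonal. The range of off-diagonal values
(`matrix_range_summary()`) measures a representation's resolution.

Distance is `1 - similarity`. `complete_linkage()` implements agglomerative
clustering with the maximum-distance merge rule in-package rather than
delegating to `stats::hclust`, because a deterministic tie-break is part of
the contract: among merges at the minimal distance, the pair whose clusters
have the lexicographically smallest (smallest-original-member) indices is
merged. On tie-free inputs the merge heights coincide with `hclust`
(asserted in the tests, along with a naive $O(n^3)$ agglomerative oracle);
on tied inputs the result is reproducible across platforms. Partition
agreement is the permutation-model Adjusted Rand Index
(`mclust::adjustedRandIndex` behind `adjusted_rand_index()`), with the
degenerate all-trivial case (both partitions a single cluster, or both all
singletons, where the index's denominator vanishes) defined as 1.
Dendrograms export to Newick via `ape`.

Ground-truth relationships arrive as a labeled identity matrix (percent or
fractional scale, auto-detected by range since percent data exceed 1;
`percent =` forces a scale); `evaluate_representations()` aligns all
matrices by label, cuts every tree at `k` and reports one ARI per
representation.

## What the synthetic generator emulates — and what it does not

`generator_spec()` models a fingerprint population as independent per-bit
Bernoulli draws. The default base spectrum is
`qbeta(ppoints(n_bits), 1.2, 2.6)`: skewed toward rare features, mean
frequency ≈ 0.31, matching the typical set-bit density of MACCS
fingerprints of drug-like molecules (around 52 of 166 bits set on
average), with a minority of bits above 0.5 reproducing the
common-feature bias that motivates the SB-DFP in the first place. Default
dimensions echo the scales at which the method is used: 166 bits,
reference collections of $10^6$ observations, target sets of a few hundred
molecules.

Two deliberate idealizations, and their consequences:

* **Bit independence.** Real fingerprint bits are strongly correlated
  (rings imply ring-atom counts, and so on). Independence is exactly the
  assumption of the per-bit test, so calibration results on this fixture
  (type-I error of the bit selection ≈ $\alpha$, asserted within
  [0.004, 0.025] at $\alpha = 0.01$ over 2000 null targets of
  $n_t = 200$) validate the *implementation*, not the test's behaviour on
  correlated real bits. A block-correlated mode (`block_size`,
  `block_rho`: bits in a block share a latent event while keeping their
  marginals) exists for robustness probes.
* **Enrichment strength of the screening fixture.** An activity class in
  this fixture is 20 planted bits, rare in the background (0.2) and
  near-universal among actives (0.9). The strength matters: it sets the
  actives' intra-set Tanimoto median (≈ 0.41 at 0.9 — inside the 0.35-0.8
  range real activity classes show, and about the most 20 of 166 bits can
  carry). The 1-NN search strategy lives off exactly this within-class
  resemblance, so a much weaker enrichment understates 1-NN relative to
  its behaviour on real classes, while the condensed-fingerprint
  strategies are less sensitive to it. Under the matched fixture the
  benchmark reproduces the qualitative strategy ordering
  SB-DFP ≥ 1-NN > DFP (25 replicates of 10-compound queries against 200
  actives + 5000 decoys), which is the finding the desk-scale tests are
  designed to mirror; exact real-data RR/AUC values are outside what a
  synthetic fixture can or should reproduce.

Passing tests on these fixtures therefore demonstrate correctness of the
statistics, determinism of the pipelines, and the direction of the
methodological comparisons — not performance on any particular real
compound collection.

## Reproducibility mechanics

All sampling is seeded. `benchmark()` derives an independent substream per
replicate from the top-level seed (a fixed linear-congruential scramble of
`(seed, replicate)` kept below $2^{31}$), so replicate $r$ is bit-identical
whether 2 or 100 replicates are requested, and the generator functions
save and restore the caller's RNG state. Ranking ties in the recovery rate
are broken by ascending compound identifier, never by input position, so
RR is invariant under permutation of the library. The AUC is the
Mann-Whitney form with half-credit for ties — single-fingerprint searches
produce heavily tied score vectors, for which half-credit is the unbiased
convention — and the ROC curve is built over distinct thresholds so its
trapezoidal area equals the rank-based value exactly.

## Problem sizes in the shipped tests

The test suite runs the calibration study at 2000 null targets of 200
molecules (166 bits, exact-count reference of $10^6$), the planted-signal
recovery at 200 replicates, and the screening benchmark at 25 replicates
on 200 actives / 5000 decoys — sizes chosen so the whole suite completes
in well under a minute while keeping Monte-Carlo error far from the
asserted bounds.

## Known limitations

* The chemistry adapter is OpenBabel-backed (ChemmineR/ChemmineOB); MACCS
  keys 1–166 are taken from the toolkit's padded vector and re-based to
  0–165, and ECFP4 is folded from the toolkit's 4096 bits to 2048 by
  OR-ing halves. Different toolkits assign some MACCS keys and hash ECFP
  features differently; bit-level agreement across toolkits is not
  promised, only internal consistency. All analytical modules accept
  precomputed fingerprint files, so the statistical layers carry no
  toolkit dependency at all.
* Fingerprints are binary: count-based and sparse unfolded circular
  fingerprints are out of scope.
* The SB-DFP of a set indistinguishable from the reference is all-zero by
  design; downstream Tanimoto against it is 0 under the default
  convention. Interpret near-empty SB-DFPs as "no characteristic
  chemistry detected at this α", not as a defect of the set.
* Only Tanimoto similarity and complete linkage are implemented; other
  coefficients and linkages would slot into the same interfaces but are
  not provided.
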