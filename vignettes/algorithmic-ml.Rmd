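---
title: "Algorithmic-probability machine learning: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algorithmic-probability machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`apml` treats supervised learning as inference of generative mechanisms.
The loss of predicting `ŷ` when the truth is `y` is the *information
deficit* `K(y | ŷ)` — the length in bits of the shortest program turning
`ŷ` into `y` — and the cost of a model over a sample is the sum of
squared deficits. Minimizing this cost drives the model toward an object
that is algorithmically close to all members of its target, which for
classification means a **centroid**: the classifier stores one
representative object per class and assigns a new sample to
`argmin_j K(x | c_j*)`. Because the resulting cost surfaces are defined
on spaces of bit strings, nothing here is differentiable, and
optimization proceeds by exhaustive or greedy discrete search, ordered
where possible by algorithmic probability (simple candidates first).

`K` is uncomputable; the package approximates it at three levels.

**Conditional CTM.** For a finite generative space run exhaustively —
all (initial string, rule) pairs of a cellular automaton, or all Boolean
networks of a family — the conditional complexity of outcome `x` given
condition `s` is estimated as `−log2(m(s, x) / |P|)` with `m` the pair's
occurrence count and `|P|` the total number of pair occurrences. This is
a *domain-specific* estimator: it is exact for the enumerated space and
a heuristic beyond it. Pairs never produced by the space are charged
`floor(log2 |P|) + 1` bits, the smallest integer strictly above every
tabulated value, so absence is always costlier than rarity (for the
524,288-pair automaton table that is 20 bits; for the 331,776-network
table, 19).

**BDM.** Objects too large to enumerate are cut into blocks by a
non-overlapping row-major partition; complexity is the sum of block CTM
values plus `log2` of each block's multiplicity. The conditional
variants either compare block multisets (*coarse*) or pair blocks of the
object with blocks of the condition and sum pairwise conditional CTM
values, minimized over pairings (*strong*). Because the pairing map is
functional, the minimum decomposes per block, which is why the greedy
and exhaustive strategies coincide; the *positional* strategy pairs
co-located blocks and is the right prior for objects generated by local
dynamics. In the worst case — all blocks equally complex — BDM ordering
degenerates to block-entropy ordering, which is also the package's
explicit entropy baseline.

## The experimental corpora

The generators are first-class, tested code; their defaults *are* the
study conditions, and every dataset carries a manifest whose seed
regenerates it bit-for-bit.

* **Initial-condition task.** Ten classes, the 12-bit binary expansions
  of 704, 3572, 3067, 3184, 1939, 2386, 2896, 205, 828, 3935. A sample
  is the 4-step evolution of its class string under a uniformly random
  ECA rule in 0–127 with the initialization row removed; 20 samples per
  class per split. The conditional table is compiled from all 4,096
  12-bit strings under those 128 rules, cropped to the inner 6 bits of
  the string and the inner 6×4 window of the evolution: the crop removes
  frontier cells whose light cone wraps the 12-cell ring. (4,096 × 128
  gives |P| = 524,288; a printed figure of 528,384 corresponds to
  including rule 128 as well, available via the `rules` argument.)
* **24-bit transfer.** Twenty random 24-bit class strings, 24×4 images,
  same table — a deliberate test of the table beyond the width it was
  built from.
* **NK tasks.** n = 4, k = 2 networks, zero initial state, 10 recorded
  rows (the initial row plus nine updates, giving 40-bit vectors).
  Classes are either ten ordered 4-function lists over
  {And, Or, Nand, XOr} or ten random k = 2 wirings. Function lists must
  contain Nand: it is the only pool function mapping (0,0) to 1, so
  without it the zero start can only produce forty zeros. The
  conditional tables come from the complete enumeration of the
  (C(4,2) · 4)^4 = 331,776 networks.
* **Kauffman connectivity.** n = 24 networks with k ∈ {1, 2, 3} as the
  class (frozen / critical / chaotic), functions uniform over all
  `2^(2^k)` k-ary Boolean functions, uniform random initial state
  (a zero start would make the k = 1 class nearly degenerate), 100
  samples per class per split, 240-bit vectors.

## Classifier training

Centroids start as all-zero bit strings and are optimized blockwise in
schedule order against the summed training distance. Blocks of at most
16 bits are searched exhaustively over all `2^b` candidates, accepting
only strict improvements, so the first (lexicographically smallest)
minimum wins ties and the training cost is non-increasing; wider blocks
(the 8×8 quadrants of the 16×16 rule-task centroids, 64 bits) fall back
to single-bit coordinate descent, since `2^64` candidates are not
enumerable — this is recorded on the model rather than silently
approximated. For the initial-condition task the sample is cut into
6-column blocks positionally paired with the centroid's 6-bit halves;
the two halves then decouple and two 64-candidate sweeps are exact.
Under this distance the trained centroids reproduce the class strings
themselves, which is the package's core demonstration that the
classifier recovers generative information rather than surface
statistics.

Prediction ties break toward the earliest class in declared order,
everywhere, for determinism. The exhaustive-search baseline classifies
an image by scanning (rule, class string) pairs in ascending order for
an exact reproduction of the evolution; collisions (images reachable
from two classes) are resolved by that scan order, and non-matching
images fall back to the trained centroid model.

## Parameter search

Continuous parameters are represented by an unsigned fixed-point codec
(4 integer + 4 fractional bits per scalar by default; the pair (5, 1)
is the string `0101000000010000`). Search visits all candidates in
ascending estimated complexity — here BDM over 8-bit blocks with a base
table enumerated from all 10,000 two-state, two-symbol Turing machines
(outputs the machines never produce receive an entropy-calibrated
surrogate, flagged in the table metadata) — keeping the first strict
minimum, halting on an iteration budget or a cost threshold.

The identification benchmark is the linear cascade `dz1/dt = −θ1·z1`,
`dz2/dt = θ1·z1 − θ2·z2`, `z(0) = [1, 0]`, integrated by classical
fixed-step RK4 at h = 0.01 (via deSolve; the closed form of the linear
system serves as the test oracle). The sign of the `θ1·z1` term in the
second equation is sometimes printed negative for this system; that
reading forces `z2 ≤ 0`, which the unsigned codec would clip to zero
and make `θ2` unidentifiable, so the package adopts the cascade form
under which the printed recovery behaviour is reproducible. Observations
are the two states encoded to 16 bits per time point; corruption is
exactly `n` uniformly chosen bit flips. Noise-free identification from
two informative time points (e.g. t = 0.1, 0.2) is quantization-exact
and touches exactly the true pair's rank in the complexity order (2,231
of 65,536); pairs of late times can be genuinely ambiguous at 4.4-bit
precision, with a simpler candidate reproducing both encoded samples —
a property of the codec, not of the search. RK4 at h = 0.01 matches the
closed form to ~1e−6 except near the stiff corner θ1 = θ2 = 15, where
the accumulated error reaches a few 1e−6.

## Sample weighting and regularization

`regularized_cost()` adds `λ·K(M)` to any cost. `algorithmic_weights()`
implements bracketed complexity weighting: within each class,
nearest-rank percentiles of the samples' estimated complexities define
brackets scanned from the largest percentile down, the first bracket
whose threshold the sample reaches (`K ≥ threshold`) supplying the
weight; the canonical scheme is (75th → 0.01, 50th → 0.5, rest → 2).
Nearest-rank percentiles and ≥-matching are the package's choice where
the quantile convention is open; weights therefore depend only on
within-class complexity *ranks* and are invariant to monotone rescaling
of the estimator. The corruption operator (`salt_samples()`) permutes a
fraction of pixel positions in a fraction of images, preserving each
image's pixel multiset; salted samples receive strictly lower mean
weight under the canonical brackets with either a BDM or block-entropy
scorer, which is the mechanism the weighting is meant to exploit.

## Problem sizes, tolerances, and numerical choices

All logarithms are base 2 — every quantity in the package is
denominated in bits. Conditional tables check `Σ 2^(−value) = 1` to
1e−9. Partition remainders are discarded by default (the partitions in
actual use divide evenly); zero-padding is available behind a flag.
Missing unconditional base-table entries are a hard error unless the
entropy surrogate is explicitly enabled. Ranking ties are lexicographic
on the bit sequence, so orderings are seed-free.

The packaged experiments run at the sizes stated above: table
construction enumerates 524,288 automaton pairs (~2 s) and 331,776
networks (~2 s); the headline accuracies average five dataset seeds and
complete in about two minutes total. The acceptance script reports
those five averaged accuracies; database-specific figures from the
published large-scale CTM tables (absolute BDM values and search-rank
positions) are deliberately not reproduced, since they are properties
of external tables this package does not bundle — the ECA-rule
classifier that needs the published two-dimensional table is fully
implemented and activates when a converted table is supplied.

## What the synthetic corpora do and do not show

The generators reproduce the study conditions exactly — enumerable rule
spaces, balanced classes, noiseless labels — so passing tests show that
the estimators and search procedures behave as designed *within
enumerated generative spaces*. They do not show robustness to
observation noise in the images, to unbalanced classes, or to dynamics
outside the enumerated family (the 24-bit transfer task probes one
step in that direction). The Kauffman connectivity task's scalar-BDM
classifier additionally depends on a base CTM table for its blocks;
with the entropy surrogate it reduces to an entropy-profile classifier
and should be read as such.
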