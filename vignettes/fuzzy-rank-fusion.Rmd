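---
title: "Fuzzy-rank ensemble fusion: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-rank ensemble fusion: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FuzzyRankFusion)
```

## The fusion model

The package combines the softmax outputs of `X` probabilistic classifiers
on a `Y`-class problem. Its core assumption is that a classifier's softmax
row is a usable per-sample confidence signal: not necessarily calibrated,
but monotone in the classifier's actual confidence, and summing to one.
Nothing about the classifiers themselves is modelled — they enter only
through their decision-score matrices.

The rank transform is the re-parameterized Gompertz curve. The general
Gompertz function `a·exp(−exp(d − k·t))` is a double-exponential sigmoid
(historically a mortality model, now common for tumour and population
growth); the fusion uses its reflection

$$FR(dc) = 1 - e^{-e^{-2\,dc}},\qquad dc \in [0,1],$$

which maps confidence to a *rank value*: strictly decreasing, with
`FR(1) ≈ 0.1266` and `FR(0) = 1 − e^{−1} ≈ 0.6321`. Two properties make
it attractive over a linear re-scaling: the curve never reaches zero (a
confident prediction keeps a non-trivial rank value, mirroring the fact
that softmax scores of deep networks never reach exact zero), and its
slope is steepest in the mid-confidence region, so it spreads apart the
scores where classifiers actually disagree.

Per sample, each classifier's classes are ordered by ascending rank value
(descending confidence) and only the `m` best are *retained*. For class
`y` the fused quantities are

$$FRSum_y = \sum_n \begin{cases} FR^n_y & \text{retained} \\ 1-e^{-1} & \text{otherwise,} \end{cases}
\qquad
CCFSum_y = 1 - \frac{1}{X}\sum_n \begin{cases} DC^n_y & \text{retained} \\ 0 & \text{otherwise,} \end{cases}$$

and the prediction is `argmin_y FRSum_y · CCFSum_y`. A class outside
every classifier's top-`m` scores exactly `X·(1−e^{−1})·1`, while a class
retained everywhere with confidence at least `δ > 0` scores at most
`X·FR(δ)·(1−δ) < X·(1−e^{−1})`, so a fully penalized class can never win
against a uniformly retained, positively confident one. This inequality
is kept exact by storing the rank penalty as the closed form `1 − e^{−1}`
rather than the rounded 0.632.

### The complement in `CCFSum`

The uncomplemented variant `CCFSum_y = (1/X)·Σ contrib` — the confidence
sum itself rather than its complement — is self-defeating under an argmin
rule: a class penalized by every classifier would have a confidence sum
of 0, hence a fused score of 0, and would *always* win. The complemented
form restores the intended semantics (penalties prevent a class from
winning) and is the package default; the uncomplemented variant remains
available as `gompertzParams(literalCCF = TRUE)` for comparison, and the
test suite documents its pathological behaviour.

## Comparator ensembles

**Weighted average** fuses with `argmax_y Σ w_n DC^n_y / Σ w_n`. Weights
default to the classifiers' validation accuracies (the CLI measures them
on the supplied labels file when no explicit weights are given); uniform
and user-supplied weights are also supported. This is the canonical
static ensemble: weights are fixed across samples.

**Sugeno integral** computes, per class, `max_k min(DC^{(k)}, g(A_k))`
over the descending-sorted classifier scores, where `A_k` is the set of
the `k` top scorers and `g` a λ-fuzzy measure. The measure is built from
per-classifier fuzzy densities; since accuracies can equal or exceed
bounds, they are rescaled as `g_n = a_n / (max a_n + 10^{-6})` to lie
strictly in `(0, 1)`. λ is the unique root greater than −1 of
`1 + λ = Π (1 + λ g_n)`, which normalizes the full set to measure 1; a
single classifier degenerates to `g({1}) = 1`. Note that with densities
this close to 1 the measure of *any* non-empty subset approaches 1 and
the integral approaches the per-class maximum over classifiers — an
intrinsic property of accuracy-derived densities for strong classifiers,
not a defect of the solver.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `topM` | 2 | classes retained per classifier (dimensionless count, `1 ≤ m ≤ Y`). For `Y = 3` this penalizes exactly the weakest class. The originating method leaves `m` unstated; 2-of-3 is the only choice that exercises the penalty without silencing a majority of classes, and it should be confirmed per application. |
| `literalCCF` | `FALSE` | use the uncomplemented confidence sum (see above). |
| `a, d, k` | 1, 0, 2 | Gompertz constants; fixed to the re-parameterized form. |
| `tol` (validation) | `1e-6` | unit-sum tolerance; admits single-precision softmax rows. |
| weights / densities | validation accuracies | fusion weights for the comparators. How validation accuracy is measured (split, metric) is the caller's choice; the package accepts any non-negative weights. |

Tie-breaks are deterministic throughout: ties in confidence within a
classifier's row are broken by ascending class index, and ties in the
fused score across classes by lowest class index. Class indices are
1-based internally (the natural R convention); class *names* are carried
alongside and used in all file formats, so external semantics do not
depend on index origin.

## The synthetic generator

`generateScores()` emulates a panel of classifiers on a balanced test
set: labels uniform over `Y`; per (sample, classifier) a Dirichlet score
row whose peak concentration sits on the true class with probability
`targetAccuracy` and on a uniformly chosen wrong class otherwise. The
default concentrations (peak 8, base 0.8) give rows whose winning class
typically carries ~0.8 of the mass — confident but not saturated, like a
well-trained network away from saturation. An optional
`correlation` parameter lets classifiers copy a shared latent peak draw,
emulating correlated errors; it defaults to 0 (independent errors).

`referenceConfig()` pins the documented study setting: `N = 1030`
(a 30% test split of three balanced 1,145-image classes), `X = 4`
classifiers with target accuracies (0.961, 0.962, 0.963, 0.968), `Y = 3`
classes named normal/benign/malignant, seed 1812.

What the generator does *not* emulate: inter-classifier error
correlation (real networks trained on the same data share failure
modes), per-class difficulty structure (confusions are uniform over
wrong classes), and miscalibration patterns specific to architectures.
Consequently, passing tests on synthetic panels demonstrate correctness
of the fusion arithmetic and sane ensemble behaviour under independent
errors; they do not certify accuracy gains on any real imaging panel.
Indeed, with independent errors all reasonable fusion rules approach the
same ceiling: at the reference configuration the fuzzy-rank ensemble and
the weighted average typically differ by at most a couple of samples in
either direction, so the two are statistically indistinguishable there —
separating them requires the correlated, heteroscedastic errors of real
classifier panels.

## Numerical choices

* **Rank penalty** stored as `1 − exp(−1)`, not 0.632 (exact dominance).
* **λ root-finding**: bracketed `uniroot` refined by bisection to
  `|f(λ)| ≤ 10^{-10}`. With densities near 1 the root lies within machine
  epsilon of −1, so the bracket starts at −1 itself, where
  `f(−1) = Π(1 − g_n) > 0` is guaranteed; the returned root is clamped to
  be strictly greater than −1. Densities summing to 1 within `10^{-9}`
  short-circuit to λ = 0.
* **Zero denominators** in per-class metrics (a class never predicted,
  or absent from the truth) yield 0 with a warning, keeping batch tables
  total.
* **Strict unit-sum checks** allow an additive slack of 64 machine
  epsilons so a deviation of exactly the tolerance is accepted.
* **CSV output** prints scores with 6 significant digits; the CLI
  therefore renormalizes rows on input by default (`--normalize strict`
  restores hard checking, as used for freshly produced softmax files).
* **Degenerate inputs**: empty tensors, `Y < 2`, non-finite or negative
  scores, zero-sum rows and all-zero weights are rejected at
  construction with specific messages.

## Problem sizes in the test suite

Oracle-equivalence checks run 1,000 random instances at `X ≤ 3`,
`Y ≤ 4` against independent loop/brute-force implementations (the Sugeno
route enumerates all `2^X − 1` subsets); penalty-dominance and
degeneracy properties use 1,000-sample tensors; generator calibration
uses 10,000 samples for binomial checks; the ensemble-level regression
runs ten seeded replicates of the full 1,030-sample reference panel.
These sizes give stable statistics while keeping the default suite quick
on a single CPU.

## Known limitations

* The fusion consumes probabilities as given; no calibration is applied
  or checked.
* `m` must be chosen by the user for `Y ≠ 3`; there is no data-driven
  selection.
* The Sugeno comparator with accuracy-derived densities collapses toward
  a per-class max for uniformly strong panels (see above).
* Synthetic benchmarks bound what can be claimed about real data — see
  the generator section.
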