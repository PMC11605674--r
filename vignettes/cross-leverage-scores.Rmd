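---
title: "Cross leverage scores: model, approximations, and design notes"
author: "crossLeverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross leverage scores: model, approximations, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossLeverage)
```

## The statistic and why it sees interactions

Univariate screening ranks each variable by its own association with
the response. A variable that influences the response only through an
interaction can be invisible to such a screen: in the package's toy
dataset (`toyDataset()`), the response is `(x1 & x2) | (x3 & x4)` and
the design is balanced so that `cor(x1, y)` and `cor(x2, y)` are
*exactly* zero.

The cross leverage score takes the multivariate view. With the
variables as rows and the response appended,
$\tilde{X} = [X, y]^T \in \mathbb{R}^{\tilde{p}\times n}$,
$\tilde{p} = p + 1$, let $Q$ be an orthonormal basis of the column
space of $\tilde{X}$. The hat matrix $H = QQ^T$ is the orthogonal
projector onto that space; its diagonal entries are the classical
leverage scores, and the off-diagonal entries of the response column,

$$c_{i\tilde{p}} = \langle Q_{i\cdot}, Q_{\tilde{p}\cdot}\rangle
  = H[i, \tilde{p}],$$

measure the leverage each variable exerts on the response *within the
subspace spanned by all variables jointly*. An interacting variable
shifts that subspace even without a marginal effect, so its score is
pulled away from zero, while pure noise concentrates near zero. The
scores also approximate the coefficients of the minimum-norm least
squares solution when the row space is well aligned with the response;
`clsOLSGap()` reports the observed gap together with an alignment
diagnostic ($h_y^2/\sum_i c_i^2$, which equals $h_y/(1-h_y)$ at full
rank) rather than asserting a bound, because the constant in the
theoretical statement is not pinned down sharply.

No centering, scaling, or intercept is applied: the statistic is a
property of the raw column space, and the toy example's exact zero
correlations rely on the raw 0/1 values. A binary response enters as
numeric 0/1; real-valued responses are accepted unchanged.

```{r toy}
d <- toyDataset(seed = 1)
c(cor(d@X[, 1], d@y), cor(d@X[, 2], d@y))
round(exactCLS(d@X, d@y)@scores[1:4], 4)
```

## Numerical choices in the exact computation

* **Basis.** Thin QR when $\tilde{X}$ has full numerical column rank
  $n$. The scores are then obtained without materializing $Q$: with
  $\tilde{X}P = QR$, the response column of $H$ is
  $\tilde{X}P\,(R^TR)^{-1}(\tilde{X}P)_{\tilde{p}\cdot}^T$, applied by
  two triangular back-substitutions — the dominant cost stays the QR
  factorization itself.
* **Rank deficiency.** When the QR rank falls below $n$ (duplicated
  samples, tiny windows), the basis falls back to the SVD truncated at
  $\mathrm{tol} = \max(\tilde{p},n)\,\varepsilon_{mach}\,\sigma_{max}$.
  The projector onto the column space is unique, so the scores do not
  depend on which basis realizes it; orthonormality of $Q$ and the
  projector identity $\sum_i c_i^2 = h_y(1 - h_y)$ are enforced by the
  test suite at $10^{-10}$ and $10^{-8}$ respectively.
* **Sign conventions** of QR/SVD are irrelevant by construction: the
  scores are dot products of rows of the *same* basis.

## Selection

`defaultQ(n)` $= \lceil n\ln n\rceil$ (575 at $n = 120$; 45 at
$n = 16$): an $n \log n$ oversampling, motivated by the coupon
collector's problem, so that the selected submatrix retains rank $n$
with good probability. Ranking ties are broken by ascending variable
index, which makes selections deterministic and prefix-nested in $q$.

The default ranking key is the **absolute** score: when the *absence*
of an interaction pattern drives the disease (the `negative` scenario
preset), the important variables attain largely negative scores, and a
signed ranking would discard them. The signed ranking (`mode =
"largest"`) is the right choice when effects are known to be positive,
and is what reproduces the benchmark medians below. For the
correlation baseline the package ranks by absolute value as well; note
that a *signed* correlation ranking would make the toy comparison
meaningless (with $q = 45$ of $p = 60$, a zero correlation outranks
every negatively correlated noise variable, so the hidden pair would
be selected by default rather than by merit).

## The approximations and their parameters

**Sliding window** (`slidingWindowCLS`, parameter `w`, in variables):
consecutive blocks of `w` variables, each augmented with $y$ and
scored exactly; the last block absorbs `p %% w` leftovers (a runt
block would be rank deficient). `w` should be at least
$\lceil n\ln n\rceil$ so that each window's augmented matrix can reach
rank $n$; below that the function warns but proceeds, since the
benchmark parameterization itself (w = 200 at $n = 120$) sits below
the rule and still recovers the interactions. Exactly one block is
resident at a time, so file-backed sources (`tsvSource`) bound memory
by $O(wn)$.

**Random window** (`randomWindowCLS`, parameters `w`, `R`, `seed`):
`R` uniform draws of `w` distinct variables; per draw an exact
computation; per-variable merge keeps the score of largest magnitude
(signed value retained, `merge = "signed"` available). The default
$R = \mathrm{round}((p/w)\ln p)$ (`defaultNumWindows`) covers every
variable with good probability; uncovered variables keep the neutral
score 0, with a warning, and coverage counts are returned. Draws are
sorted (natural fetch order for block sources), so `w = p` reproduces
the exact scores bit for bit.

**Sketching** (`sketchCLS`, parameters `epsilon`, `r`, `s`, `seed`):
an OSNAP-style sparse embedding with exactly `s` nonzeros $\pm
1/\sqrt{s}$ per column, one per contiguous row block — the block
placement guarantees the fixed per-column count without collisions,
and unit column norms make $E[\Pi^T\Pi] = I$ while reducing to the
classical single-nonzero $\pm 1$ CountSketch at `s = 1`. Defaults:
$r = \lceil\lceil n\ln n\rceil/\varepsilon^2\rceil$
(`defaultSketchDim`; 2300 at $n = 120$, $\varepsilon = 0.5$) and
$s = \max(1, \lceil\log_2 n\rceil)$ (7 at $n = 120$) — the theory asks
for $O(\log n)$ nonzeros and leaves the base open. Pass 1 accumulates
$\Pi\tilde{X} \in \mathbb{R}^{r\times n}$ block by block; pass 2
applies $R^{\star-1}$ by triangular back-substitution per block (never
an explicit inverse), response row first. The additive guarantee
$|c_i - \hat{c}_i| \le \varepsilon$ holds with high probability over
the embedding; the test suite audits it empirically across seeds and
asserts a $\ge 90\%$ success rate rather than a certainty, since the
failure probability is not quantified sharply. When $r \ge \tilde{p}$
the sketch cannot compress and the function falls back to the exact
computation with a warning. Two implementation notes: the sparse
operator is built once ($s\tilde{p}$ nonzeros) rather than
regenerated per block, so the working state is $O(rn + s\tilde{p})$ —
the dense accumulator still dominates; and a rank-deficient sketch
raises an error advising a larger `r` or another seed.

## What the simulator emulates — and what it does not

`simulateGenotypes` draws a minor allele frequency $m_j \sim U(0.15,
0.45)$ per SNP and genotypes $\{0,1,2\}$ with Hardy–Weinberg
probabilities $((1-m)^2,\, 2m(1-m),\, m^2)$, independent across
samples and SNPs. Responses come from a logistic model whose linear
predictor is $\beta_0 + \sum_j \beta_j M_j$ with Boolean terms $M_j$:
conjunctions of *dominant* indicators (genotype $\ge 1$), optionally
negated. The scenario presets fix $\beta_0 = \log(0.3/0.7)$ (baseline
disease probability exactly 0.3) and interaction coefficients
$\log 50$ (disease probability $\approx 0.955$ given the pattern);
`weak_main` uses $\log 1.1$ for its marginal terms, a value chosen
here as "negligibly small" since no canonical value exists.

Deliberately **not** emulated: linkage disequilibrium or any
correlation between SNPs, population structure, missing genotypes,
and higher-order interaction presets (the generic `interactionModel`
supports arbitrary conjunctions, but no preset claims to match
unpublished result tables). Passing recovery tests on this generator
therefore demonstrates the method's behavior under independent,
HWE-clean genotypes — real panels with strong LD will spread leverage
across correlated neighbors, and the scores of tag SNPs should be
interpreted accordingly.

## Validation suite: problem sizes and expectations

The suite (see `tests/testthat/test-acceptance.R`) recomputes, among
others:

* the toy study — 1000 replicate toy datasets; median recovery of the
  correlation-blind pair is 2 of 2 under CLS ranking and 0 of 2 under
  correlation ranking at $q = 45$;
* scenario medians at $q = 575$, signed ranking — S1 at $p = 2000$
  and $p = 20000$ (101 replicates each, median 2 of 2), S2 at
  $p = 20000$ (101 replicates, median 3 of 4), and S1 at $p = 200000$
  (60 replicates, median at least 1 of 2); the replicate counts are
  the package's chosen desk-scale defaults, with seeds fixed in the
  tests;
* degenerate-configuration equivalences (`w = p` windows bit-identical
  to exact; identity embedding within $10^{-10}$), the sketch
  $\varepsilon$-guarantee audit, the SVD-pseudoinverse oracle
  comparison at $\tilde{p} \le 600$, and the calibration of the
  uniform baseline against its hypergeometric mean $kq/p$.

`scripts/acceptance.R` re-runs the S2/$p{=}20000$ experiment from
scratch (101 replicates) and writes the median recovery as JSON.

## Known limitations

* Scores are relative diagnostics, not test statistics: no p-values,
  no FDR control — the method is a screening step in front of an
  interaction-capable learner.
* The window heuristics carry no approximation guarantee; their
  fidelity is established empirically (rank agreement and recovery on
  the benchmark scenarios).
* For very large $p$ the recommended $q = \lceil n\ln n\rceil$ grows
  only with $n$; recovery at $p \gtrsim 2\times 10^5$ drops to one of
  two interacting SNPs in the median, and a larger $q$ is advisable
  there, though no automatic $p$-dependent rule is implemented.
* Exact scores at $p$ in the millions require the window or sketch
  paths; the direct QR is $\Theta(pn^2)$ time and $O(pn)$ memory.
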