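# crossLeverage

Screening for **interaction effects** in the p ≫ n regime — typically
SNP epistasis in case/control studies, where millions of genetic
variants but only a few hundred samples are available. Univariate
screens (per-variant correlation or association tests) are blind to
variables that act only through interactions: such a variable can have
marginal correlation exactly zero with the phenotype. `crossLeverage`
ranks variables by their **cross leverage score (CLS)**, a multivariate
quantity that remains nonzero for interacting variables, and scales the
computation to arbitrarily large p.

## The statistic

Stack the variables as rows and append the response, giving the
augmented matrix

```
X̃ = [X, y]ᵀ ∈ R^(p̃×n),   p̃ = p + 1 .
```

Let Q be an orthonormal basis of the column space of X̃ (thin QR
decomposition; SVD with a singular-value cutoff when X̃ is rank
deficient). The hat matrix H = QQᵀ projects onto that space, and the
cross leverage score of variable i is the off-diagonal entry coupling
it to the response row,

```
c_i = H[i, p̃] = ⟨Q_i·, Q_p̃·⟩ ,   i = 1, …, p ,
```

computed as row dot products without ever forming H. Selecting the
q = ⌈n ln n⌉ variables with the most extreme CLS retains the
interacting variables with high probability (the log factor is a
coupon-collector oversampling that preserves the rank of the selected
submatrix).

Three approximations make this workable when X̃ no longer fits in
memory:

* **Sliding window** — exact CLS on consecutive blocks of w variables
  (plus y), concatenated; one block resident at a time.
* **Random window** — repeated exact CLS on uniformly drawn w-subsets,
  merged by keeping each variable's largest-magnitude score;
  R ≈ (p/w)·ln p windows cover every variable with good probability.
* **Sketching** — a sparse oblivious subspace embedding
  Π ∈ R^(r×p̃) with s = O(log n) nonzeros ±1/√s per column compresses
  X̃ to ΠX̃ with r = ⌈⌈n ln n⌉/ε²⌉ rows; the QR factor R* of the sketch
  gives Ω = X̃R*⁻¹ ≈ Q, and the approximate scores
  ĉ_i = ⟨Ω_i·, Ω_p̃·⟩ satisfy |c_i − ĉ_i| ≤ ε with high probability,
  in two streaming passes and memory independent of p.

## Worked example

Simulate the S1 benchmark scenario — n = 120 samples, p = 2000 SNPs
with Hardy–Weinberg genotypes at MAF ~ U(0.15, 0.45), and a binary
response whose disease probability rises from 0.3 to ≈0.95 when the
pattern SNP1 ∧ SNP2 (dominant coding) is present:

```r
library(crossLeverage)

ds <- simulateScenario("s1", n = 120, p = 2000, seed = 42)
res <- exactCLS(ds@X, ds@y)
res
#> CLSResult (exact): 2000 variables, h_y = 0.03417
#>   largest |score|: SNP2=0.0216, SNP1=0.0151, SNP1939=0.0148, SNP188=-0.0138, SNP1350=-0.0133

sel <- topQ(clsScores(res), defaultQ(120), mode = "largest")
sel
#> SelectionResult: q = 575 of 2000 variables (mode largest)
#>   top: 2 1 1939 454 1990 1147 1056 289 1132 1133 ...

countRecovered(sel, truthVariables(ds))
#> [1] 2
```

The two interacting SNPs carry the two largest scores although neither
has a main effect in the generating model; both are recovered in the
top q = 575. The same run through the random-window approximation
(w = 575, R defaulting to 26):

```r
rw <- randomWindowCLS(ds@X, ds@y, w = 575, seed = 1)
countRecovered(topQ(clsScores(rw), 575, "largest"), truthVariables(ds))
#> [1] 2
```

A command-line interface covering simulation, scoring, selection and
evaluation is installed at `inst/scripts/cls-tool`
(`cls-tool simulate ... | cls-tool cls --method sketch --epsilon 0.5 ...`).

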