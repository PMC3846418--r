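# lapnb — Laplacianised naive Bayes for binary molecular fingerprints

`lapnb` is an R package for multi-class classification of chemical compounds
described by binary fingerprints (presence/absence of substructural
features), and — just as importantly — for deciding whether the popular
*present-features-only* shortcut to naive Bayes is actually safe on your
data.

## The problem

Ligand-based virtual screening routinely classifies compounds with a
Bernoulli naive Bayes model over fingerprints `x = (x_1, …, x_L)`,
`x_j ∈ {0, 1}`, where `L` can run to thousands of bits. A widely used
variant — the Laplacian Corrected Modified Naive Bayes (LCMNB) of Xia and
co-workers — speeds this up by scoring **only the features a compound has**
and silently discarding every absent-feature term. That shortcut is
heuristic: absence of a feature can carry real class information, and
nothing guarantees the discarded term is harmless. `lapnb` implements the
full model, the shortcut, and per-compound diagnostics that quantify the
gap between them.

## The model

For class `ω_i` (of `C`) and feature `j`, a per-class Beta(α_i, β_i) prior
on the Bernoulli parameter gives the smoothed conditional estimate (the
posterior mean)

    μ_ij = p(x_j = 1 | ω_i) = (N_ij + α_i) / (N_ωi + α_i + β_i),

where `N_ωi` counts training compounds in class `i` and `N_ij` counts those
with feature `j` present; `α = β = 1` is the classical add-one "Laplacian
correction". Bayes inversion yields per-feature class posteriors for
present and absent features,

    ξ_ij = p(ω_i | x_j = 1),    ν_ij = p(ω_i | x_j = 0),

each available in an **exact** form or a **simplified** large-class form

    ξ_ij ≈ (N_ij + α_i) / (N_j+ + Σ_k α_k),
    ν_ij ≈ (N_ωi − N_ij − α_i) / (N − N_j+ − Σ_k α_k),

valid when `N_ωi ≫ α_i + β_i`. A compound is scored with the
class-dependent discriminant, computed entirely in log space:

    D_i(x) = Σ_j x_j ln ξ_ij − ln p(ω_i) + Σ_j (1 − x_j) ln ν_ij − (L−1) ln p(ω_i).

The LCMNB estimator `ξ_ij = (N_ij + A_i)/(N_j+ + K)` with
`A_i = p(ω_i)·K` is *exactly* the simplified form with `α_i = A_i`, and the
LCMNB score is the first two terms of `D_i(x)` alone. The discarded
remainder,

    Δ_i(x) = Σ_j (1 − x_j) ln ν_ij − (L−1) ln p(ω_i),

cannot change any decision when, per compound, it is (i) zero, (ii) dwarfed
by the present-feature term, or (iii) constant across classes.
`check_conditions()` evaluates all three, runs both scorers, and reports a
safe / marginal / unsafe verdict with the observed decision agreement.

## Worked example

A small synthetic training set ships with the package:

```r
library(lapnb)

train <- read_fp_csv(system.file("extdata", "example_train.csv", package = "lapnb"))
fit <- fp_fit(train, mode = "exact", alpha = 1, beta = 1, prior = "empirical")
fit
#> <fp_model> mode = exact, C = 2 classes, L = 12 features, N = 30 compounds
#>   prior (empirical): 0.6, 0.4
#>   Beta prior: alpha = 1, 1, beta = 1, 1

p <- predict(fit, train)
p[1:4, ]
#> # A tibble: 4 x 5
#>   id    class label  tie   margin
#>   <chr> <int> <chr>  <lgl>  <dbl>
#> 1 cpd1      1 active FALSE   7.58
#> 2 cpd2      1 active FALSE  12.2
#> 3 cpd3      1 active FALSE  10.5
#> 4 cpd4      1 active FALSE  12.3
mean(p$class == train$labels)
#> [1] 1
```

`margin` is the best-minus-second-best discriminant gap, so `cpd1` is
assigned `active` with a log-score lead of 7.58 over `inactive`. Is the
present-features-only shortcut safe here?

```r
check_conditions(train, fit)
#> <fp_conditions> 30 compounds | verdict: SAFE | SNB/LCMNB agreement: 1.0000
#>   (i) zero      : 0/30 compounds (max |Delta| <= 1e-08)
#>   (ii) dominance: 0/30 compounds (ratio >= 10)
#>   (iii) constancy: 0/30 compounds (spread <= 1e-08)
```

No condition holds exactly — the discarded term is nonzero and varies
across classes — yet on this easy dataset both scorers make identical
decisions (agreement 1.0), hence the safe verdict. On datasets where
absence is informative the picture changes: `fp_disagreement()` builds one,
and `tidy(check_conditions(...))` pinpoints the flipped compounds. Use
`autoplot()` on the report, or `plot_score_comparison()`, to see them.

The simulator `fp_simulate()` draws class-conditional Bernoulli
fingerprints from named presets (`"separable"`, `"uninformative"`,
`"absence_informative"`, `"imbalanced"`) or any `C × L` probability matrix,
and is the basis of the test-suite fixtures.

## File formats and command line

- **Dense CSV**: header `id,label,f1,…,fL` (label optional), 0/1 cells.
- **Sparse list**: first line `L=<integer>`; then one compound per line,
  `id<TAB>label<TAB>j1 j2 …` with 1-based indices of present features
  (label `-` when unlabelled, empty index list allowed).
- **Model files**: versioned JSON; doubles stored as 17-digit decimal
  strings so a reloaded model scores bit-identically.

A CLI wraps the same functions (`fit`, `predict`, `diagnose`, `simulate`,
`compare`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lapnb", package = "lapnb"))')
Rscript $CLI simulate --preset absence_informative --sizes 40,40 --L 20 --seed 1 --out train.csv
Rscript $CLI fit --data train.csv --mode exact --model model.json
Rscript $CLI diagnose --model model.json --data train.csv --out report.json
```

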