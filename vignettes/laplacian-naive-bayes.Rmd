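---
title: "Methods: Laplacianised naive Bayes and the present-features-only shortcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Laplacianised naive Bayes and the present-features-only shortcut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapnb)
```

## Model and assumptions

A compound is a binary fingerprint $x = (x_1, \dots, x_L)$,
$x_j \in \{0, 1\}$, indicating presence of substructural features. The
classifier assumes class-conditional independence of the bits (naive
Bayes): within class $\omega_i$, $x_j \sim \mathrm{Bernoulli}(\mu_{ij})$
independently. This is the sole modelling assumption; real fingerprints
violate it (correlated substructures), but the decision rule is known to be
robust to moderate violations, and every guarantee this package tests is a
*mathematical identity under the model*, not an empirical claim about
chemistry.

### Smoothed conditional estimates

With a conjugate $\mathrm{Beta}(\alpha_i, \beta_i)$ prior per class, the
posterior-mean estimate from training counts is

$$\mu_{ij} = \frac{N_{ij} + \alpha_i}{N_{\omega_i} + \alpha_i + \beta_i},$$

where $N_{\omega_i}$ is the number of training compounds in class $i$ and
$N_{ij}$ the number of those with feature $j$ present. The default
$\alpha = \beta = 1$ is the uniform prior, i.e. the classical add-one
"Laplacian correction"; it guarantees $0 < \mu_{ij} < 1$ so logarithms are
finite, at the cost of shrinking estimates toward $1/2$. `estimate_mu()`
computes it; `beta_posterior_oracle()` recomputes the same quantity by
numerical quadrature of the normalised Beta posterior density and is used
by the test suite to validate the closed form (agreement below $10^{-8}$
over a grid of counts and hyperparameters).

### Per-feature class posteriors

Bayes inversion turns the conditionals into per-feature class posteriors
$\xi_{ij} = p(\omega_i \mid x_j = 1)$ and
$\nu_{ij} = p(\omega_i \mid x_j = 0)$. Three estimator modes are offered by
`fp_fit(mode = ...)`:

* **`"exact"`** — direct Bayes inversion,
  $\xi_{ij} = \mu_{ij}\,p(\omega_i) / \sum_k \mu_{kj}\,p(\omega_k)$ and the
  analogous $\nu_{ij}$ with $1 - \mu$. The absent-feature exact form is an
  implementation-added extension (a routine Bayes inversion the source
  derivation does not spell out); it is always well defined.
* **`"simplified"`** — the large-class approximation
  $\xi_{ij} = (N_{ij} + \alpha_i) / (N_{j+} + \sum_k \alpha_k)$ and
  $\nu_{ij} = (N_{\omega_i} - N_{ij} - \alpha_i) /
  (N - N_{j+} - \sum_k \alpha_k)$, where $N_{j+} = \sum_i N_{ij}$. Valid
  when $N_{\omega_i} \gg \alpha_i + \beta_i$; the two modes converge as the
  counts grow with the proportions fixed, which the test suite checks by
  scaling a fixture by 1, 10, and 100.
* **`"lcmnb"`** — the Laplacian Corrected Modified Naive Bayes estimator
  $\xi_{ij} = (N_{ij} + A_i)/(N_{j+} + K)$ with $A_i = p(\omega_i)\,K$.
  This is *algebraically identical* to the simplified form with
  $\alpha_i = A_i$ (the package tests the identity to a few ulp), so LCMNB
  is a choice of hyperparameters, not a different model. The binary
  special case $A = (K - 1, 1)$ corresponds to
  $p(\omega_1) = (K-1)/K$. `hyper_from_lcmnb()` performs the mapping; its
  $\beta$ defaults to 1 because the equivalence is independent of $\beta$
  (absent features never enter the LCMNB score).

**Degenerate regime.** The simplified $\nu_{ij}$ has numerator
$N_{\omega_i} - N_{ij} - \alpha_i$, which can be $\le 0$ when a feature is
present in (almost) every compound of a class — the approximation is then
outside its validity domain and would produce a non-probability. The
package refuses to clamp: `fp_fit(mode = "simplified")` raises the typed
error `lapnb_degenerate_feature` naming the offending class/feature cells
and pointing at `mode = "exact"`, which handles the same data without
issue.

## Scoring

All scoring is done in log space; probabilities are never multiplied. The
full discriminant for class $i$ is

$$D_i(x) = \underbrace{\sum_j x_j \ln \xi_{ij} - \ln p(\omega_i)}_{\text{present / LCMNB part}}
         + \underbrace{\sum_j (1 - x_j) \ln \nu_{ij} - (L - 1)\ln p(\omega_i)}_{\Delta_i(x),\ \text{discarded by LCMNB}}.$$

`score_snb()` computes $D$, `score_lcmnb()` the first bracket,
`absent_term()` the second, and the identity
$D_i = \text{LCMNB}_i + \Delta_i$ is asserted (to $10^{-12}$ relative)
every time `check_conditions()` runs. `score_snb_uniform()` is the
uniform-prior reduction that drops the prior terms; it differs from $D$ by
the class-constant $L\ln(1/C)$ and therefore ranks identically.
`likelihood_oracle()` scores with the raw Bernoulli log-likelihood
$\sum_j [x_j \ln \mu_{ij} + (1 - x_j)\ln(1 - \mu_{ij})]$; in exact mode
$D_i$ differs from it only by a term constant across classes, so the two
agree on every argmax — another identity the acceptance tests verify over
the full $2^{10}$ input cube at $L = 10$.

Decisions (`predict()`, `decide()`) take the argmax; a tie is declared
when the top two scores are within $10^{-12}$ and broken to the lowest
class index, deterministically. `rank = "posterior"` adds $\ln p(\omega_i)$
back to the discriminant; with non-uniform priors the discriminant argmax
is *not* the posterior-mode argmax (the discriminant subtracts $L$ prior
terms), so the option exists and the default is documented rather than
hidden.

A hard floor $\ln \max(p, 10^{-300})$ guards the logarithms; with the
mandatory positive hyperparameters no table entry can reach it, so it is a
defence against pathological user-supplied tables, not part of the model.

## When is discarding absent features safe?

`check_conditions()` evaluates, per compound, three sufficient conditions
under which $\Delta$ cannot change a decision:

1. **zero** — $\max_i |\Delta_i| \le$ `zero_tol` ($10^{-8}$): the term
   vanishes (e.g. every feature present under a uniform prior, the
   `fp_all_present()` fixture).
2. **dominance** — the present-feature score range exceeds the
   $\Delta$ range by at least `dominance_min` ($10\times$): the discarded
   term is too small to reorder the classes. This is a heuristic margin,
   not a proof, hence the conservative default.
3. **constancy** — $\max_i \Delta_i - \min_i \Delta_i \le$ `constancy_tol`
   ($10^{-8}$): a class-constant shift never changes an argmax.

The tolerances ($10^{-8}$ absolute for conditions tied to exact identities,
a factor 10 for the heuristic one) sit far above accumulated double-precision
rounding at realistic $L$ yet far below any score difference of practical
meaning; all are arguments of `check_conditions()` and are echoed in the
report. The verdict is **safe** if every compound satisfies (1) or (3), or
if the observed SNB/LCMNB decision agreement is exactly 1; **marginal** if
agreement $\ge 0.95$; otherwise **unsafe**.

## Synthetic data: what it does and does not emulate

`fp_simulate()` draws from the model itself — independent Bernoulli bits
per class — so it is the correct instrument for testing identities,
estimator consistency (parameter recovery at $2 \times 20{,}000$ compounds
is within $10^{-2}$), and engineered regimes. It does **not** emulate real
fingerprints: no bit correlations, no folding collisions, no heavy-tailed
feature frequencies. Conclusions about the *shortcut's safety on real
data* must come from running `check_conditions()` on that data, not from
the simulator.

The `"absence_informative"` preset deserves a note: its first half holds
sparse per-class presence markers (0.6 vs 0.05) and its second half a
dense block common in class 2 and rare in class 1 (0.9 vs 0.05), so for
class-1 compounds the discriminative signal is mostly the absence of the
dense block — precisely what the present-features-only scorer cannot see.
`fp_disagreement()` freezes a draw from this pattern on which the two
scorers provably disagree; the draw is a deterministic function of its
seed (sub-seeds are tried in order until the property holds).

## Problem sizes and cost

Everything is dense matrix algebra: fitting is $O(NL + CL)$, scoring
$O(NLC)$. The shipped tests exercise $L$ up to 1024 and $N$ up to 40,000;
the full suite runs in seconds on one core. For genuinely large sparse
fingerprints the sparse list reader keeps files small, but matrices are
densified internally — a deliberate simplicity/scale trade-off.

## Limitations

* Independence is assumed, never tested; use the diagnostics to compare
  scorers, not to validate the model itself.
* The dominance condition is a margin heuristic.
* Two-class presets only; multi-class simulation requires an explicit
  `mu`.
* Unlabelled data can be scored but not fitted; there is no
  semi-supervised machinery.
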