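#' Beta-smoothed class-conditional feature probabilities
#'
#' Posterior-mean estimate of `p(x_j = 1 | omega_i)` under a per-class
#' Beta(alpha_i, beta_i) prior and a Bernoulli likelihood:
#' `mu[i, j] = (N_present[i, j] + alpha_i) / (N_class[i] + alpha_i + beta_i)`.
#' With `alpha = beta = 1` this is add-one Laplacian smoothing. Every entry
#' is strictly inside (0, 1), so logarithms of both `mu` and `1 - mu` are
#' always finite.
#'
#' @param counts An `fp_counts` object.
#' @param hyper An `fp_hyper` object (defaults to Beta(1, 1) per class).
#' @return A `C x L` numeric matrix of probabilities.
#' @seealso [beta_posterior_oracle()] for a quadrature check of the same
#'   quantity.
#' @export
estimate_mu <- function(counts, hyper = beta_hyper(C = counts$C)) {
  stopifnot(inherits(counts, "fp_counts"), inherits(hyper, "fp_hyper"))
  if (length(hyper$alpha) != counts$C) {
    rlang::abort("hyperparameter length does not match the number of classes",
      class = "lapnb_input_error"
    )
  }
  (counts$N_present + hyper$alpha) / (counts$N_class + hyper$alpha + hyper$beta)
}

#' Posterior mean of a Beta-Bernoulli model by numerical integration
#'
#' Computes `E[mu | data]` for a single (class, feature) cell directly from
#' its definition: the normalized integral of
#' `mu * mu^(N_ij + alpha - 1) * (1 - mu)^(N_class - N_ij + beta - 1)` over
#' \[0, 1\]. This deliberately avoids the closed form
#' `(N_ij + alpha) / (N_class + alpha + beta)` so it can serve as an
#' independent check of [estimate_mu()]; it is intended for tests, not for
#' fitting.
#'
#' @param n_ij Number of compounds in the class with the feature present.
#' @param n_class Number of compounds in the class (`n_ij <= n_class`).
#' @param alpha,beta Positive Beta prior shapes.
#' @return The posterior mean, a probability.
#' @export
beta_posterior_oracle <- function(n_ij, n_class, alpha = 1, beta = 1) {
  stopifnot(n_ij >= 0, n_class >= n_ij, alpha > 0, beta > 0)
  a <- n_ij + alpha
  b <- n_class - n_ij + beta
  # normalized posterior density keeps the integrand O(1); splitting the
  # interval at the density's peak keeps adaptive quadrature stable when the
  # posterior is sharply concentrated
  dens <- function(mu) stats::dbeta(mu, a, b)
  split <- if (a + b > 2) min(max((a - 1) / (a + b - 2), 0.1), 0.9) else 0.5
  piece <- function(f, lo, hi) {
    r <- stats::integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-13,
      subdivisions = 500L, stop.on.error = FALSE
    )
    if (!r$message %in% c("OK", "roundoff error was detected")) {
      rlang::abort(sprintf("quadrature did not converge: %s", r$message),
        class = "lapnb_quadrature_error"
      )
    }
    r$value
  }
  integrand <- function(mu) mu * dens(mu)
  num <- piece(integrand, 0, split) + piece(integrand, split, 1)
  den <- piece(dens, 0, split) + piece(dens, split, 1)
  num / den
}

#' Per-feature class posteriors, present and absent
#'
#' The four estimators of `p(omega_i | x_j)` used by the scorers, each
#' returning a `C x L` matrix whose columns sum to 1.
#'
#' `posterior_present_exact()` applies Bayes' theorem to the Beta-smoothed
#' conditionals: `xi[i, j] = mu[i, j] p(omega_i) / sum_k mu[k, j] p(omega_k)`.
#'
#' `posterior_present_simplified()` is its large-class limit (valid when
#' `N_class[i] >> alpha_i + beta_i`, as in large chemical datasets):
#' `xi[i, j] = (N_present[i, j] + alpha_i) / (N_feat[j] + sum(alpha))`.
#'
#' `posterior_present_lcmnb()` is the Xia et al. estimator
#' `(N_present[i, j] + A_i) / (N_feat[j] + K)` with `A_i = p(omega_i) K`;
#' it is algebraically identical to the simplified form with
#' `alpha = hyper_from_lcmnb(prior, K)$alpha`.
#'
#' `posterior_absent_simplified()` is the matching large-class estimator for
#' absent features,
#' `nu[i, j] = (N_class[i] - N_present[i, j] - alpha_i) / (N - N_feat[j] - sum(alpha))`.
#' When a feature is present in (almost) every compound of a class the
#' numerator or denominator can go non-positive — the large-class assumption
#' has failed — and the function raises a typed `lapnb_degenerate_feature`
#' error listing the offending cells rather than fabricating a probability;
#' use the exact form in that regime.
#'
#' `posterior_absent_exact()` is the always-well-defined Bayes inversion
#' `nu[i, j] = (1 - mu[i, j]) p(omega_i) / sum_k (1 - mu[k, j]) p(omega_k)`.
#' The source formulation only derives the simplified absent-feature
#' estimator; this exact analogue is an extension provided by this package.
#'
#' @param counts An `fp_counts` object.
#' @param hyper An `fp_hyper` object.
#' @param prior An `fp_prior` object.
#' @param K Positive LCMNB smoothing constant.
#' @return A `C x L` matrix with unit column sums.
#' @name posteriors
NULL

#' @rdname posteriors
#' @export
posterior_present_exact <- function(counts, hyper, prior) {
  mu <- estimate_mu(counts, hyper)
  w <- mu * prior$probs
  sweep(w, 2L, colSums(w), "/")
}

#' @rdname posteriors
#' @export
posterior_present_simplified <- function(counts, hyper) {
  stopifnot(inherits(counts, "fp_counts"), inherits(hyper, "fp_hyper"))
  num <- counts$N_present + hyper$alpha
  sweep(num, 2L, counts$N_feat + sum(hyper$alpha), "/")
}

#' @rdname posteriors
#' @export
posterior_present_lcmnb <- function(counts, prior, K) {
  stopifnot(inherits(counts, "fp_counts"), inherits(prior, "fp_prior"))
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    rlang::abort("K must be a single positive number", class = "lapnb_input_error")
  }
  a <- prior$probs * K
  sweep(counts$N_present + a, 2L, counts$N_feat + K, "/")
}

#' @rdname posteriors
#' @export
posterior_absent_simplified <- function(counts, hyper) {
  stopifnot(inherits(counts, "fp_counts"), inherits(hyper, "fp_hyper"))
  num <- counts$N_class - (counts$N_present + hyper$alpha)
  den <- counts$N - (counts$N_feat + sum(hyper$alpha))
  bad_num <- which(num <= 0, arr.ind = TRUE)
  bad_den <- which(den <= 0)
  if (nrow(bad_num) > 0L || length(bad_den) > 0L) {
    cells <- character(0)
    if (nrow(bad_num) > 0L) {
      cells <- apply(utils::head(bad_num, 10L), 1L, function(rc) {
        sprintf("(class %d, feature %d)", rc[1L], rc[2L])
      })
    }
    rlang::abort(
      paste0(
        "degenerate feature for the simplified absent-feature estimator: ",
        "features present in (nearly) all compounds of a class make its ",
        "numerator or denominator non-positive",
        if (length(cells)) paste0(" at ", paste(cells, collapse = ", ")) else "",
        if (length(bad_den)) sprintf("; non-positive denominator for %d feature(s)", length(bad_den)) else "",
        ". The large-class assumption behind the simplified form does not hold here; ",
        "refit with mode = \"exact\"."
      ),
      class = "lapnb_degenerate_feature",
      cells = bad_num, features = bad_den
    )
  }
  sweep(num, 2L, den, "/")
}

#' @rdname posteriors
#' @export
posterior_absent_exact <- function(counts, hyper, prior) {
  mu <- estimate_mu(counts, hyper)
  w <- (1 - mu) * prior$probs
  sweep(w, 2L, colSums(w), "/")
}

# log with a floor far below anything reachable for valid inputs; guards
# only against floating-point underflow in pathological hyperparameters
log_floor <- function(p) {
  pmax(log(p), log(1e-300))
}

#' Fit a Laplacianised naive Bayes fingerprint model
#'
#' Estimates the per-feature class posteriors from a labelled dataset and
#' stores them (in log space) ready for scoring. Three estimator modes:
#'
#' * `"exact"` — Bayes inversion of the Beta-smoothed conditionals for both
#'   present (`xi`) and absent (`nu`) features; always well-defined.
#' * `"simplified"` — the large-class-count approximations for `xi` and
#'   `nu`; raises a typed `lapnb_degenerate_feature` error when a feature is
#'   present in (nearly) every compound of a class (see [posteriors]).
#' * `"lcmnb"` — the Xia et al. present-feature estimator with smoothing
#'   constant `K`; no absent-feature table is built, so the fitted model can
#'   only be scored with the present-features-only scorer.
#'
#' @param data A labelled `fp_data` object, or a data frame that
#'   [as_fp_data()] understands.
#' @param mode Estimator mode, one of `"exact"`, `"simplified"`, `"lcmnb"`.
#' @param alpha,beta Beta prior shapes, recycled per class (ignored in
#'   `"lcmnb"` mode, where `K` plays their role).
#' @param prior `"empirical"` (class frequencies) or `"uniform"`.
#' @param K Smoothing constant for `"lcmnb"` mode; defaults to the number of
#'   classes, the plain add-one case under a uniform prior.
#' @return An object of class `fp_model` with components `counts`, `hyper`,
#'   `prior`, `mode`, `K`, `xi`, `nu` (`NULL` in lcmnb mode), `log_xi`,
#'   `log_nu`, `levels`, `L`, `C`.
#' @examples
#' d <- fp_simulate(class_sizes = c(100, 100), L = 16, preset = "separable", seed = 7)
#' fit <- fp_fit(d, mode = "exact")
#' predict(fit, d)
#' @export
fp_fit <- function(data, mode = c("exact", "simplified", "lcmnb"),
                   alpha = 1, beta = 1,
                   prior = c("empirical", "uniform"), K = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(data)) data <- as_fp_data(data)
  counts <- count_statistics(data)
  prior <- if (inherits(prior, "fp_prior")) prior else class_prior(counts, match.arg(prior))

  if (mode == "lcmnb") {
    if (is.null(K)) K <- counts$C
    hyper <- hyper_from_lcmnb(prior, K)
    xi <- posterior_present_lcmnb(counts, prior, K)
    nu <- NULL
  } else {
    hyper <- beta_hyper(alpha, beta, C = counts$C)
    K <- NULL
    if (mode == "exact") {
      xi <- posterior_present_exact(counts, hyper, prior)
      nu <- posterior_absent_exact(counts, hyper, prior)
    } else {
      xi <- posterior_present_simplified(counts, hyper)
      nu <- posterior_absent_simplified(counts, hyper)
    }
  }

  structure(
    list(
      counts = counts, hyper = hyper, prior = prior, mode = mode, K = K,
      xi = xi, nu = nu,
      log_xi = log_floor(xi), log_nu = if (is.null(nu)) NULL else log_floor(nu),
      levels = counts$levels, L = counts$L, C = counts$C
    ),
    class = "fp_model"
  )
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf(
    "<fp_model> mode = %s, C = %d classes, L = %d features, N = %d compounds\n",
    x$mode, x$C, x$L, x$counts$N
  ))
  cat(sprintf(
    "  prior (%s): %s\n", x$prior$mode,
    paste(format(x$prior$probs, digits = 4), collapse = ", ")
  ))
  if (x$mode == "lcmnb") {
    cat(sprintf("  K = %g (A_i = %s); absent-feature table not built\n",
      x$K, paste(format(x$hyper$alpha, digits = 4), collapse = ", ")
    ))
  } else {
    cat(sprintf(
      "  Beta prior: alpha = %s, beta = %s\n",
      paste(format(x$hyper$alpha, digits = 4), collapse = ", "),
      paste(format(x$hyper$beta, digits = 4), collapse = ", ")
    ))
  }
  invisible(x)
}
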