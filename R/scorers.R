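# Coerce a scoring input into an N x L 0/1 integer matrix matched to a model
score_input <- function(x, model) {
  if (inherits(x, "fp_data")) {
    ids <- x$ids
    x <- x$x
  } else if (is.data.frame(x)) {
    d <- as_fp_data(x)
    ids <- d$ids
    x <- d$x
  } else {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("cpd", seq_len(nrow(x)))
    if (!all(x == 0 | x == 1)) {
      rlang::abort("fingerprints must be 0/1", class = "lapnb_nonbinary_error")
    }
  }
  if (ncol(x) != model$L) {
    rlang::abort(
      sprintf("fingerprint length %d does not match the model's %d features", ncol(x), model$L),
      class = "lapnb_shape_error"
    )
  }
  list(x = x, ids = ids)
}

#' Class-dependent discriminant scores
#'
#' Per-compound, per-class scores of the naive Bayes model, computed as pure
#' log-domain sums (no exponentiation anywhere, so fingerprints with
#' thousands of features cannot underflow). All four scorers accept a single
#' 0/1 vector, an `N x L` matrix, or an `fp_data` object, and return an
#' `N x C` matrix.
#'
#' `score_snb()` is the full discriminant
#' \deqn{D_i(x) = \sum_j x_j \ln \xi_{ij} - \ln p(\omega_i)
#'       + \sum_j (1 - x_j) \ln \nu_{ij} - (L - 1) \ln p(\omega_i),}
#' i.e. `sum_j ln p(omega_i | x_j) - L ln p(omega_i)`: the log posterior odds
#' against the prior, up to a class-independent shift. Maximizing it ranks
#' classes by `p(omega_i | x) / p(omega_i)`, which is likelihood (not
#' posterior) ranking; the two coincide under equal priors. Set
#' `rank = "posterior"` in [predict.fp_model()] to add back `ln p(omega_i)`
#' and rank by the posterior instead.
#'
#' `score_snb_uniform()` is the uniform-prior reduction that drops the
#' class-constant prior terms entirely; it differs from `score_snb()` by
#' exactly `L * ln(1/C)` in every cell and is only valid for models built
#' with a uniform prior.
#'
#' `score_lcmnb()` keeps only the present-feature part,
#' `sum_j x_j ln xi_ij - ln p(omega_i)`; the absent-feature table is never
#' touched, so it is the one scorer available for lcmnb-mode models.
#'
#' `likelihood_oracle()` is the naive Bernoulli log-likelihood
#' `sum_j [x_j ln mu_ij + (1 - x_j) ln(1 - mu_ij)]` computed straight from
#' the class-conditional probabilities; in exact mode with an empirical
#' prior it differs from `score_snb()` only by a class-independent shift,
#' which makes it an independent check on the discriminant.
#'
#' @param x A 0/1 vector of length `L`, an `N x L` 0/1 matrix, or an
#'   `fp_data` object.
#' @param model A fitted `fp_model` (for `likelihood_oracle()` either a
#'   model or a bare `C x L` probability matrix `mu`).
#' @return An `N x C` numeric matrix of scores, classes in columns.
#' @name scorers
#' @examples
#' d <- fp_simulate(class_sizes = c(50, 50), L = 12, preset = "separable", seed = 3)
#' fit <- fp_fit(d, mode = "exact")
#' head(score_snb(d, fit))
NULL

#' @rdname scorers
#' @export
score_snb <- function(x, model) {
  stopifnot(inherits(model, "fp_model"))
  if (is.null(model$log_nu)) {
    rlang::abort(
      "this model was fitted in lcmnb mode and has no absent-feature table; use score_lcmnb()",
      class = "lapnb_mode_error"
    )
  }
  inp <- score_input(x, model)
  xm <- inp$x
  s <- xm %*% t(model$log_xi) + (1 - xm) %*% t(model$log_nu)
  s <- sweep(s, 2L, model$L * log(model$prior$probs), "-")
  dimnames(s) <- list(inp$ids, model$levels)
  s
}

#' @rdname scorers
#' @export
score_snb_uniform <- function(x, model) {
  stopifnot(inherits(model, "fp_model"))
  if (model$prior$mode != "uniform") {
    rlang::abort(
      "the prior-free reduction is only valid for models built with a uniform prior",
      class = "lapnb_mode_error"
    )
  }
  if (is.null(model$log_nu)) {
    rlang::abort(
      "this model was fitted in lcmnb mode and has no absent-feature table; use score_lcmnb()",
      class = "lapnb_mode_error"
    )
  }
  inp <- score_input(x, model)
  s <- inp$x %*% t(model$log_xi) + (1 - inp$x) %*% t(model$log_nu)
  dimnames(s) <- list(inp$ids, model$levels)
  s
}

#' @rdname scorers
#' @export
score_lcmnb <- function(x, model) {
  stopifnot(inherits(model, "fp_model"))
  inp <- score_input(x, model)
  s <- inp$x %*% t(model$log_xi)
  s <- sweep(s, 2L, log(model$prior$probs), "-")
  dimnames(s) <- list(inp$ids, model$levels)
  s
}

#' @rdname scorers
#' @export
likelihood_oracle <- function(x, model) {
  mu <- if (inherits(model, "fp_model")) estimate_mu(model$counts, model$hyper) else model
  stopifnot(is.matrix(mu), all(mu > 0), all(mu < 1))
  fake <- list(L = ncol(mu))
  if (!is.matrix(x) && !inherits(x, "fp_data") && !is.data.frame(x)) x <- matrix(x, nrow = 1L)
  inp <- score_input(x, fake)
  s <- inp$x %*% t(log(mu)) + (1 - inp$x) %*% t(log1p(-mu))
  rownames(s) <- inp$ids
  if (inherits(model, "fp_model")) colnames(s) <- model$levels
  s
}

#' Score a dataset with a fitted model, tidily
#'
#' Wraps the matrix scorers into a tibble with one row per compound and one
#' score column per class.
#'
#' @param model A fitted `fp_model`.
#' @param data Compounds to score (`fp_data`, matrix or data frame).
#' @param scorer One of `"snb"`, `"snb_uniform"`, `"lcmnb"`,
#'   `"likelihood_oracle"`.
#' @return A tibble with columns `id` and `score_<class>` for each class,
#'   carrying the scorer name in attribute `"scorer"`.
#' @export
fp_score <- function(model, data,
                     scorer = c("snb", "snb_uniform", "lcmnb", "likelihood_oracle")) {
  scorer <- match.arg(scorer)
  s <- switch(scorer,
    snb = score_snb(data, model),
    snb_uniform = score_snb_uniform(data, model),
    lcmnb = score_lcmnb(data, model),
    likelihood_oracle = likelihood_oracle(data, model)
  )
  out <- tibble::as_tibble(s, .name_repair = function(nm) paste0("score_", nm))
  out <- tibble::add_column(out, id = rownames(s), .before = 1L)
  attr(out, "scorer") <- scorer
  out
}

# argmax with deterministic tie-breaking to the lowest class index
decide <- function(scores, levels, tie_tol = 1e-12) {
  stopifnot(all(is.finite(scores)))
  n <- nrow(scores)
  lab <- integer(n)
  tie <- logical(n)
  margin <- numeric(n)
  for (r in seq_len(n)) {
    row <- scores[r, ]
    best <- which.max(row) # first maximum = lowest class index
    second <- if (length(row) > 1L) max(row[-best]) else -Inf
    lab[r] <- best
    margin[r] <- row[best] - second
    tie[r] <- is.finite(second) && (row[best] - second) < tie_tol
  }
  tibble::tibble(
    id = rownames(scores), class = lab,
    label = if (is.null(levels)) as.character(lab) else levels[lab],
    tie = tie, margin = margin
  )
}

#' Predict class labels for new fingerprints
#'
#' Scores each compound and assigns the class with the largest score. Ties
#' (top two scores within `1e-12`) break deterministically to the lowest
#' class index and are flagged. The default discriminant ranks classes by
#' likelihood, `p(x | omega_i)`; `rank = "posterior"` adds `ln p(omega_i)`
#' back so that classes are ranked by the posterior `p(omega_i | x)` — the
#' two differ only under unequal priors.
#'
#' @param object A fitted `fp_model`.
#' @param data Compounds to classify (`fp_data`, 0/1 matrix or data frame).
#' @param scorer `"snb"` (default; falls back to `"lcmnb"` for lcmnb-mode
#'   models), `"snb_uniform"` or `"lcmnb"`.
#' @param rank `"discriminant"` (default) or `"posterior"`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `class` (1-based index), `label`,
#'   `tie`, `margin` (best minus second-best score).
#' @export
predict.fp_model <- function(object, data,
                             scorer = c("snb", "snb_uniform", "lcmnb"),
                             rank = c("discriminant", "posterior"), ...) {
  scorer <- match.arg(scorer)
  rank <- match.arg(rank)
  if (object$mode == "lcmnb" && scorer == "snb") scorer <- "lcmnb"
  s <- switch(scorer,
    snb = score_snb(data, object),
    snb_uniform = score_snb_uniform(data, object),
    lcmnb = score_lcmnb(data, object)
  )
  if (rank == "posterior") s <- sweep(s, 2L, log(object$prior$probs), "+")
  decide(s, object$levels)
}
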