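#' Construct a binary fingerprint dataset
#'
#' Bundles an `N x L` binary feature matrix, optional class labels and
#' compound identifiers into a validated `fp_data` object, the input to all
#' fitting, scoring and diagnostic functions. Features must be exactly 0 or 1:
#' anything else is an error, never coerced, because the whole Bernoulli
#' formulation assumes binary descriptors.
#'
#' Class labels may be arbitrary strings or factors; internally they are
#' mapped to contiguous 1-based indices in order of first appearance, and the
#' mapping is carried along (and persisted in model files) so predictions are
#' reported on the original labels.
#'
#' @param features A data frame or matrix of 0/1 values, compounds in rows,
#'   features in columns. Column names, when present, name the features.
#' @param labels Optional vector of class labels, one per compound. Omit for
#'   prediction-only datasets.
#' @param ids Optional character vector of compound identifiers. Defaults to
#'   `cpd1, cpd2, ...`.
#' @param levels Optional character vector fixing the label-to-index mapping
#'   (useful to align a test set with a trained model). Defaults to first
#'   appearance order in `labels`.
#' @return An object of class `fp_data`: a list with elements `ids`,
#'   `x` (integer matrix), `labels` (integer indices or `NULL`),
#'   `levels` (character or `NULL`), `N`, `L`, `C`.
#' @examples
#' d <- fp_data(rbind(c(1, 0, 1), c(0, 0, 1)), labels = c("active", "inactive"))
#' d$N
#' @export
fp_data <- function(features, labels = NULL, ids = NULL, levels = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) {
    features <- matrix(features, nrow = 1L)
  }
  storage.mode(features) <- "double"
  bad <- which(!(features == 0 | features == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rlang::abort(
      sprintf(
        "non-binary feature value %s at compound %d, feature %d (entries must be exactly 0 or 1)",
        format(features[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L], bad[1L, 2L]
      ),
      class = "lapnb_nonbinary_error"
    )
  }
  storage.mode(features) <- "integer"
  n <- nrow(features)
  l <- ncol(features)
  if (n < 1L || l < 1L) {
    rlang::abort("a fingerprint dataset needs at least one compound and one feature",
      class = "lapnb_input_error"
    )
  }
  if (is.null(ids)) {
    ids <- paste0("cpd", seq_len(n))
  } else {
    ids <- as.character(ids)
    if (length(ids) != n) {
      rlang::abort("length of `ids` must match the number of compounds",
        class = "lapnb_input_error"
      )
    }
    if (anyDuplicated(ids)) {
      rlang::abort(sprintf("duplicate compound id '%s'", ids[duplicated(ids)][1L]),
        class = "lapnb_input_error"
      )
    }
  }
  if (is.null(colnames(features))) colnames(features) <- paste0("f", seq_len(l))
  rownames(features) <- NULL

  lab_idx <- NULL
  if (!is.null(labels)) {
    if (length(labels) != n) {
      rlang::abort("length of `labels` must match the number of compounds",
        class = "lapnb_input_error"
      )
    }
    labels <- as.character(labels)
    if (is.null(levels)) levels <- unique(labels)
    if (!all(labels %in% levels)) {
      rlang::abort(
        sprintf("label '%s' not among the declared class levels", setdiff(labels, levels)[1L]),
        class = "lapnb_input_error"
      )
    }
    lab_idx <- match(labels, levels)
  }

  structure(
    list(
      ids = ids, x = features, labels = lab_idx, levels = levels,
      N = n, L = l, C = if (is.null(levels)) NA_integer_ else length(levels)
    ),
    class = "fp_data"
  )
}

#' Coerce a tidy data frame into a fingerprint dataset
#'
#' Reads a data frame laid out one compound per row with an identifier
#' column, an optional label column, and the remaining columns as 0/1
#' features — the same layout [read_fp_csv()] produces.
#'
#' @param df A data frame.
#' @param id Name of the identifier column (default `"id"`); `NULL` for none.
#' @param label Name of the label column (default `"label"`); ignored when
#'   absent from `df`.
#' @inheritParams fp_data
#' @return An `fp_data` object.
#' @export
as_fp_data <- function(df, id = "id", label = "label", levels = NULL) {
  stopifnot(is.data.frame(df))
  ids <- NULL
  if (!is.null(id) && id %in% names(df)) {
    ids <- as.character(df[[id]])
    df[[id]] <- NULL
  }
  labels <- NULL
  if (!is.null(label) && label %in% names(df)) {
    labels <- df[[label]]
    df[[label]] <- NULL
  }
  fp_data(df, labels = labels, ids = ids, levels = levels)
}

#' @export
print.fp_data <- function(x, ...) {
  cat(sprintf(
    "<fp_data> %d compounds x %d features, %s\n", x$N, x$L,
    if (is.null(x$labels)) "unlabelled" else sprintf("%d classes (%s)", x$C, paste(x$levels, collapse = ", "))
  ))
  invisible(x)
}

#' Convert a fingerprint dataset to a tibble
#'
#' @param x An `fp_data` object.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (when present) and one column
#'   per feature.
#' @export
as_tibble.fp_data <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$x))
  if (!is.null(x$labels)) {
    out <- tibble::add_column(out, label = x$levels[x$labels], .before = 1L)
  }
  tibble::add_column(out, id = x$ids, .before = 1L)
}

#' Row-bind two fingerprint datasets
#'
#' Concatenates compounds from datasets over the same features. Class-level
#' mappings are merged (union, first-appearance order).
#'
#' @param a,b `fp_data` objects with identical feature counts.
#' @return A combined `fp_data` object.
#' @export
fp_bind <- function(a, b) {
  stopifnot(inherits(a, "fp_data"), inherits(b, "fp_data"))
  if (a$L != b$L) {
    rlang::abort("datasets have different feature counts", class = "lapnb_input_error")
  }
  labels <- NULL
  if (!is.null(a$labels) && !is.null(b$labels)) {
    labels <- c(a$levels[a$labels], b$levels[b$labels])
  }
  fp_data(rbind(a$x, b$x),
    labels = labels,
    ids = make.unique(c(a$ids, b$ids)),
    levels = if (!is.null(labels)) unique(c(a$levels, b$levels)) else NULL
  )
}

#' Sufficient statistics of a labelled fingerprint dataset
#'
#' Tabulates everything any of the estimators needs: the total compound count
#' `N`, per-class counts `N_class` (the number of training compounds in each
#' class), the `C x L` presence matrix `N_present` (compounds of class *i*
#' in which feature *j* equals 1), and the per-feature totals
#' `N_feat = colSums(N_present)`. Training requires every class to be
#' non-empty; an empty class is an error naming the class.
#'
#' @param data A labelled `fp_data` object.
#' @return An object of class `fp_counts`: list with `N`, `N_class`,
#'   `N_present`, `N_feat`, `C`, `L`, `levels`.
#' @examples
#' d <- fp_simulate(class_sizes = c(20, 20), L = 8, preset = "separable", seed = 1)
#' count_statistics(d)
#' @export
count_statistics <- function(data) {
  stopifnot(inherits(data, "fp_data"))
  if (is.null(data$labels)) {
    rlang::abort("dataset is unlabelled; counts require class labels",
      class = "lapnb_input_error"
    )
  }
  C <- data$C
  n_class <- tabulate(data$labels, nbins = C)
  if (any(n_class == 0L)) {
    empty <- which(n_class == 0L)[1L]
    rlang::abort(
      sprintf("class %d ('%s') has no training compounds", empty, data$levels[empty]),
      class = "lapnb_empty_class_error"
    )
  }
  n_present <- matrix(0L, nrow = C, ncol = data$L,
    dimnames = list(data$levels, colnames(data$x))
  )
  for (i in seq_len(C)) {
    n_present[i, ] <- as.integer(colSums(data$x[data$labels == i, , drop = FALSE]))
  }
  structure(
    list(
      N = data$N, N_class = n_class, N_present = n_present,
      N_feat = as.integer(colSums(n_present)), C = C, L = data$L, levels = data$levels
    ),
    class = "fp_counts"
  )
}

#' @export
print.fp_counts <- function(x, ...) {
  cat(sprintf(
    "<fp_counts> N = %d over %d classes (%s), L = %d features\n",
    x$N, x$C, paste(x$N_class, collapse = ", "), x$L
  ))
  invisible(x)
}

#' Elementwise sum of the counts of two disjoint datasets
#'
#' @param a,b `fp_counts` over the same classes and features.
#' @return The merged `fp_counts`.
#' @export
merge_counts <- function(a, b) {
  stopifnot(inherits(a, "fp_counts"), inherits(b, "fp_counts"))
  if (a$C != b$C || a$L != b$L) {
    rlang::abort("counts have mismatched dimensions", class = "lapnb_input_error")
  }
  structure(
    list(
      N = a$N + b$N, N_class = a$N_class + b$N_class,
      N_present = a$N_present + b$N_present, N_feat = a$N_feat + b$N_feat,
      C = a$C, L = a$L, levels = a$levels
    ),
    class = "fp_counts"
  )
}

#' Class prior distributions
#'
#' The empirical prior takes each class probability as its training
#' frequency, `N_class[i] / N`; the uniform prior sets every class to `1/C`.
#'
#' @param counts An `fp_counts` object.
#' @param mode `"empirical"` or `"uniform"`.
#' @return An object of class `fp_prior`: list with `probs` (summing to 1)
#'   and `mode`.
#' @export
class_prior <- function(counts, mode = c("empirical", "uniform")) {
  stopifnot(inherits(counts, "fp_counts"))
  mode <- match.arg(mode)
  probs <- switch(mode,
    empirical = counts$N_class / counts$N,
    uniform = rep(1 / counts$C, counts$C)
  )
  new_fp_prior(probs, mode)
}

new_fp_prior <- function(probs, mode) {
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-12) {
    rlang::abort("class prior must be strictly positive and sum to 1",
      class = "lapnb_input_error"
    )
  }
  structure(list(probs = probs, mode = mode), class = "fp_prior")
}

#' @rdname class_prior
#' @export
empirical_prior <- function(counts) class_prior(counts, "empirical")

#' @export
print.fp_prior <- function(x, ...) {
  cat(sprintf(
    "<fp_prior> %s: %s\n", x$mode,
    paste(format(x$probs, digits = 4), collapse = ", ")
  ))
  invisible(x)
}

#' Beta prior hyperparameters
#'
#' Per-class shape parameters `(alpha_i, beta_i)` of the Beta prior placed on
#' each class-conditional feature probability. Both must be strictly
#' positive; `alpha = beta = 1` (the default everywhere in the package) is
#' the uniform Beta(1, 1) prior, whose posterior-mean estimator is the
#' classical add-one Laplacian correction.
#'
#' @param alpha,beta Positive numerics, recycled to length `C`.
#' @param C Number of classes.
#' @return An object of class `fp_hyper`: list with length-`C` vectors
#'   `alpha` and `beta`.
#' @export
beta_hyper <- function(alpha = 1, beta = 1, C = length(alpha)) {
  alpha <- rep_len(as.numeric(alpha), C)
  beta <- rep_len(as.numeric(beta), C)
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) || any(alpha <= 0) || any(beta <= 0)) {
    rlang::abort("Beta hyperparameters must be finite and strictly positive",
      class = "lapnb_input_error"
    )
  }
  structure(list(alpha = alpha, beta = beta), class = "fp_hyper")
}

#' Map the LCMNB smoothing constant K to Beta hyperparameters
#'
#' The Xia et al. estimator smooths the feature-presence posterior with
#' per-class constants `A_i = p(omega_i) * K`, which sum to `K`. Setting
#' `alpha_i = A_i` makes the simplified Beta-smoothed posterior identical to
#' the LCMNB estimator, so this mapping embeds LCMNB in the Beta family. In
#' the original binary formulation `p(Active) = 1/K`, giving
#' `A = (K - 1, 1)`. `beta_i` is never used by the simplified
#' (present-feature) estimator, so the LCMNB construction leaves it free;
#' it defaults to 1 here so that exact-mode comparisons remain runnable, and
#' the chosen value is recorded in serialized models.
#'
#' @param prior An `fp_prior`.
#' @param K Positive smoothing constant.
#' @param beta Value used for the (unconstrained) `beta_i`; default 1.
#' @return An `fp_hyper` with `alpha = prior$probs * K`.
#' @examples
#' cnt <- count_statistics(fp_simulate(class_sizes = c(40, 20), L = 4, seed = 1))
#' hyper_from_lcmnb(empirical_prior(cnt), K = 3)
#' @export
hyper_from_lcmnb <- function(prior, K, beta = 1) {
  stopifnot(inherits(prior, "fp_prior"))
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    rlang::abort("K must be a single positive number", class = "lapnb_input_error")
  }
  beta_hyper(alpha = prior$probs * K, beta = beta, C = length(prior$probs))
}
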