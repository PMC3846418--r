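#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a fitted fingerprint model
#'
#' One row per (class, feature) cell with the fitted quantities: the
#' Beta-smoothed conditional `mu`, the present-feature posterior `xi` and,
#' when available, the absent-feature posterior `nu`.
#'
#' @param x A fitted `fp_model`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `feature`, `mu`, `xi`, `nu`.
#' @export
tidy.fp_model <- function(x, ...) {
  mu <- estimate_mu(x$counts, x$hyper)
  tibble::tibble(
    class = rep(x$levels, each = x$L),
    feature = rep(colnames(x$counts$N_present), times = x$C),
    n_present = as.vector(t(x$counts$N_present)),
    mu = as.vector(t(mu)),
    xi = as.vector(t(x$xi)),
    nu = if (is.null(x$nu)) NA_real_ else as.vector(t(x$nu))
  )
}

#' One-row summary of a fitted fingerprint model
#'
#' @param x A fitted `fp_model`.
#' @param ... Unused.
#' @return A one-row tibble with `mode`, `n`, `n_classes`, `n_features`,
#'   `prior_mode`, `K`, `alpha`, `beta` (hyperparameters collapsed to a
#'   comma-separated string when they differ across classes).
#' @export
glance.fp_model <- function(x, ...) {
  collapse <- function(v) {
    if (length(unique(v)) == 1L) format(v[1L]) else paste(format(v), collapse = ",")
  }
  tibble::tibble(
    mode = x$mode,
    n = x$counts$N,
    n_classes = x$C,
    n_features = x$L,
    prior_mode = x$prior$mode,
    K = if (is.null(x$K)) NA_real_ else x$K,
    alpha = collapse(x$hyper$alpha),
    beta = collapse(x$hyper$beta)
  )
}

#' Attach predictions to a dataset
#'
#' @param x A fitted `fp_model`.
#' @param data The compounds to classify.
#' @param ... Passed on to [predict.fp_model()].
#' @return The dataset as a tibble with prediction columns `.fitted_class`,
#'   `.fitted_label`, `.tie`, `.margin` appended.
#' @export
augment.fp_model <- function(x, data, ...) {
  if (!inherits(data, "fp_data")) data <- as_fp_data(as.data.frame(data))
  p <- predict(x, data, ...)
  dplyr::bind_cols(
    as_tibble(data),
    tibble::tibble(
      .fitted_class = p$class, .fitted_label = p$label,
      .tie = p$tie, .margin = p$margin
    )
  )
}

#' Tidy a condition report
#'
#' @param x An `fp_conditions` object.
#' @param ... Unused.
#' @return The per-compound tibble of condition verdicts.
#' @export
tidy.fp_conditions <- function(x, ...) x$compounds

#' One-row summary of a condition report
#'
#' @param x An `fp_conditions` object.
#' @param ... Unused.
#' @return A one-row tibble with the dataset-level verdict, the SNB/LCMNB
#'   agreement fraction, per-condition compound counts and the thresholds
#'   used.
#' @export
glance.fp_conditions <- function(x, ...) {
  cc <- x$compounds
  tibble::tibble(
    verdict = x$verdict,
    agreement = x$agreement,
    n_compounds = nrow(cc),
    n_zero_ok = sum(cc$zero_ok),
    n_dominance_ok = sum(cc$dominance_ok),
    n_constancy_ok = sum(cc$constancy_ok),
    n_disagreeing = sum(!cc$agree),
    zero_tol = x$thresholds$zero_tol,
    constancy_tol = x$thresholds$constancy_tol,
    dominance_min = x$thresholds$dominance_min
  )
}
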