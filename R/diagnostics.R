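#' The absent-feature contribution discarded by LCMNB
#'
#' For each compound and class, the part of the full discriminant that the
#' present-features-only scorer throws away:
#' \deqn{\Delta_i(x) = \sum_j (1 - x_j) \ln \nu_{ij} - (L - 1) \ln p(\omega_i).}
#' By construction `score_snb(x) = score_lcmnb(x) + absent_term(x)`
#' elementwise, so this matrix is exactly the SNB-vs-LCMNB score gap.
#'
#' @param x A 0/1 vector, `N x L` matrix or `fp_data` object.
#' @param model A fitted `fp_model` with an absent-feature table (exact or
#'   simplified mode).
#' @return An `N x C` matrix of `Delta` values.
#' @export
absent_term <- function(x, model) {
  stopifnot(inherits(model, "fp_model"))
  if (is.null(model$log_nu)) {
    rlang::abort(
      "lcmnb-mode models carry no absent-feature table, so the discarded term is unavailable",
      class = "lapnb_mode_error"
    )
  }
  inp <- score_input(x, model)
  d <- (1 - inp$x) %*% t(model$log_nu)
  d <- sweep(d, 2L, (model$L - 1) * log(model$prior$probs), "-")
  dimnames(d) <- list(inp$ids, model$levels)
  d
}

#' Fraction of compounds on which two prediction sets agree
#'
#' Compares assigned labels after tie-breaking.
#'
#' @param preds_a,preds_b Prediction tibbles from [predict.fp_model()] over
#'   the same compounds.
#' @return A fraction in \[0, 1\].
#' @export
fp_agreement <- function(preds_a, preds_b) {
  if (nrow(preds_a) != nrow(preds_b)) {
    rlang::abort("prediction sets cover different numbers of compounds",
      class = "lapnb_input_error"
    )
  }
  mean(preds_a$class == preds_b$class)
}

#' Is it safe to drop the absent-feature term? The three conditions
#'
#' Evaluates, per compound, the three conditions under which scoring only
#' the present features (LCMNB) provably reproduces the full naive Bayes
#' decision:
#'
#' * (i) *zero*: the discarded term vanishes, `max_i |Delta_i| <= zero_tol`;
#' * (ii) *dominance*: the kept present-feature term dwarfs the discarded
#'   one, `min_i |present_i| / max_i |Delta_i| >= dominance_min`;
#' * (iii) *constancy*: the discarded term is the same for every class,
#'   `max_i Delta_i - min_i Delta_i <= constancy_tol`, so it cannot change
#'   the argmax.
#'
#' Conditions (i) and (iii) are decision-exact guarantees; (ii) is a
#' heuristic "much greater than", quantified here as one order of magnitude
#' by default since no sharper definition exists. Compounds whose discarded
#' term is identically zero satisfy (i) and are excluded from the (ii)
#' ratio to avoid dividing by zero. The report also runs both scorers and
#' records the observed decision agreement.
#'
#' The dataset-level `verdict` is `"safe"` when every compound satisfies
#' (i) or (iii), or when the observed SNB/LCMNB agreement is 1;
#' `"marginal"` when agreement is at least 0.95; otherwise `"unsafe"`.
#'
#' @param data A dataset of fingerprints (`fp_data`, matrix or data frame).
#' @param model A fitted `fp_model` with an absent-feature table.
#' @param zero_tol Tolerance for condition (i). Default `1e-8`.
#' @param constancy_tol Tolerance for the spread in condition (iii).
#'   Default `1e-8`.
#' @param dominance_min Minimum ratio for condition (ii). Default `10`.
#' @return An object of class `fp_conditions`: list with a per-compound
#'   tibble `compounds` (columns `id`, `max_abs_delta`, `zero_ok`,
#'   `dominance_ratio`, `dominance_ok`, `spread`, `constancy_ok`,
#'   `snb_class`, `lcmnb_class`, `agree`), the `thresholds` used, the
#'   `agreement` fraction, and the `verdict`.
#' @examples
#' d <- fp_simulate(class_sizes = c(60, 60), L = 16, preset = "separable", seed = 2)
#' fit <- fp_fit(d, mode = "exact")
#' check_conditions(d, fit)
#' @export
check_conditions <- function(data, model, zero_tol = 1e-8,
                             constancy_tol = 1e-8, dominance_min = 10) {
  stopifnot(inherits(model, "fp_model"))
  if (any(c(zero_tol, constancy_tol, dominance_min) <= 0)) {
    rlang::abort("thresholds must be positive", class = "lapnb_input_error")
  }
  delta <- absent_term(data, model)
  lcm <- score_lcmnb(data, model)
  snb <- score_snb(data, model)
  # the decomposition is exact by construction; assert it on every run
  if (max(abs(snb - (lcm + delta))) > 1e-12 * max(1, max(abs(snb)))) {
    rlang::abort("internal error: score decomposition identity violated",
      class = "lapnb_internal_error"
    )
  }
  max_abs_delta <- apply(abs(delta), 1L, max)
  spread <- apply(delta, 1L, max) - apply(delta, 1L, min)
  min_abs_present <- apply(abs(lcm), 1L, min)
  dominance_ratio <- ifelse(max_abs_delta == 0, Inf, min_abs_present / max_abs_delta)

  zero_ok <- max_abs_delta <= zero_tol
  constancy_ok <- spread <= constancy_tol
  dominance_ok <- !zero_ok & dominance_ratio >= dominance_min

  p_snb <- decide(snb, model$levels)
  p_lcm <- decide(lcm, model$levels)
  agree <- p_snb$class == p_lcm$class
  agreement <- mean(agree)

  verdict <- if (all(zero_ok | constancy_ok) || agreement == 1) {
    "safe"
  } else if (agreement >= 0.95) {
    "marginal"
  } else {
    "unsafe"
  }

  structure(
    list(
      compounds = tibble::tibble(
        id = rownames(delta),
        max_abs_delta = max_abs_delta,
        zero_ok = zero_ok,
        dominance_ratio = dominance_ratio,
        dominance_ok = dominance_ok,
        spread = spread,
        constancy_ok = constancy_ok,
        snb_class = p_snb$class,
        lcmnb_class = p_lcm$class,
        agree = agree
      ),
      thresholds = list(
        zero_tol = zero_tol, constancy_tol = constancy_tol,
        dominance_min = dominance_min
      ),
      agreement = agreement,
      verdict = verdict,
      model_mode = model$mode,
      prior_mode = model$prior$mode
    ),
    class = "fp_conditions"
  )
}

#' @export
print.fp_conditions <- function(x, ...) {
  cc <- x$compounds
  cat(sprintf(
    "<fp_conditions> %d compounds | verdict: %s | SNB/LCMNB agreement: %.4f\n",
    nrow(cc), toupper(x$verdict), x$agreement
  ))
  cat(sprintf(
    "  (i) zero      : %d/%d compounds (max |Delta| <= %g)\n",
    sum(cc$zero_ok), nrow(cc), x$thresholds$zero_tol
  ))
  cat(sprintf(
    "  (ii) dominance: %d/%d compounds (ratio >= %g)\n",
    sum(cc$dominance_ok), nrow(cc), x$thresholds$dominance_min
  ))
  cat(sprintf(
    "  (iii) constancy: %d/%d compounds (spread <= %g)\n",
    sum(cc$constancy_ok), nrow(cc), x$thresholds$constancy_tol
  ))
  if (any(!cc$agree)) {
    cat(sprintf(
      "  disagreeing compounds: %s\n",
      paste(utils::head(cc$id[!cc$agree], 8L), collapse = ", ")
    ))
  }
  invisible(x)
}
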