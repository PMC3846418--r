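#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a condition report
#'
#' Scatter of each compound's discarded-term spread across classes
#' (condition (iii)) against the magnitude of its discarded term
#' (condition (i)), with compounds where the full and present-only
#' classifiers disagree highlighted. Compounds sitting on the dashed
#' tolerance lines or below are the ones for which dropping absent features
#' is provably harmless.
#'
#' @param object An `fp_conditions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_conditions <- function(object, ...) {
  cc <- object$compounds
  ggplot2::ggplot(
    cc,
    ggplot2::aes(
      x = .data$max_abs_delta, y = .data$spread,
      colour = .data$agree
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = object$thresholds$constancy_tol,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_vline(
      xintercept = object$thresholds$zero_tol,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f"),
      labels = c(`TRUE` = "agree", `FALSE` = "disagree"),
      name = "SNB vs LCMNB"
    ) +
    ggplot2::labs(
      x = "max over classes of |discarded term|",
      y = "spread of discarded term across classes",
      title = sprintf(
        "Absent-feature term diagnostics (verdict: %s, agreement %.3f)",
        object$verdict, object$agreement
      )
    ) +
    ggplot2::theme_minimal()
}

#' Compare full and present-only scores compound by compound
#'
#' Plots each compound's best-class SNB margin against its LCMNB margin;
#' points off the diagonal sign (one classifier confident, the other
#' choosing differently) are where the shortcut changes decisions.
#'
#' @param model A fitted `fp_model` with an absent-feature table.
#' @param data Compounds to score.
#' @return A ggplot object.
#' @export
plot_score_comparison <- function(model, data) {
  snb <- predict(model, data, scorer = "snb")
  lcm <- predict(model, data, scorer = "lcmnb")
  df <- tibble::tibble(
    id = snb$id,
    snb_margin = ifelse(snb$class == 1, 1, -1) * snb$margin,
    lcmnb_margin = ifelse(lcm$class == 1, 1, -1) * lcm$margin,
    agree = snb$class == lcm$class
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lcmnb_margin, .data$snb_margin, colour = .data$agree)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f"), name = "decisions agree"
    ) +
    ggplot2::labs(
      x = "LCMNB signed margin (class 1 vs rest)",
      y = "SNB signed margin (class 1 vs rest)"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the fitted per-feature class posteriors
#'
#' @param model A fitted `fp_model`.
#' @param table `"xi"` (present-feature posterior) or `"nu"`
#'   (absent-feature posterior).
#' @return A ggplot object.
#' @export
plot_posteriors <- function(model, table = c("xi", "nu")) {
  table <- match.arg(table)
  m <- model[[table]]
  if (is.null(m)) {
    rlang::abort("this model has no absent-feature table", class = "lapnb_mode_error")
  }
  df <- tidy(model) |>
    dplyr::select("class", "feature", value = dplyr::all_of(table)) |>
    dplyr::mutate(feature = factor(.data$feature, levels = colnames(model$xi)))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$class, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = table) +
    ggplot2::labs(x = "feature", y = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
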