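# Diagnostic figures. Each result type has a ggplot2 front end; nothing is
# drawn as a side effect.

#' Volcano plot of an EWAS table
#'
#' Absolute beta difference (binary phenotype) or M-scale coefficient
#' (continuous) against `-log10(q)`, with the significance threshold marked.
#'
#' @param object An `ewas_table`.
#' @param q_threshold Threshold line; default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ewas_table
#' @export
autoplot.ewas_table <- function(object, q_threshold = 0.05, ...) {
  binary <- identical(attr(object, "phenotype"), "binary")
  df <- dplyr::filter(as_tibble(object), !is.na(.data$q_value))
  df$effect <- if (binary) df$delta_beta_pp else df$coefficient_m
  df$significant <- df$q_value < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B"),
                                 name = sprintf("q < %g", q_threshold)) +
    ggplot2::labs(
      x = if (binary) "case - control methylation difference (pp)" else "M-value coefficient per mmol/mol",
      y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' Quadrant plot of directional concordance
#'
#' Scatter of the two analyses' coefficients for all doubly significant
#' sites, concordant sites coloured by quadrant, discordant sites marked.
#'
#' @param concordance A `concordance` object.
#' @param ewas_a,ewas_b The EWAS tables it was computed from.
#' @return A ggplot object.
#' @export
plot_concordance <- function(concordance, ewas_a, ewas_b) {
  ids <- c(concordance$both$probe_id, concordance$discordant$probe_id)
  df <- tibble(
    probe_id = ids,
    coef_a = ewas_a$coefficient_m[match(ids, ewas_a$probe_id)],
    coef_b = ewas_b$coefficient_m[match(ids, ewas_b$probe_id)],
    group = c(concordance$both$quadrant,
              rep("discordant", nrow(concordance$discordant)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coef_a, y = .data$coef_b,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up_up = "#B2182B", down_down = "#2166AC",
                                            discordant = "grey40")) +
    ggplot2::labs(x = "coefficient, analysis A (M per unit)",
                  y = "coefficient, analysis B (M per unit)") +
    ggplot2::theme_minimal()
}

#' Risk-score distributions by group
#'
#' @param scores Tibble from [compute_mrs()].
#' @param samples Sample table with `group`.
#' @return A ggplot object.
#' @export
plot_mrs <- function(scores, samples) {
  df <- dplyr::inner_join(scores, samples[, c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "methylation risk score (weighted %)") +
    ggplot2::theme_minimal()
}
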