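# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_line
#'   geom_point geom_errorbar geom_boxplot scale_fill_viridis_c
#'   scale_x_log10 labs facet_wrap theme_minimal coord_fixed
NULL

#' @export
ggplot2::autoplot

tile_df <- function(M) {
  tibble::tibble(
    row = rep(seq_len(nrow(M)), times = ncol(M)),
    col = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.vector(M)
  )
}

#' Plot an identifiability matrix
#'
#' Heat map of correlation distances; the main diagonal (for cross-segment
#' pairs) is the per-participant reconfiguration.
#'
#' @param object An [identifiability_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot identifiability_matrix
#' @export
autoplot.identifiability_matrix <- function(object, ...) {
  pair <- attr(object, "segment_pair") %||% c("A", "B")
  df <- tile_df(unclass(object))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "corr. distance") +
    ggplot2::scale_y_reverse() +
    coord_fixed() +
    labs(x = pair[2], y = pair[1],
         title = sprintf("Identifiability matrix %s vs %s", pair[1], pair[2])) +
    theme_minimal()
}

#' Plot a meta-identifiability matrix
#'
#' @param object A [meta_identifiability()] object.
#' @param ... Unused.
#' @return A ggplot of the stacked `5n x 5n` distance matrix with segment
#'   boundaries.
#' @method autoplot meta_identifiability
#' @export
autoplot.meta_identifiability <- function(object, ...) {
  M <- as.matrix(object)
  n <- length(attr(object, "subject_order"))
  segs <- attr(object, "segments")
  df <- tile_df(M)
  breaks <- n * seq_along(segs) - n / 2
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "corr. distance") +
    ggplot2::scale_x_continuous(breaks = breaks, labels = segs) +
    ggplot2::scale_y_reverse(breaks = breaks, labels = segs) +
    coord_fixed() +
    ggplot2::geom_hline(yintercept = n * seq_len(length(segs) - 1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = n * seq_len(length(segs) - 1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    labs(x = NULL, y = NULL, title = "Meta-identifiability matrix") +
    theme_minimal()
}

#' Plot a fitted reconfiguration model
#'
#' Coefficient estimates with standard-error bars (intercept omitted),
#' annotated with the additive-R2 sequence.
#'
#' @param object A [fit_reconfig_model()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reconfig_model
#' @export
autoplot.reconfig_model <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  td$term <- factor(td$term, levels = object$predictor_order)
  td$significant <- td$p_value <= 0.05
  ggplot(td, aes(x = .data$term, y = .data$estimate, fill = .data$significant)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$estimate - .data$std_error,
                      ymax = .data$estimate + .data$std_error), width = 0.25) +
    labs(x = NULL, y = "coefficient",
         title = sprintf("Reconfiguration model %s (R² = %.2f)",
                         object$transition %||% "", glance(object)$r_squared)) +
    theme_minimal()
}

#' Plot leave-one-out coefficient distributions
#'
#' @param object A [loo_model_stability()] or [loo_reference_stability()]
#'   result.
#' @param ... Unused.
#' @return A ggplot (one box per predictor, intercept omitted).
#' @method autoplot loo_distribution
#' @export
autoplot.loo_distribution <- function(object, ...) {
  df <- object[object$term != "(Intercept)", ]
  ggplot(df, aes(x = .data$term, y = .data$estimate)) +
    geom_boxplot() +
    labs(x = NULL, y = "leave-one-out coefficient",
         title = sprintf("Coefficient stability (%s)", attr(object, "mode"))) +
    theme_minimal()
}

#' Plot a regularization sweep
#'
#' Explained variance of each transition's model and the pooled variance of
#' tangent-connectome elements against the regularization value (log axis).
#'
#' @param object A [regularization_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- dplyr::distinct(tibble::as_tibble(object)[, c("lambda", "transition",
                                                      "r_squared")])
  ggplot(df, aes(x = .data$lambda, y = .data$r_squared,
                 colour = .data$transition)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "regularization value", y = expression(R^2),
         title = "Model explained variance across regularization values") +
    theme_minimal()
}
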