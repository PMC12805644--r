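#' Tidy an imputed trait
#'
#' @param x An `imputed_trait` from [ls_impute()], [combined_impute()] or
#'   [transfer_impute()].
#' @param ... Unused.
#' @return A tibble with `sample_id` and `value`.
#' @export
tidy.imputed_trait <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids, value = x$values)
}

#' One-row summary of an imputed trait
#'
#' @inheritParams tidy.imputed_trait
#' @return A one-row tibble with the method, sample and SNP counts, and
#'   (for transfer fits) the epochs run and final objective.
#' @export
glance.imputed_trait <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = length(x$values),
    n_snps = length(x$snp_panel),
    epochs = if (!is.null(x$trajectory)) max(x$trajectory$epoch) else NA_integer_,
    objective = if (!is.null(x$trajectory)) tail(x$trajectory$objective, 1) else NA_real_)
}

#' Tidy a tuning result
#'
#' @param x A `tuning_result` from [select_omega()] or [select_epochs()].
#' @param ... Unused.
#' @return The evaluation grid as a tibble, with a `selected` flag.
#' @export
tidy.tuning_result <- function(x, ...) {
  g <- x$grid
  g$selected <- g[[x$parameter]] == x$selected
  g
}

#' One-row summary of a tuning result
#'
#' @inheritParams tidy.tuning_result
#' @return A one-row tibble with the selected value and its metric.
#' @export
glance.tuning_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, selected = x$selected,
                 metric_name = x$metric_name,
                 metric = max(x$grid$metric, na.rm = TRUE))
}

#' Plot a tuning grid
#'
#' Metric against the tuned parameter, with the selected value marked.
#'
#' @param object A `tuning_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tuning_result <- function(object, ...) {
  g <- tidy(object)
  ggplot2::ggplot(g, ggplot2::aes(.data[[object$parameter]], .data$metric)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = g[g$selected, ], colour = "red", size = 2) +
    ggplot2::labs(y = object$metric_name,
                  title = sprintf("Validation %s against %s (selected: %s)",
                                  object$metric_name, object$parameter,
                                  format(object$selected))) +
    ggplot2::theme_minimal()
}

#' Plot a transfer-imputation trajectory
#'
#' Objective (and validation metric, when recorded) against the epoch.
#'
#' @param object An `imputed_trait` with a trajectory (from
#'   [transfer_impute()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imputed_trait <- function(object, ...) {
  if (is.null(object$trajectory)) {
    stop("no trajectory recorded; only transfer fits can be plotted",
         call. = FALSE)
  }
  tr <- tidyr::pivot_longer(object$trajectory, -"epoch",
                            names_to = "series", values_to = "value")
  tr <- tr[!is.na(tr$value), ]
  ggplot2::ggplot(tr, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = "SGD trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param scores,labels As in [roc_points()].
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", auc_score(scores, labels))) +
    ggplot2::theme_minimal()
}
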