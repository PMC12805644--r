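.new_tuning_result <- function(grid, selected, metric_name, parameter) {
  structure(list(grid = grid, selected = selected,
                 metric_name = metric_name, parameter = parameter),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s selected by %s: %s (metric %.4f)\n",
              x$parameter, x$metric_name, format(x$selected),
              x$grid$metric[match(x$selected, x$grid[[x$parameter]])]))
  invisible(x)
}

#' Validation-based selection of the ancestry mixing weight
#'
#' Runs [combined_impute()] on validation genotypes for every `omega` on
#' the grid, scores the imputed values against the observed validation
#' trait, and selects the argmax (ties broken toward the smaller `omega`).
#' The metric is the Pearson correlation for quantitative traits and the
#' AUC for binary (0/1) traits.
#'
#' @inheritParams combined_impute
#' @param validation Observed validation trait values (tibble with
#'   `sample_id`, `value`, or numeric aligned to the samples).
#' @param grid Candidate `omega` values (default `seq(0, 1, by = 0.01)`).
#' @param metric `"auto"`, `"pearson"` or `"auc"`.
#' @return A `tuning_result`; `tidy()` returns the grid, `glance()` the
#'   selection.
#' @export
select_omega <- function(g1, beta1, g2, beta2, validation,
                         grid = seq(0, 1, by = 0.01),
                         metric = c("auto", "pearson", "auc"),
                         ridge_lambda = 1e-6) {
  if (!length(grid)) stop("empty omega grid", call. = FALSE)
  metric <- match.arg(metric)
  yobs <- .align_pheno(g1, validation)
  binary <- all(yobs %in% c(0, 1))
  metric_name <- switch(metric, auto = if (binary) "auc" else "pearson", metric)
  score <- if (metric_name == "auc") function(v) auc_score(v, yobs)
           else function(v) trait_cor(v, yobs)
  if (!identical(g1$sample_ids, g2$sample_ids)) {
    stop("the two genotype panels must cover the same samples in the same order",
         call. = FALSE)
  }
  if (!g1$standardized || !g2$standardized) {
    stop("genotypes must be standardized", call. = FALSE)
  }
  # the Gram matrices and projected betas do not depend on omega; computing
  # them once makes the grid sweep a sequence of n x n solves
  b1 <- .align_beta(g1, beta1); b2 <- .align_beta(g2, beta2)
  gram1 <- tcrossprod(g1$dosages); gram2 <- tcrossprod(g2$dosages)
  r1 <- g1$dosages %*% b1; r2 <- g2$dosages %*% b2
  n <- nrow(g1$dosages)
  vals <- vapply(grid, function(w) {
    yhat <- (n - 1) * gram_solve(w * gram1 + (1 - w) * gram2,
                                 w * r1 + (1 - w) * r2, ridge_lambda)
    score(drop(yhat))
  }, 0)
  gtab <- tibble::tibble(omega = grid, metric = vals)
  # ties (to floating tolerance) break toward the smaller omega
  sel <- min(grid[vals >= max(vals) - 1e-12])
  .new_tuning_result(gtab, sel, metric_name, "omega")
}

#' Early-stopping selection of the SGD epoch count
#'
#' Picks the epoch with the maximum recorded validation metric (ties
#' broken toward the earliest epoch). No shape is assumed for the
#' metric-versus-epoch curve; only the argmax is taken.
#'
#' @param trajectory A transfer [transfer_impute()] result, its
#'   `trajectory` tibble (`epoch`, `metric`), or a bare numeric vector of
#'   per-epoch metrics (treated as epochs `1..length`).
#' @return A `tuning_result` with `parameter = "epoch"`.
#' @export
select_epochs <- function(trajectory) {
  if (inherits(trajectory, "imputed_trait")) trajectory <- trajectory$trajectory
  metric_name <- attr(trajectory, "metric_name")
  if (is.null(metric_name) || is.na(metric_name)) metric_name <- "metric"
  if (is.numeric(trajectory)) {
    trajectory <- tibble::tibble(epoch = seq_along(trajectory),
                                 metric = as.numeric(trajectory))
  }
  if (!all(c("epoch", "metric") %in% names(trajectory))) {
    stop("trajectory needs columns epoch and metric", call. = FALSE)
  }
  tr <- trajectory[!is.na(trajectory$metric), c("epoch", "metric")]
  if (!nrow(tr)) stop("no recorded validation metrics", call. = FALSE)
  sel <- tr$epoch[order(-tr$metric, tr$epoch)][1]
  .new_tuning_result(tibble::as_tibble(tr), sel, metric_name, "epoch")
}
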