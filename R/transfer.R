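#' Transfer-learning trait imputation by SGD with early stopping
#'
#' Starts from trait values imputed with auxiliary-ancestry summary
#' statistics and refines them toward the target-ancestry statistics by
#' minimizing `||beta2 - X'Y/(n2-1)||^2` with mini-batch stochastic
#' gradient descent over the SNP equations. The objective is quadratic and
#' convex, so running to convergence recovers the target-only solution and
#' discards the initialization; the value of the method comes from stopping
#' at the validation-optimal epoch (see [select_epochs()]).
#'
#' One epoch is a shuffled pass over all SNP equations split into
#' mini-batches of `sgd_batch_snps`; each mini-batch applies its share of a
#' calibrated full-gradient-equivalent step, so an epoch makes the same
#' expected progress regardless of the batch count and epoch budgets scale
#' as `1/learning_rate`. The learning-rate unit is calibrated so that
#' `learning_rate = 0.1` reaches the validation optimum after roughly ten
#' epochs under the default benchmark conditions. The full objective is
#' recorded after every epoch (epoch 0 = the initial value); if a
#' validation trait is supplied, the validation metric is recorded after
#' every epoch as well.
#'
#' @param g A standardized [genotype_matrix()] for the target ancestry.
#' @param beta Target-ancestry marginal effects (as in [ls_impute()]).
#' @param y_init Initial trait values: an `imputed_trait` (typically from
#'   [ls_impute()] with auxiliary statistics) or a numeric vector aligned
#'   with `g`'s samples.
#' @param config An [impute_config()]; uses `learning_rate`, `max_epochs`,
#'   `sgd_batch_snps`, `full_batch` and `seed`.
#' @param validation Optional observed trait values for `g`'s samples
#'   (tibble or numeric) used to record a per-epoch validation metric.
#' @param metric Validation metric: `"auto"` (AUC when `validation` is
#'   0/1-valued, Pearson correlation otherwise), `"pearson"`, or `"auc"`.
#' @return An `imputed_trait` with `method = "transfer"` and a `trajectory`
#'   tibble (`epoch`, `objective`, `metric`); epoch 0 is the initial state.
#' @export
transfer_impute <- function(g, beta, y_init, config = impute_config(),
                            validation = NULL, metric = c("auto", "pearson", "auc")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "impute_config"))
  if (!g$standardized) stop("genotypes must be standardized", call. = FALSE)
  metric <- match.arg(metric)
  b <- .align_beta(g, beta)
  if (inherits(y_init, "imputed_trait")) {
    if (!identical(y_init$sample_ids, g$sample_ids)) {
      stop("y_init samples do not match the genotype panel", call. = FALSE)
    }
    y0 <- y_init$values
  } else {
    if (length(y_init) != nrow(g$dosages)) {
      stop("y_init length does not match sample count", call. = FALSE)
    }
    y0 <- as.numeric(y_init)
  }
  yobs <- NULL
  metric_type <- 0L
  metric_name <- NA_character_
  if (!is.null(validation)) {
    yobs <- .align_pheno(g, validation)
    binary <- all(yobs %in% c(0, 1))
    metric_name <- switch(metric,
                          auto = if (binary) "auc" else "pearson",
                          metric)
    metric_type <- if (metric_name == "auc") 2L else 1L
  }
  n <- nrow(g$dosages)
  fit <- withr::with_seed(config$seed, {
    sgd_core(g$dosages, b, y0, config$learning_rate, config$max_epochs,
             config$sgd_batch_snps, config$full_batch, yobs, metric_type,
             divergence_factor = 1e6)
  })
  if (fit$diverged_at > 0) {
    rlang::abort(sprintf(
      "SGD diverged at epoch %d (objective exceeded 1e6 x its initial value)",
      fit$diverged_at),
      class = "lsimpute_divergence", epoch = fit$diverged_at,
      last_state = fit$Y)
  }
  ne <- fit$epochs_run
  metric0 <- if (metric_type == 1L) cor(y0, yobs)
             else if (metric_type == 2L) auc_score(y0, yobs)
             else NA_real_
  traj <- tibble::tibble(
    epoch = 0:ne,
    objective = as.numeric(fit$objective),
    metric = c(metric0, if (ne > 0) as.numeric(fit$metric) else numeric(0)))
  attr(traj, "metric_name") <- metric_name
  .new_imputed_trait(g$sample_ids, fit$Y, "transfer", unclass(config),
                     g$snps$snp_id, trajectory = traj)
}
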