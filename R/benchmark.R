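# One full tuning-and-evaluation cycle on a simulated two-ancestry cohort:
# impute the validation split with each method, select omega and the SGD
# stopping epoch on validation, apply the selections to the test split,
# and score against the observed test trait. Mirrors the
# validation-then-test protocol of run_workflow() on in-memory data.
.benchmark_one <- function(cohorts, learning_rate = 0.1, max_epochs = 150L,
                           omega_grid = seq(0, 1, by = 0.01),
                           ridge_lambda = 1e-6) {
  cfg <- cohorts$config
  gv <- standardize_genotypes(cohorts$val$genotypes)
  gt <- standardize_genotypes(cohorts$test$genotypes)
  yv <- .align_pheno(gv, cohorts$val$phenotype)
  yt <- .align_pheno(gt, cohorts$test$phenotype)
  binary <- all(yv %in% c(0, 1))
  score <- if (binary) auc_score else trait_cor

  val_aux <- ls_impute(gv, cohorts$aux_stats, ridge_lambda)
  test_aux <- ls_impute(gt, cohorts$aux_stats, ridge_lambda)
  test_tgt <- ls_impute(gt, cohorts$tgt_stats, ridge_lambda)

  om <- select_omega(gv, cohorts$aux_stats, gv, cohorts$tgt_stats,
                     cohorts$val$phenotype, grid = omega_grid,
                     ridge_lambda = ridge_lambda)
  test_comb <- combined_impute(gt, cohorts$aux_stats, gt, cohorts$tgt_stats,
                               om$selected, ridge_lambda)

  icfg <- impute_config(ridge_lambda = ridge_lambda,
                        learning_rate = learning_rate,
                        max_epochs = max_epochs, seed = cfg$seed + 104729L)
  tr_val <- transfer_impute(gv, cohorts$tgt_stats, val_aux, icfg,
                            validation = cohorts$val$phenotype)
  ep <- select_epochs(tr_val)
  test_transfer <- if (ep$selected == 0) {
    test_aux
  } else {
    icfg_t <- icfg
    icfg_t$max_epochs <- as.integer(ep$selected)
    icfg_t$seed <- icfg$seed + 1L
    transfer_impute(gt, cohorts$tgt_stats, test_aux, icfg_t)
  }

  tibble::tibble(
    seed = cfg$seed,
    metric = if (binary) "auc" else "pearson",
    single_aux = score(test_aux$values, yt),
    single_tgt = score(test_tgt$values, yt),
    combined = score(test_comb$values, yt),
    transfer = score(test_transfer$values, yt),
    omega = om$selected,
    epoch = ep$selected)
}

#' Multi-seed two-ancestry imputation benchmark
#'
#' For each seed, simulates the default two-ancestry study
#' ([sim_config()]), tunes `omega` and the SGD stopping epoch on the
#' validation split, applies the selected parameters to the test split,
#' and reports the test-set metric (Pearson correlation, or AUC for binary
#' traits) for single-ancestry, combined and transfer imputation.
#'
#' @param n_seeds Number of simulation replicates.
#' @param config Base [sim_config()]; replicate `i` uses `seed + i - 1`.
#' @param learning_rate,max_epochs SGD settings for the transfer method.
#' @param omega_grid Grid for [select_omega()].
#' @return A tibble with one row per seed: `single_aux`, `single_tgt`,
#'   `combined`, `transfer`, the selected `omega` and `epoch`.
#' @export
run_benchmark <- function(n_seeds = 20L, config = sim_config(),
                          learning_rate = 0.1, max_epochs = 150L,
                          omega_grid = seq(0, 1, by = 0.01)) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    .benchmark_one(simulate_cohorts(cfg), learning_rate, max_epochs,
                   omega_grid)
  })
}

#' Learning-rate robustness of transfer imputation
#'
#' Runs transfer imputation on one simulated validation split for several
#' learning rates, giving each an epoch budget inversely proportional to
#' its rate, and reports the maximum validation metric over epochs
#' (including epoch 0, the initialization). For a convex quadratic
#' objective the SGD path depends on the learning rate only through its
#' time discretization, so the maxima should nearly coincide.
#'
#' @param cohorts Output of [simulate_cohorts()].
#' @param learning_rates Learning rates to compare.
#' @param epoch_budget_at_01 Epoch budget at learning rate 0.1; other
#'   rates get `epoch_budget_at_01 * 0.1 / lr`.
#' @param ridge_lambda Ridge constant for the initializing imputation.
#' @return A tibble with `learning_rate`, `epochs_budget`, `max_metric`,
#'   `argmax_epoch`.
#' @export
benchmark_lr_robustness <- function(cohorts,
                                    learning_rates = c(0.1, 0.01, 0.001),
                                    epoch_budget_at_01 = 150L,
                                    ridge_lambda = 1e-6) {
  gv <- standardize_genotypes(cohorts$val$genotypes)
  val_aux <- ls_impute(gv, cohorts$aux_stats, ridge_lambda)
  purrr::map_dfr(learning_rates, function(lr) {
    budget <- as.integer(round(epoch_budget_at_01 * 0.1 / lr))
    icfg <- impute_config(ridge_lambda = ridge_lambda, learning_rate = lr,
                          max_epochs = budget,
                          seed = cohorts$config$seed + 104729L)
    tr <- transfer_impute(gv, cohorts$tgt_stats, val_aux, icfg,
                          validation = cohorts$val$phenotype)
    ep <- select_epochs(tr)
    tibble::tibble(learning_rate = lr, epochs_budget = budget,
                   max_metric = max(tr$trajectory$metric, na.rm = TRUE),
                   argmax_epoch = ep$selected)
  })
}
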