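#' Run the full imputation workflow from a configuration
#'
#' Executes, in order: SNP quality control (and optional LD pruning) on the
#' validation genotypes, allele harmonization of both ancestries' summary
#' statistics, optional logistic-to-linear conversion and per-ancestry SNP
#' panel selection, validation-set imputation across the omega grid and the
#' SGD epoch budget, parameter selection on the validation split only,
#' test-set imputation with the selected parameters, evaluation, and an
#' optional marginal GWAS on the imputed test trait. Tuning strictly
#' precedes any use of the test phenotype.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' entries:
#' \preformatted{
#' seed: 1
#' output_dir: out
#' trait_type: quantitative        # or "binary"
#' genotypes: {validation: <plink prefix>, test: <plink prefix>}
#' phenotypes: {validation: <tsv>, test: <tsv>}
#' sumstats: {aux: <tsv>, tgt: <tsv>}
#' aux_counts: {cases: 0, controls: 0}   # optional: log-OR stats to convert
#' tgt_counts: {cases: 0, controls: 0}   # optional
#' qc: {maf_min: 0.05, miss_max: 0.1, hwe_p_min: 0.001,
#'      ld_window: 50, ld_step: 5, ld_r2_max: 0.8}
#' ld_prune: true
#' selection:                       # optional SNP panel selection
#'   aux: {target_count: 100, p_threshold: 0.05}
#'   tgt: {target_count: 100, p_threshold: 0.05}
#' impute: {ridge_lambda: 1.0e-6, learning_rate: 0.1, max_epochs: 100,
#'          sgd_batch_snps: 512}
#' omega_grid_step: 0.01
#' run_gwas: false
#' }
#'
#' @param config Path to a YAML file or a named list as above.
#' @return The run manifest (a named list, also written to
#'   `output_dir/manifest.json`) capturing every artifact path, parameter,
#'   seed and metric.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_run_config(config)
  manifest <- list(config = cfg, stages = character(0))
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(.manifest_json(manifest),
                           file.path(out_dir, "manifest_partial.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("workflow failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  # -- validation-side data ----------------------------------------------
  dat <- stage("read_validation", {
    list(g = read_plink(paste0(cfg$genotypes$validation, ".bed")),
         pheno = read_phenotype(cfg$phenotypes$validation),
         aux = read_sumstats(cfg$sumstats$aux, ancestry = "aux"),
         tgt = read_sumstats(cfg$sumstats$tgt, ancestry = "tgt"))
  })

  qc_res <- stage("qc", {
    thr <- do.call(qc_thresholds, cfg$qc)
    res <- apply_qc(dat$g, thr)
    if (isTRUE(cfg$ld_prune)) {
      kept <- ld_prune(res$genotypes, thr)
      res$genotypes <- res$genotypes[, kept]
    }
    write_qc_verdicts(res$verdicts, file.path(out_dir, "qc_verdicts.tsv"))
    res
  })
  manifest$qc <- list(n_input = nrow(dat$g$snps),
                      n_pass = ncol(qc_res$genotypes$dosages),
                      verdicts = file.path(out_dir, "qc_verdicts.tsv"))

  stats <- stage("harmonize", {
    aux <- harmonize_sumstats(dat$aux, qc_res$genotypes)
    tgt <- harmonize_sumstats(dat$tgt, qc_res$genotypes)
    for (cname in c("aux", "tgt")) {
      cc <- cfg[[paste0(cname, "_counts")]]
      if (!is.null(cc)) {
        b0 <- logit_baseline(cc$cases, cc$controls)
        s <- get(cname)
        s$beta <- glm_to_lm(b0, s$beta)
        assign(cname, s)
      }
    }
    list(aux = aux, tgt = tgt)
  })
  manifest$harmonize <- list(
    n_aux = nrow(stats$aux), n_tgt = nrow(stats$tgt),
    dropped_aux = as.list(attr(stats$aux, "dropped")),
    dropped_tgt = as.list(attr(stats$tgt, "dropped")))

  panels <- stage("select_snps", {
    pick <- function(s, sel, seed_off) {
      if (is.null(sel)) return(s$snp_id)
      select_snps(s, sel$target_count,
                  sel$p_threshold %||% 0.05, cfg$seed + seed_off)
    }
    list(aux = pick(stats$aux, cfg$selection$aux, 1L),
         tgt = pick(stats$tgt, cfg$selection$tgt, 2L))
  })
  manifest$panels <- list(n_aux = length(panels$aux),
                          n_tgt = length(panels$tgt))

  # -- tuning on the validation split only -------------------------------
  icfg <- do.call(impute_config, c(cfg$impute, list(seed = cfg$seed)))
  tuning <- stage("tune", {
    gv_aux <- standardize_genotypes(qc_res$genotypes[, panels$aux])
    gv_tgt <- standardize_genotypes(qc_res$genotypes[, panels$tgt])
    val_aux <- ls_impute(gv_aux, stats$aux, icfg$ridge_lambda)
    grid <- seq(0, 1, by = cfg$omega_grid_step %||% 0.01)
    om <- select_omega(gv_aux, stats$aux, gv_tgt, stats$tgt, dat$pheno,
                       grid = grid, ridge_lambda = icfg$ridge_lambda)
    tr <- transfer_impute(gv_tgt, stats$tgt, val_aux$values, icfg,
                          validation = dat$pheno)
    ep <- select_epochs(tr)
    utils::write.table(
      data.frame(PARAM = om$grid$omega, METRIC = om$grid$metric),
      file.path(out_dir, "omega_grid.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(PARAM = tr$trajectory$epoch, METRIC = tr$trajectory$metric),
      file.path(out_dir, "epoch_grid.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(omega = om, epochs = ep, metric_name = om$metric_name)
  })
  manifest$tuning <- list(
    selected_omega = tuning$omega$selected,
    selected_epoch = tuning$epochs$selected,
    metric = tuning$metric_name,
    best_val_omega_metric = max(tuning$omega$grid$metric),
    best_val_epoch_metric = max(tuning$epochs$grid$metric))
  jsonlite::write_json(.manifest_json(manifest),
                       file.path(out_dir, "manifest_tuning.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- test split: selected parameters only ------------------------------
  test_res <- stage("test", {
    gte <- read_plink(paste0(cfg$genotypes$test, ".bed"))
    pheno_te <- read_phenotype(cfg$phenotypes$test)
    gt_aux <- standardize_genotypes(gte[, intersect(panels$aux, gte$snps$snp_id)])
    gt_tgt <- standardize_genotypes(gte[, intersect(panels$tgt, gte$snps$snp_id)])
    yt <- .align_pheno(gt_aux, pheno_te)
    score <- if (tuning$metric_name == "auc") function(v) auc_score(v, yt)
             else function(v) trait_cor(v, yt)
    t_aux <- ls_impute(gt_aux, stats$aux, icfg$ridge_lambda)
    t_tgt <- ls_impute(gt_tgt, stats$tgt, icfg$ridge_lambda)
    t_comb <- combined_impute(gt_aux, stats$aux, gt_tgt, stats$tgt,
                              tuning$omega$selected, icfg$ridge_lambda)
    t_tr <- if (tuning$epochs$selected == 0) t_aux else {
      icfg_t <- icfg
      icfg_t$max_epochs <- as.integer(tuning$epochs$selected)
      transfer_impute(gt_tgt, stats$tgt, t_aux$values, icfg_t)
    }
    write_phenotype(tidy(t_comb), file.path(out_dir, "imputed_combined.tsv"))
    write_phenotype(tidy(t_tr), file.path(out_dir, "imputed_transfer.tsv"))
    list(genotypes = gt_tgt,
         imputed = list(single_aux = t_aux, single_tgt = t_tgt,
                        combined = t_comb, transfer = t_tr),
         metrics = list(single_aux = score(t_aux$values),
                        single_tgt = score(t_tgt$values),
                        combined = score(t_comb$values),
                        transfer = score(t_tr$values)))
  })
  manifest$test <- test_res$metrics
  manifest$outputs <- list(
    imputed_combined = file.path(out_dir, "imputed_combined.tsv"),
    imputed_transfer = file.path(out_dir, "imputed_transfer.tsv"))

  if (isTRUE(cfg$run_gwas)) {
    gwas <- stage("gwas", {
      res <- marginal_gwas(test_res$genotypes,
                           tidy(test_res$imputed$transfer))
      write_gwas(res, file.path(out_dir, "gwas_imputed.tsv"))
      res
    })
    manifest$gwas <- list(path = file.path(out_dir, "gwas_imputed.tsv"),
                          n_snps = nrow(gwas),
                          min_p = min(gwas$p))
  }

  manifest$seed <- cfg$seed
  jsonlite::write_json(.manifest_json(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.validate_run_config <- function(cfg) {
  need <- c("seed", "output_dir", "genotypes", "phenotypes", "sumstats")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("config missing entries: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  files <- c(paste0(cfg$genotypes$validation, c(".bed", ".bim", ".fam")),
             paste0(cfg$genotypes$test, c(".bed", ".bim", ".fam")),
             cfg$phenotypes$validation, cfg$phenotypes$test,
             cfg$sumstats$aux, cfg$sumstats$tgt)
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    stop("config references missing file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$qc <- cfg$qc %||% list()
  cfg$impute <- cfg$impute %||% list()
  cfg
}

# drop non-serializable pieces before writing JSON
.manifest_json <- function(m) {
  m$config$selection <- m$config$selection %||% NULL
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
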