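#' Two-ancestry simulation configuration
#'
#' Defaults emulate the asymmetry that motivates multi-ancestry trait
#' imputation: a large auxiliary-ancestry GWAS (50,000 samples), a small
#' target-ancestry GWAS (1,000), modest allele-frequency divergence
#' (Fst 0.01), partially shared genetic architecture (effect correlation
#' 0.8), and a polygenic quantitative trait (heritability 0.5 spread over
#' 500 causal SNPs out of 5,000).
#'
#' @param p SNP count.
#' @param n_aux_gwas Auxiliary-ancestry GWAS sample size.
#' @param n_tgt_gwas Target-ancestry GWAS sample size.
#' @param n_val,n_test Target-ancestry validation and test cohort sizes.
#' @param fst Wright's Fst between the two populations, in `[0, 0.5)`.
#' @param rho_effects Cross-ancestry correlation of causal effect sizes.
#' @param h2 Trait heritability in `(0, 1)`.
#' @param n_causal Number of causal SNPs (at least 1, at most `p`).
#' @param prevalence Case prevalence for a liability-threshold binary
#'   trait, or `NULL` for a quantitative trait.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p = 5000L, n_aux_gwas = 50000L, n_tgt_gwas = 1000L,
                       n_val = 500L, n_test = 500L, fst = 0.01,
                       rho_effects = 0.8, h2 = 0.5, n_causal = 500L,
                       prevalence = NULL, seed = 1L) {
  stopifnot(p >= 2, n_aux_gwas >= 10, n_tgt_gwas >= 10, n_val >= 10,
            n_test >= 10, fst >= 0, fst < 0.5, rho_effects >= -1,
            rho_effects <= 1, h2 > 0, h2 < 1, n_causal >= 1, n_causal <= p)
  if (!is.null(prevalence)) stopifnot(prevalence > 0, prevalence < 1)
  structure(list(p = as.integer(p), n_aux_gwas = as.integer(n_aux_gwas),
                 n_tgt_gwas = as.integer(n_tgt_gwas),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 fst = fst, rho_effects = rho_effects, h2 = h2,
                 n_causal = as.integer(n_causal), prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate diverged allele frequencies for two populations
#'
#' Balding-Nichols model: an ancestral frequency `q ~ Uniform(0.05, 0.95)`
#' per SNP, and population frequencies drawn independently from
#' `Beta(q(1-F)/F, (1-q)(1-F)/F)` with `F = fst`. At `fst = 0` both
#' populations keep the ancestral frequency exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with `snp_id`, `q`, `freq_aux`, `freq_tgt`.
#' @export
simulate_freqs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_freqs_impl(config))
}

.simulate_freqs_impl <- function(config) {
  p <- config$p
  q <- runif(p, 0.05, 0.95)
  if (config$fst <= 0) {
    f1 <- q; f2 <- q
  } else {
    a <- q * (1 - config$fst) / config$fst
    b <- (1 - q) * (1 - config$fst) / config$fst
    f1 <- rbeta(p, a, b)
    f2 <- rbeta(p, a, b)
  }
  tibble::tibble(snp_id = sprintf("snp%05d", seq_len(p)), q = q,
                 freq_aux = f1, freq_tgt = f2)
}

# marginal GWAS summary statistics (per standardized genotype and trait SD)
# on a freshly simulated panel, via the byte-matrix backend; the phenotype
# is standardized, so betas are correlations and p-values follow from the
# t statistic on n - 2 df.
.sim_gwas_stats <- function(n, freq, beta_std, h2, binary = FALSE,
                            prevalence = NULL) {
  p <- length(freq)
  X <- sample_geno_raw(n, freq)
  mo <- raw_col_moments(X, n, p)
  sdc <- pmax(mo$sd, 1e-12)
  g <- raw_prod_vec(X, n, p, beta_std / sdc)
  g <- g - mean(g)
  vg <- var(g)
  e <- rnorm(n, 0, sqrt(max(vg, 1e-12) * (1 - h2) / h2))
  y <- g + e
  if (binary) y <- as.numeric(y > stats::quantile(y, 1 - prevalence))
  ys <- (y - mean(y)) / sd(y)
  r <- raw_crossprod_vec(X, n, p, ys) / ((n - 1) * sdc)
  r2 <- pmin(r^2, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  list(beta = r, se = abs(r / pmax(abs(tstat), .Machine$double.eps)),
       p = 2 * pt(-abs(tstat), df = n - 2))
}

# dense genotype cohort with phenotype for validation/test splits
.sim_cohort <- function(n, freq, snps, beta_std, h2, binary, prevalence,
                        id_prefix) {
  p <- length(freq)
  X <- matrix(as.numeric(sample_geno_raw(n, freq)), n, p)
  g <- genotype_matrix(X, snps, sprintf("%s%04d", id_prefix, seq_len(n)))
  gs <- standardize_genotypes(g)
  bpanel <- beta_std[match(gs$snps$snp_id, snps$snp_id)]
  gv <- drop(gs$dosages %*% bpanel)
  y <- gv + rnorm(n, 0, sqrt(max(var(gv), 1e-12) * (1 - h2) / h2))
  if (binary) y <- as.numeric(y > stats::quantile(y, 1 - prevalence))
  list(genotypes = g,
       phenotype = tibble::tibble(sample_id = g$sample_ids, value = y),
       genetic_value = gv)
}

#' Simulate two-ancestry GWAS cohorts end to end
#'
#' Draws Balding-Nichols allele frequencies, sparse causal effects shared
#' across ancestries with correlation `rho_effects`, simulates the
#' auxiliary and target GWAS panels internally (marginal statistics are
#' computed on standardized genotypes and a standardized phenotype, so
#' betas are on the correlation scale), and returns genotype + phenotype
#' data for target-ancestry validation and test splits. Binary traits are
#' generated by thresholding the liability at the `1 - prevalence`
#' quantile.
#'
#' @param config A [sim_config()].
#' @return A list with `aux_stats` and `tgt_stats` (`sumstats` tibbles with
#'   `beta`, `se`, `p_value`, `n_gwas`), `val` and `test` (each a list of
#'   `genotypes`, `phenotype`, `genetic_value`), `effects` (true
#'   standardized effects per ancestry), `freqs`, and the `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    p <- config$p
    freqs <- .simulate_freqs_impl(config)
    causal <- sample.int(p, config$n_causal)
    b_aux <- numeric(p); b_tgt <- numeric(p)
    sd_b <- sqrt(config$h2 / config$n_causal)
    b_aux[causal] <- rnorm(config$n_causal, 0, sd_b)
    b_tgt[causal] <- config$rho_effects * b_aux[causal] +
      sqrt(1 - config$rho_effects^2) * rnorm(config$n_causal, 0, sd_b)
    binary <- !is.null(config$prevalence)
    snps <- tibble::tibble(snp_id = freqs$snp_id, chrom = "1",
                           pos_bp = seq_len(p) * 1000L,
                           effect_allele = "A", other_allele = "G")
    aux <- .sim_gwas_stats(config$n_aux_gwas, freqs$freq_aux, b_aux,
                           config$h2, binary, config$prevalence)
    tgt <- .sim_gwas_stats(config$n_tgt_gwas, freqs$freq_tgt, b_tgt,
                           config$h2, binary, config$prevalence)
    mkstats <- function(s, n, label) {
      sumstats(tibble::tibble(
        snp_id = snps$snp_id, chrom = snps$chrom, pos_bp = snps$pos_bp,
        effect_allele = snps$effect_allele, other_allele = snps$other_allele,
        beta = s$beta, se = s$se, p_value = s$p, n_gwas = n),
        ancestry = label, aligned = TRUE)
    }
    val <- .sim_cohort(config$n_val, freqs$freq_tgt, snps, b_tgt,
                       config$h2, binary, config$prevalence, "val")
    test <- .sim_cohort(config$n_test, freqs$freq_tgt, snps, b_tgt,
                        config$h2, binary, config$prevalence, "tst")
    list(aux_stats = mkstats(aux, config$n_aux_gwas, "auxiliary"),
         tgt_stats = mkstats(tgt, config$n_tgt_gwas, "target"),
         val = val, test = test,
         effects = tibble::tibble(snp_id = snps$snp_id, beta_aux = b_aux,
                                  beta_tgt = b_tgt),
         freqs = freqs, config = config)
  })
}

#' Simulate a genotype panel with autoregressive LD
#'
#' Generates genotypes from a latent Gaussian AR(1) process thresholded at
#' the Hardy-Weinberg genotype quantiles, giving adjacent-SNP correlation
#' controlled by `ar_rho`. Intended to exercise [ld_prune()]; the main
#' simulator draws independent SNPs.
#'
#' @param n Sample count.
#' @param freq Per-SNP allele frequencies.
#' @param ar_rho Latent AR(1) coefficient in `[0, 1)`.
#' @param seed Integer seed.
#' @return A raw [genotype_matrix()] (SNPs on chromosome 1, 1 kb apart).
#' @export
simulate_ld_panel <- function(n, freq, ar_rho = 0.9, seed = 1L) {
  stopifnot(ar_rho >= 0, ar_rho < 1)
  p <- length(freq)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(p)[-1]) {
      Z[, j] <- ar_rho * Z[, j - 1] + sqrt(1 - ar_rho^2) * Z[, j]
    }
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      f <- freq[j]
      t1 <- qnorm((1 - f)^2)        # below: 0 copies
      t2 <- qnorm(1 - f^2)          # above: 2 copies
      X[, j] <- (Z[, j] > t1) + (Z[, j] > t2)
    }
    snps <- tibble::tibble(snp_id = sprintf("ld%05d", seq_len(p)), chrom = "1",
                           pos_bp = seq_len(p) * 1000L,
                           effect_allele = "A", other_allele = "G")
    genotype_matrix(X, snps, sprintf("s%04d", seq_len(n)))
  })
}

#' Write a simulated cohort as an on-disk fixture tree
#'
#' Writes PLINK triplets for the validation and test genotypes, summary-
#' statistic TSVs for both ancestries, and phenotype TSVs, such that
#' [read_plink()] round-trips the genotypes exactly.
#'
#' @param cohorts Output of [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture <- function(cohorts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    val_geno = file.path(dir, "val"),
    test_geno = file.path(dir, "test"),
    aux_stats = file.path(dir, "aux_stats.tsv"),
    tgt_stats = file.path(dir, "tgt_stats.tsv"),
    val_pheno = file.path(dir, "val_pheno.tsv"),
    test_pheno = file.path(dir, "test_pheno.tsv"))
  write_plink(cohorts$val$genotypes, paths$val_geno)
  write_plink(cohorts$test$genotypes, paths$test_geno)
  write_sumstats(cohorts$aux_stats, paths$aux_stats)
  write_sumstats(cohorts$tgt_stats, paths$tgt_stats)
  write_phenotype(cohorts$val$phenotype, paths$val_pheno)
  write_phenotype(cohorts$test$phenotype, paths$test_pheno)
  invisible(paths)
}
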