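#' Marginal association estimates on standardized genotypes
#'
#' Computes the per-SNP marginal effect vector `X'Y / (n - 1)`, the summary
#' statistic that the imputation equations invert. On standardized genotypes
#' this equals the no-intercept regression slope of `Y` on each SNP; if `Y`
#' is also standardized it is the sample correlation.
#'
#' @param g A standardized [genotype_matrix()].
#' @param pheno Phenotype tibble (`sample_id`, `value`) or numeric vector
#'   aligned to `g`'s samples.
#' @return A tibble with `snp_id` and `beta`.
#' @export
marginal_betas <- function(g, pheno) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$standardized) stop("genotypes must be standardized", call. = FALSE)
  y <- .align_pheno(g, pheno)
  n <- nrow(g$dosages)
  tibble::tibble(snp_id = g$snps$snp_id,
                 beta = unname(drop(crossprod(g$dosages, y))) / (n - 1))
}

#' Per-SNP marginal GWAS by simple linear regression
#'
#' Regresses the trait on each SNP separately (with intercept) and reports
#' the slope, standard error, t statistic and two-sided p-value on `n - 2`
#' degrees of freedom. Intended for association scans on imputed
#' (continuous) trait values.
#'
#' @inheritParams marginal_betas
#' @return A tibble with `snp_id`, `chrom`, `pos_bp`, `effect_allele`,
#'   `beta`, `se`, `t`, `p`, and `p_underflow` (`TRUE` where the p-value
#'   underflowed below 1e-300 and is reported as 0).
#' @export
marginal_gwas <- function(g, pheno) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$standardized) stop("genotypes must be standardized", call. = FALSE)
  y <- .align_pheno(g, pheno)
  n <- nrow(g$dosages)
  if (n <= 2) stop("need more than 2 samples", call. = FALSE)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2) / (n - 1))
  r <- unname(drop(crossprod(g$dosages, yc))) / ((n - 1) * sy)
  r2 <- pmin(r^2, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  beta <- r * sy
  se <- ifelse(abs(tstat) > 0, abs(beta / tstat),
               sy * sqrt((1 - r2) / (n - 2)))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  # exact collinearity (perfect fit) and genuine underflow are both
  # reported as 0 with the flag set
  underflow <- p < 1e-300 | (1 - r2) <= 4 * .Machine$double.eps
  p[underflow] <- 0
  tibble::tibble(snp_id = g$snps$snp_id, chrom = g$snps$chrom,
                 pos_bp = g$snps$pos_bp, effect_allele = g$snps$effect_allele,
                 beta = beta, se = se, t = tstat, p = p,
                 p_underflow = underflow)
}

#' Write marginal GWAS results
#'
#' @param gwas Result tibble from [marginal_gwas()].
#' @param path Output path (TSV: `SNP`, `CHR`, `BP`, `A1`, `BETA`, `SE`,
#'   `T`, `P`).
#' @return Invisibly, `path`.
#' @export
write_gwas <- function(gwas, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(SNP = gwas$snp_id, CHR = gwas$chrom, BP = gwas$pos_bp,
               A1 = gwas$effect_allele, BETA = gwas$beta, SE = gwas$se,
               T = gwas$t, P = gwas$p),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert logistic-regression effect sizes to the linear-model scale
#'
#' A logistic-regression log odds ratio `b1` is rescaled to the slope of the
#' corresponding linear model as `mu * (1 - mu) * b1`, where
#' `mu = plogis(b0)` is the baseline case probability. This lets
#' case-control GWAS summary statistics feed the least-squares imputation,
#' which assumes linear-model effects.
#'
#' @param b0 Baseline log odds of being a case (scalar; see
#'   [logit_baseline()]).
#' @param b1 Log odds ratio(s) from logistic regression.
#' @return Effect size(s) on the linear-model scale.
#' @export
glm_to_lm <- function(b0, b1) {
  if (!all(is.finite(b0)) || !all(is.finite(b1))) {
    stop("b0 and b1 must be finite", call. = FALSE)
  }
  mu <- stats::plogis(b0)  # e^{-b0}/(1+e^{-b0})^2 == mu(1-mu), stable for large |b0|
  mu * (1 - mu) * b1
}

#' Baseline log odds from case/control counts
#'
#' @param n_cases,n_controls Positive case and control counts.
#' @return `log(n_cases / n_controls)`.
#' @export
logit_baseline <- function(n_cases, n_controls) {
  if (n_cases <= 0 || n_controls <= 0) {
    stop("case and control counts must both be positive", call. = FALSE)
  }
  log(n_cases / n_controls)
}

#' Select a SNP panel for imputation
#'
#' Takes every SNP significant at `p_threshold` when they fit within
#' `target_count` (otherwise a seeded uniform subset of them), topping up
#' with a seeded uniform sample of nonsignificant SNPs to reach exactly
#' `target_count`.
#'
#' @param stats A `sumstats` tibble with a `p_value` column.
#' @param target_count Number of SNPs to select.
#' @param p_threshold Significance threshold (default 0.05).
#' @param seed Integer seed making the panel reproducible.
#' @return Character vector of selected SNP ids sorted by `(chrom, pos_bp)`
#'   (falling back to id order when positions are absent), with attributes
#'   `seed`, `n_significant`, `n_random`.
#' @export
select_snps <- function(stats, target_count, p_threshold = 0.05, seed = 1L) {
  if (!"p_value" %in% names(stats)) stop("stats must have p-values", call. = FALSE)
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (target_count > nrow(stats)) {
    stop("target_count exceeds available SNP count", call. = FALSE)
  }
  sig <- stats$snp_id[!is.na(stats$p_value) & stats$p_value < p_threshold]
  other <- setdiff(stats$snp_id, sig)
  chosen <- withr::with_seed(seed, {
    if (length(sig) >= target_count) {
      sample(sig, target_count)
    } else {
      c(sig, sample(other, target_count - length(sig)))
    }
  })
  sel <- stats[stats$snp_id %in% chosen, ]
  ord <- if (all(c("chrom", "pos_bp") %in% names(sel)) && !anyNA(sel$pos_bp)) {
    order(sel$chrom, sel$pos_bp)
  } else {
    order(sel$snp_id)
  }
  out <- sel$snp_id[ord]
  attr(out, "seed") <- seed
  attr(out, "n_significant") <- sum(chosen %in% sig)
  attr(out, "n_random") <- sum(!chosen %in% sig)
  out
}
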