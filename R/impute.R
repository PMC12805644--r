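#' Imputation configuration
#'
#' @param ridge_lambda Ridge constant approximating the pseudoinverse,
#'   `(G + lambda I)^{-1} ~ G^+` for the sample Gram matrix `G` (default
#'   `1e-6`).
#' @param omega Ancestry mixing weight in `[0, 1]` for the combined method
#'   (weight on the first/auxiliary ancestry).
#' @param learning_rate SGD learning rate for the transfer method.
#' @param max_epochs SGD epoch budget.
#' @param sgd_batch_snps Mini-batch size in SNP equations (default 512).
#' @param sample_batch_max Maximum samples per batch when splitting large
#'   cohorts (default 2000).
#' @param seed Integer seed for SGD shuffling and any other randomness.
#' @param full_batch If `TRUE`, deterministic full-gradient descent.
#' @return A list of class `impute_config`.
#' @export
impute_config <- function(ridge_lambda = 1e-6, omega = 0.5,
                          learning_rate = 0.1, max_epochs = 100L,
                          sgd_batch_snps = 512L, sample_batch_max = 2000L,
                          seed = 1L, full_batch = FALSE) {
  stopifnot(ridge_lambda > 0, omega >= 0, omega <= 1, learning_rate > 0,
            max_epochs >= 0, sgd_batch_snps >= 1, sample_batch_max >= 2)
  structure(list(ridge_lambda = ridge_lambda, omega = omega,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 sgd_batch_snps = as.integer(sgd_batch_snps),
                 sample_batch_max = as.integer(sample_batch_max),
                 seed = as.integer(seed), full_batch = isTRUE(full_batch)),
            class = "impute_config")
}

#' Ridge-regularized solve on a symmetric PSD matrix
#'
#' Returns `(m + lambda I)^{-1} v` via a Cholesky factorization; with small
#' `lambda` this realizes the Moore-Penrose pseudoinverse applied to `v`
#' for the (possibly rank-deficient) Gram matrix `m`.
#'
#' @param m Symmetric positive semi-definite matrix.
#' @param v Right-hand-side vector (or matrix of columns).
#' @param ridge_lambda Positive ridge constant (default `1e-6`).
#' @return The solution vector/matrix.
#' @export
gram_solve <- function(m, v, ridge_lambda = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), ridge_lambda > 0)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  a <- m + diag(ridge_lambda, nrow(m))
  ch <- tryCatch(chol(a), error = function(e) {
    stop(sprintf(
      "Cholesky factorization failed (lambda = %g, diagonal range [%g, %g]): %s",
      ridge_lambda, min(diag(a)), max(diag(a)), conditionMessage(e)),
      call. = FALSE)
  })
  backsolve(ch, forwardsolve(t(ch), v))
}

# resolve a beta argument (numeric vector, tibble with snp_id+beta, or
# sumstats) against a genotype panel; errors if any panel SNP lacks a beta
.align_beta <- function(g, beta) {
  if (is.numeric(beta)) {
    if (length(beta) != ncol(g$dosages)) {
      stop("beta length does not match SNP panel", call. = FALSE)
    }
    return(as.numeric(beta))
  }
  if (!all(c("snp_id", "beta") %in% names(beta))) {
    stop("beta must be numeric or have columns snp_id and beta", call. = FALSE)
  }
  m <- match(g$snps$snp_id, beta$snp_id)
  if (anyNA(m)) {
    stop("summary statistics missing for ", sum(is.na(m)),
         " SNP(s) in the genotype panel", call. = FALSE)
  }
  as.numeric(beta$beta[m])
}

.new_imputed_trait <- function(sample_ids, values, method, config, snp_panel,
                               trajectory = NULL) {
  stopifnot(all(is.finite(values)))
  structure(list(sample_ids = sample_ids, values = as.numeric(values),
                 method = method, config = config, snp_panel = snp_panel,
                 trajectory = trajectory),
            class = "imputed_trait")
}

#' @export
print.imputed_trait <- function(x, ...) {
  cat(sprintf("<imputed_trait> %d samples, method = %s, %d SNPs\n",
              length(x$values), x$method, length(x$snp_panel)))
  invisible(x)
}

#' Single-ancestry least-squares trait imputation
#'
#' Imputes trait values for `n2` genotyped individuals from GWAS marginal
#' effects by solving the system `beta = X'Y / (n2 - 1)` in the
#' least-squares sense:
#' `Yhat = (n2 - 1) (XX')^+ X beta`, with the pseudoinverse realized as a
#' ridge-regularized solve on the sample Gram matrix.
#'
#' @param g A standardized [genotype_matrix()]; the method assumes more
#'   SNPs than samples (`p > n2`) and warns otherwise.
#' @param beta Marginal effects per standardized genotype unit: numeric
#'   vector in panel order, or a tibble/`sumstats` with `snp_id` and
#'   `beta` covering the panel (e.g. harmonized summary statistics).
#' @param ridge_lambda Ridge constant (default `1e-6`).
#' @return An `imputed_trait` object; see [tidy.imputed_trait()].
#' @export
ls_impute <- function(g, beta, ridge_lambda = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$standardized) stop("genotypes must be standardized", call. = FALSE)
  b <- .align_beta(g, beta)
  X <- g$dosages
  n <- nrow(X)
  if (ncol(X) <= n) {
    warning("SNP count (", ncol(X), ") does not exceed sample count (", n,
            "); the system is not underdetermined")
  }
  yhat <- (n - 1) * gram_solve(tcrossprod(X), X %*% b, ridge_lambda)
  .new_imputed_trait(g$sample_ids, drop(yhat), "single",
                     list(ridge_lambda = ridge_lambda), g$snps$snp_id)
}

#' Two-ancestry combined trait imputation
#'
#' Blends two sets of GWAS summary statistics with weight `omega` on the
#' first (auxiliary) ancestry and solves the combined least-squares
#' problem in closed form:
#' `Yhat = (n2-1) (omega X1 X1' + (1-omega) X2 X2')^+ (omega X1 b1 + (1-omega) X2 b2)`.
#' At `omega = 1` (or `0`) this reduces exactly to single-ancestry
#' imputation with the first (or second) statistics.
#'
#' @param g1,g2 Standardized [genotype_matrix()] objects over the same
#'   samples (column subsets of one genotype source; panels may differ).
#' @param beta1,beta2 Marginal effects aligned to `g1`/`g2` (as in
#'   [ls_impute()]).
#' @param omega Mixing weight in `[0, 1]` on the first ancestry.
#' @param ridge_lambda Ridge constant (default `1e-6`).
#' @return An `imputed_trait` object.
#' @export
combined_impute <- function(g1, beta1, g2, beta2, omega, ridge_lambda = 1e-6) {
  stopifnot(inherits(g1, "genotype_matrix"), inherits(g2, "genotype_matrix"),
            omega >= 0, omega <= 1)
  if (!g1$standardized || !g2$standardized) {
    stop("genotypes must be standardized", call. = FALSE)
  }
  if (!identical(g1$sample_ids, g2$sample_ids)) {
    stop("the two genotype panels must cover the same samples in the same order",
         call. = FALSE)
  }
  b1 <- .align_beta(g1, beta1)
  b2 <- .align_beta(g2, beta2)
  n <- nrow(g1$dosages)
  gram <- omega * tcrossprod(g1$dosages) + (1 - omega) * tcrossprod(g2$dosages)
  rhs <- omega * (g1$dosages %*% b1) + (1 - omega) * (g2$dosages %*% b2)
  yhat <- (n - 1) * gram_solve(gram, rhs, ridge_lambda)
  .new_imputed_trait(g1$sample_ids, drop(yhat), "combined",
                     list(ridge_lambda = ridge_lambda, omega = omega),
                     union(g1$snps$snp_id, g2$snps$snp_id))
}

#' Split samples into contiguous batches
#'
#' Large cohorts are imputed batch by batch (each batch re-standardized, so
#' the least-squares system is internally consistent) and the results
#' concatenated in the original order.
#'
#' @param g A [genotype_matrix()].
#' @param sample_batch_max Maximum samples per batch (at least 2).
#' @return List of `genotype_matrix` objects forming a disjoint, exhaustive,
#'   contiguous partition of the samples.
#' @export
split_batches <- function(g, sample_batch_max = 2000L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (sample_batch_max < 2) stop("sample_batch_max must be >= 2", call. = FALSE)
  n <- nrow(g$dosages)
  starts <- seq(1L, n, by = as.integer(sample_batch_max))
  lapply(starts, function(s) g[s:min(s + sample_batch_max - 1L, n), ])
}

#' Batched single-ancestry imputation on raw genotypes
#'
#' Convenience driver: splits samples into batches of at most
#' `sample_batch_max`, standardizes each batch, runs [ls_impute()] per
#' batch, and concatenates the imputed values in the original sample order.
#'
#' @param g A raw [genotype_matrix()].
#' @inheritParams ls_impute
#' @param sample_batch_max Maximum samples per batch.
#' @return An `imputed_trait` object.
#' @export
ls_impute_batched <- function(g, beta, ridge_lambda = 1e-6,
                              sample_batch_max = 2000L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) stop("supply raw dosages; batches are re-standardized",
                           call. = FALSE)
  if (is.numeric(beta)) {
    # key by snp_id so batches that lose constant columns still align
    beta <- tibble::tibble(snp_id = g$snps$snp_id, beta = as.numeric(beta))
  }
  batches <- split_batches(g, sample_batch_max)
  parts <- lapply(batches, function(b) {
    bs <- suppressWarnings(standardize_genotypes(b))
    ls_impute(bs, beta, ridge_lambda)
  })
  .new_imputed_trait(g$sample_ids,
                     unlist(lapply(parts, function(p) p$values)),
                     "single",
                     list(ridge_lambda = ridge_lambda,
                          sample_batch_max = sample_batch_max,
                          n_batches = length(batches)),
                     g$snps$snp_id)
}
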