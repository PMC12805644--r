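#' SNP quality-control thresholds
#'
#' Defaults follow standard GWAS practice: minor allele frequency at least
#' 0.05, at most 10% missing calls, Hardy-Weinberg exact p at least 0.001,
#' and LD pruning with a 50-SNP window, step 5, r-squared threshold 0.8.
#'
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @param miss_max Maximum missing-call fraction, in `[0, 1]`.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value, in `[0, 1]`.
#' @param ld_window Pruning window size in SNPs.
#' @param ld_step Window step in SNPs.
#' @param ld_r2_max Maximum tolerated pairwise r-squared within a window.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, miss_max = 0.10, hwe_p_min = 0.001,
                          ld_window = 50L, ld_step = 5L, ld_r2_max = 0.8) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, ld_window >= 1, ld_step >= 1,
            ld_r2_max > 0, ld_r2_max <= 1)
  structure(list(maf_min = maf_min, miss_max = miss_max,
                 hwe_p_min = hwe_p_min, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts (with the same
#' allele totals) whose conditional probability does not exceed that of the
#' observed configuration. Probabilities are evaluated in log space.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative integers).
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  r <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # rare-allele count
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2) # attainable het counts
  # log P(het = h | n, r), up to the shared constant r!(2n-r)!/(2n)! * n!
  logp <- hs * log(2) - lfactorial((r - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (r + hs) / 2)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_het, hs)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# per-SNP MAF on non-missing calls
.snp_maf <- function(X) {
  af <- colMeans(X, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Apply SNP-level quality-control filters
#'
#' Removes SNPs with minor allele frequency below `maf_min`, missing-call
#' fraction above `miss_max`, or Hardy-Weinberg exact-test p-value below
#' `hwe_p_min`. The three filters are independent, so their order does not
#' affect the result.
#'
#' @param g A raw [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `genotypes` (the filtered `genotype_matrix`) and
#'   `verdicts`, a tibble with per-SNP `maf`, `f_miss`, `p_hwe`, `keep`,
#'   and comma-separated failure `reasons`.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) stop("QC needs raw dosages", call. = FALSE)
  X <- g$dosages
  maf <- .snp_maf(X)
  f_miss <- colMeans(is.na(X))
  p_hwe <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, 0)
  fail_maf <- maf < thresholds$maf_min
  fail_miss <- f_miss > thresholds$miss_max
  fail_hwe <- !is.na(p_hwe) & p_hwe < thresholds$hwe_p_min
  keep <- !(fail_maf | fail_miss | fail_hwe)
  reasons <- vapply(seq_len(ncol(X)), function(j) {
    paste(c("maf", "missingness", "hwe")[c(fail_maf[j], fail_miss[j], fail_hwe[j])],
          collapse = ",")
  }, "")
  verdicts <- tibble::tibble(snp_id = g$snps$snp_id, maf = unname(maf),
                             f_miss = unname(f_miss), p_hwe = p_hwe,
                             keep = keep, reasons = reasons)
  list(genotypes = g[, which(keep)], verdicts = verdicts)
}

#' Write a QC verdict table
#'
#' @param verdicts Verdict tibble from [apply_qc()].
#' @param path Output path (TSV: `SNP`, `MAF`, `F_MISS`, `P_HWE`, `KEEP`,
#'   `REASONS`).
#' @return Invisibly, `path`.
#' @export
write_qc_verdicts <- function(verdicts, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(SNP = verdicts$snp_id, MAF = verdicts$maf,
               F_MISS = verdicts$f_miss, P_HWE = verdicts$p_hwe,
               KEEP = as.integer(verdicts$keep), REASONS = verdicts$reasons),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `ld_window` SNPs (per chromosome, advancing by
#' `ld_step`), repeatedly removes one member of the retained pair with the
#' highest squared Pearson correlation of dosages until no pair exceeds
#' `ld_r2_max`. The member with the lower minor allele frequency is dropped
#' first (ties: the later position). Correlations are computed on
#' mean-imputed, centered dosages.
#'
#' @param g A raw [genotype_matrix()] with SNPs ordered by `(chrom, pos_bp)`.
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  sn <- g$snps
  ord <- order(sn$chrom, sn$pos_bp)
  if (!identical(ord, seq_len(nrow(sn)))) {
    stop("SNPs must be ordered by (chrom, pos)", call. = FALSE)
  }
  X <- g$dosages
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }
  maf <- .snp_maf(X)
  keep <- rep(TRUE, ncol(X))
  w <- thresholds$ld_window; s <- thresholds$ld_step; thr <- thresholds$ld_r2_max
  for (chr in unique(sn$chrom)) {
    cols <- which(sn$chrom == chr)
    starts <- seq(1L, max(1L, length(cols) - 1L), by = s)
    for (st in starts) {
      win <- cols[st:min(st + w - 1L, length(cols))]
      act <- win[keep[win]]
      if (length(act) < 2) next
      r2 <- suppressWarnings(cor(X[, act, drop = FALSE]))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      while (max(r2) > thr) {
        ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- act[ij[1]]; b <- act[ij[2]]
        drop_snp <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else max(a, b)  # equal MAF: drop the later position
        keep[drop_snp] <- FALSE
        k <- match(drop_snp, act)
        r2[k, ] <- 0; r2[, k] <- 0
      }
    }
  }
  g$snps$snp_id[keep]
}
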