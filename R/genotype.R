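#' Genotype matrix container
#'
#' Bundles an `n x p` dosage matrix (count of the effect allele, `0/1/2`,
#' `NA` for missing) with per-SNP metadata and sample identifiers. All
#' imputation routines operate on this container; columns are SNPs.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns. Entries
#'   must be 0, 1, 2 or `NA` unless `standardized = TRUE`.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele` (one row per dosage column). The
#'   effect allele is the counted allele.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `dosages`.
#' @param standardized Logical; `TRUE` only for output of
#'   [standardize_genotypes()].
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_plink()], [standardize_genotypes()]
#' @export
genotype_matrix <- function(dosages, snps, sample_ids, standardized = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snps <- tibble::as_tibble(snps)
  sample_ids <- as.character(sample_ids)
  req <- c("snp_id", "chrom", "pos_bp", "effect_allele", "other_allele")
  if (!all(req %in% names(snps))) {
    stop("`snps` must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(snps) != ncol(dosages)) {
    stop("`snps` has ", nrow(snps), " rows but `dosages` has ",
         ncol(dosages), " columns", call. = FALSE)
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("`sample_ids` length does not match rows of `dosages`", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp ids", call. = FALSE)
  if (any(snps$effect_allele == snps$other_allele)) {
    stop("effect and other allele identical for some SNPs", call. = FALSE)
  }
  if (any(snps$pos_bp < 1)) stop("`pos_bp` must be >= 1", call. = FALSE)
  if (!standardized) {
    vals <- dosages[!is.na(dosages)]
    if (length(vals) && !all(vals %in% c(0, 1, 2))) {
      stop("raw dosages must be 0, 1, 2 or NA", call. = FALSE)
    }
  }
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(
    list(dosages = dosages, snps = snps, sample_ids = sample_ids,
         standardized = isTRUE(standardized)),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (x$standardized) "standardized" else "raw dosages"))
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat(sprintf("  %d missing entries\n", nm))
  invisible(x)
}

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x A [genotype_matrix()].
#' @param i Sample index (integer, logical, or sample ids).
#' @param j SNP index (integer, logical, or SNP ids).
#' @param ... Unused.
#' @return A `genotype_matrix` with metadata subset accordingly.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  genotype_matrix(x$dosages[i, j, drop = FALSE], x$snps[j, , drop = FALSE],
                  x$sample_ids[i], standardized = x$standardized)
}

#' Standardize genotype dosages
#'
#' Mean-imputes missing dosages per SNP, then centers each column and scales
#' it to unit sample variance (denominator `n - 1`). Constant columns cannot
#' be standardized and are dropped with a warning. The imputation equations
#' assume this standardization.
#'
#' @param g A raw (non-standardized) [genotype_matrix()].
#' @return A `genotype_matrix` with `standardized = TRUE`; dropped SNP ids
#'   are recorded in the `dropped_constant` attribute.
#' @export
standardize_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) stop("genotypes already standardized", call. = FALSE)
  X <- g$dosages
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples to standardize", call. = FALSE)
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }
  cm <- colMeans(X)
  sds <- sqrt(colSums(sweep(X, 2, cm)^2) / (n - 1))
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant SNP column(s) dropped during standardization")
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, cm[keep]), 2, sds[keep], "/")
  out <- genotype_matrix(Xs, g$snps[keep, , drop = FALSE], g$sample_ids,
                         standardized = TRUE)
  attr(out, "dropped_constant") <- g$snps$snp_id[!keep]
  out
}
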