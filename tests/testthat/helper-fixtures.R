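# small in-code fixtures shared across test files

# random raw genotype matrix with plausible metadata
make_geno <- function(n, p, seed = 1, maf_range = c(0.1, 0.5),
                      missing_frac = 0) {
  withr::with_seed(seed, {
    f <- runif(p, maf_range[1], maf_range[2])
    X <- matrix(rbinom(n * p, 2, rep(f, each = n)), n, p, byrow = FALSE)
    X <- matrix(as.numeric(X), n, p)
    if (missing_frac > 0) {
      idx <- sample(length(X), round(missing_frac * length(X)))
      X[idx] <- NA
    }
    snps <- tibble::tibble(
      snp_id = sprintf("rs%04d", seq_len(p)), chrom = "1",
      pos_bp = seq_len(p) * 1000L,
      effect_allele = "A", other_allele = "G")
    genotype_matrix(X, snps, sprintf("s%03d", seq_len(n)))
  })
}

# standardized genotype container around an arbitrary numeric matrix
make_std_geno <- function(X, prefix = "rs") {
  n <- nrow(X); p <- ncol(X)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  snps <- tibble::tibble(
    snp_id = sprintf("%s%04d", prefix, seq_len(p)), chrom = "1",
    pos_bp = seq_len(p) * 1000L, effect_allele = "A", other_allele = "G")
  genotype_matrix(Xs, snps, sprintf("s%03d", seq_len(n)), standardized = TRUE)
}

# sumstats tibble from a beta vector aligned to a genotype panel
make_stats <- function(g, beta, ...) {
  sumstats(tibble::tibble(
    snp_id = g$snps$snp_id, chrom = g$snps$chrom, pos_bp = g$snps$pos_bp,
    effect_allele = g$snps$effect_allele, other_allele = g$snps$other_allele,
    beta = beta, ...), aligned = TRUE)
}

# direct enumeration oracle for the Hardy-Weinberg exact test: conditional
# probability of each heterozygote count from the exact hypergeometric-type
# formula, summed over configurations no more probable than the observed one
hwe_oracle <- function(a, b, c) {
  n <- a + b + c
  r <- 2 * min(a, c) + b
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  pr <- vapply(hs, function(h) {
    n1 <- (r - h) / 2
    n2 <- n - (r + h) / 2
    exp(lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
          h * log(2) + lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n))
  }, 0)
  obs <- pr[match(b, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
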