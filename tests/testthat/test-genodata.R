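test_that("PLINK round-trip preserves dosages, metadata and missing calls", {
  g <- make_geno(9, 7, seed = 3)
  g$dosages[2, 4] <- NA  # one missing call at a known position
  g$dosages[7, 1] <- NA
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_plink(g, prefix)
  g2 <- read_plink(paste0(prefix, ".bed"))
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$snps$snp_id, g$snps$snp_id)
  expect_identical(g2$snps$effect_allele, g$snps$effect_allele)
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_true(is.na(g2$dosages[2, 4]))
  # a known 4 x 3 matrix round-trips exactly
  X <- matrix(c(0, 1, 2, 0, 2, 2, 1, 0, NA, 1, 1, 2), 4, 3)
  snps <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = "2",
                         pos_bp = c(10L, 20L, 30L),
                         effect_allele = c("A", "C", "G"),
                         other_allele = c("G", "T", "A"))
  g3 <- genotype_matrix(X, snps, c("i1", "i2", "i3", "i4"))
  write_plink(g3, paste0(prefix, "2"))
  g4 <- read_plink(paste0(prefix, "2.bed"))
  expect_identical(unname(g4$dosages), unname(X))
})

test_that("malformed bed files are rejected", {
  prefix <- file.path(withr::local_tempdir(), "bad")
  g <- make_geno(4, 3)
  write_plink(g, prefix)
  # corrupt the magic bytes
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(paste0(prefix, ".bed")), "magic")
  # payload inconsistent with bim/fam
  write_plink(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(c(raw, as.raw(0)), paste0(prefix, ".bed"))
  expect_error(read_plink(paste0(prefix, ".bed")), "inconsistent")
})

test_that("standardization centers, scales, mean-imputes and drops constants", {
  X <- cbind(c(0, 2, 0, 2), c(1, 1, 1, 1), c(0, 1, 2, 1))
  snps <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = "1",
                         pos_bp = 1:3, effect_allele = "A", other_allele = "G")
  g <- genotype_matrix(X, snps, paste0("s", 1:4))
  expect_warning(gs <- standardize_genotypes(g), "constant")
  expect_equal(ncol(gs$dosages), 2)
  expect_identical(attr(gs, "dropped_constant"), "b")
  expect_equal(mean(gs$dosages[, 1]), 0, tolerance = 1e-12)
  expect_equal(var(gs$dosages[, 1]), 1, tolerance = 1e-12)

  g2 <- make_geno(12, 3, seed = 7)
  gs2 <- standardize_genotypes(g2)
  expect_lt(max(abs(colMeans(gs2$dosages))), 1e-10)
  expect_lt(max(abs(apply(gs2$dosages, 2, var) - 1)), 1e-10)

  # missing entries are mean-imputed before scaling
  g3 <- make_geno(20, 4, seed = 9, missing_frac = 0.1)
  gs3 <- standardize_genotypes(g3)
  expect_false(anyNA(gs3$dosages))
  expect_lt(max(abs(colMeans(gs3$dosages))), 1e-10)

  expect_error(standardize_genotypes(make_geno(1, 3)), "at least 2")
  expect_error(standardize_genotypes(gs2), "already")
})

test_that("harmonization keeps, flips, complements and drops correctly", {
  ref <- tibble::tibble(snp_id = c("r1", "r2", "r3", "r4", "r5"),
                        chrom = "1", pos_bp = 1:5,
                        effect_allele = c("A", "A", "A", "A", "C"),
                        other_allele = c("G", "G", "T", "G", "G"))
  st <- sumstats(tibble::tibble(
    snp_id = c("r1", "r2", "r3", "r4", "r5", "r9"),
    effect_allele = c("A", "G", "A", "T", "C", "A"),
    other_allele = c("G", "A", "T", "C", "G", "G"),
    beta = c(0.3, 0.3, 0.3, 0.4, 0.5, 0.9)))
  h <- harmonize_sumstats(st, ref)
  # r1 exact match; r2 swapped; r3 ambiguous A/T; r4 complement (T/C -> A/G);
  # r5 ambiguous C/G; r9 absent from panel
  expect_identical(h$snp_id, c("r1", "r2", "r4"))
  expect_equal(h$beta, c(0.3, -0.3, 0.4))
  expect_identical(h$effect_allele, c("A", "A", "A"))
  expect_true(attr(h, "aligned"))
  d <- attr(h, "dropped")
  expect_equal(unname(d["ambiguous"]), 2)
  expect_equal(unname(d["absent"]), 1)
})

test_that("harmonization is idempotent and antisymmetric under allele swap", {
  g <- make_geno(5, 8, seed = 11)
  g$snps$effect_allele <- rep(c("A", "C"), 4)
  g$snps$other_allele <- rep(c("G", "T"), 4)
  st <- withr::with_seed(2, {
    swap <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    sumstats(tibble::tibble(
      snp_id = g$snps$snp_id,
      effect_allele = ifelse(swap, g$snps$other_allele, g$snps$effect_allele),
      other_allele = ifelse(swap, g$snps$effect_allele, g$snps$other_allele),
      beta = rnorm(8)))
  })
  h1 <- harmonize_sumstats(st, g)
  h2 <- harmonize_sumstats(h1, g)
  expect_equal(h2$beta, h1$beta)
  expect_identical(h2$snp_id, h1$snp_id)

  # swapping the allele roles in the input negates every harmonized beta
  st_sw <- st
  st_sw$effect_allele <- st$other_allele
  st_sw$other_allele <- st$effect_allele
  h3 <- harmonize_sumstats(st_sw, g)
  expect_equal(h3$beta, -h1$beta)

  # empty intersection errors
  st2 <- st
  st2$snp_id <- paste0("x", st2$snp_id)
  expect_error(harmonize_sumstats(st2, g), "no SNPs shared")
})

test_that("summary-statistic and phenotype files round-trip", {
  g <- make_geno(6, 4)
  st <- make_stats(g, beta = c(0.1, -0.2, 0.3, 0), se = rep(0.05, 4),
                   p_value = c(0.01, 0.5, 1e-5, 0.9), n_gwas = 100L)
  path <- file.path(withr::local_tempdir(), "st.tsv")
  write_sumstats(st, path)
  st2 <- read_sumstats(path)
  expect_equal(st2$beta, st$beta)
  expect_equal(st2$p_value, st$p_value)
  expect_identical(st2$snp_id, st$snp_id)
  expect_true(attr(st2, "aligned"))

  ph <- tibble::tibble(sample_id = g$sample_ids, value = rnorm(6))
  pp <- file.path(withr::local_tempdir(), "ph.tsv")
  write_phenotype(ph, pp)
  ph2 <- read_phenotype(pp)
  expect_equal(ph2$value, ph$value)
  expect_identical(ph2$sample_id, ph$sample_id)
})
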