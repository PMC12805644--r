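test_that("marginal betas equal per-SNP no-intercept slopes on standardized data", {
  g <- standardize_genotypes(make_geno(50, 10, seed = 4))
  withr::with_seed(8, y <- rnorm(50))
  mb <- marginal_betas(g, y)
  for (j in seq_len(10)) {
    fit <- lm(y ~ g$dosages[, j] - 1)
    expect_equal(mb$beta[j], unname(coef(fit)), tolerance = 1e-10)
  }
  # y equal to a standardized column gives beta 1 there
  y2 <- g$dosages[, 3]
  mb2 <- marginal_betas(g, y2)
  expect_equal(mb2$beta[3], 1, tolerance = 1e-12)
  # y orthogonal to a column gives 0
  y3 <- y - g$dosages[, 5] * sum(y * g$dosages[, 5]) / sum(g$dosages[, 5]^2)
  mb3 <- marginal_betas(g, y3)
  expect_equal(mb3$beta[5], 0, tolerance = 1e-12)
  # correlation-scale bound when y is standardized
  ys <- (y - mean(y)) / sd(y)
  expect_true(all(abs(marginal_betas(g, ys)$beta) <= 1 + 1e-12))
})

test_that("marginal GWAS matches a reference least-squares fit", {
  g <- standardize_genotypes(make_geno(30, 6, seed = 10))
  withr::with_seed(11, y <- rnorm(30, sd = 2) + 3)
  res <- marginal_gwas(g, y)
  for (j in seq_len(6)) {
    fit <- summary(lm(y ~ g$dosages[, j]))
    expect_equal(res$beta[j], fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(res$se[j], fit$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(res$p[j], fit$coefficients[2, 4], tolerance = 1e-8)
  }
  # a perfect linear relationship underflows to zero with a flag
  yj <- 2 * g$dosages[, 1]
  res2 <- marginal_gwas(g, yj)
  expect_equal(res2$p[1], 0)
  expect_true(res2$p_underflow[1])
  expect_error(marginal_gwas(suppressWarnings(standardize_genotypes(make_geno(2, 3))), 1:2),
               "more than 2")
})

test_that("marginal GWAS p-values are uniform under the null", {
  g <- standardize_genotypes(make_geno(300, 2000, seed = 12,
                                       maf_range = c(0.05, 0.5)))
  withr::with_seed(13, y <- sample(rnorm(300)))  # independent of genotypes
  res <- marginal_gwas(g, y)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))  # 1% critical value
})

test_that("logistic-to-linear conversion follows the baseline-odds formula", {
  expect_equal(glm_to_lm(0.7, 0), 0)
  expect_equal(glm_to_lm(0, 1), 0.25)
  b0 <- log(2748 / 5222)
  expect_equal(glm_to_lm(b0, 0.2),
               exp(-b0) / (1 + exp(-b0))^2 * 0.2, tolerance = 1e-12)
  # odd in b1, symmetric in b0, multiplier maximized at b0 = 0
  expect_equal(glm_to_lm(1.3, -0.5), -glm_to_lm(1.3, 0.5))
  expect_equal(glm_to_lm(-2.1, 0.4), glm_to_lm(2.1, 0.4))
  b0s <- seq(-5, 5, by = 0.1)
  mult <- vapply(b0s, function(b) glm_to_lm(b, 1), 0)
  expect_equal(max(mult), 0.25)
  expect_equal(b0s[which.max(mult)], 0)
  # numerically stable for extreme baselines
  expect_equal(glm_to_lm(800, 1), 0)
  expect_error(glm_to_lm(Inf, 1), "finite")
})

test_that("baseline log odds come from case/control counts", {
  expect_equal(logit_baseline(100, 100), 0)
  expect_equal(logit_baseline(2748, 5222), log(2748 / 5222))
  expect_error(logit_baseline(1, 0), "positive")
  expect_error(logit_baseline(0, 10), "positive")
})

test_that("SNP panel selection keeps significant SNPs and tops up randomly", {
  g <- make_geno(10, 100, seed = 14)
  withr::with_seed(15, {
    p_values <- runif(100)
    p_values[1:40] <- runif(40, 0, 0.049)  # exactly 40 significant
    p_values[41:100] <- runif(60, 0.05, 1)
  })
  st <- make_stats(g, beta = rnorm(100), p_value = p_values)
  sel <- select_snps(st, 60, seed = 7)
  expect_length(sel, 60)
  sig_ids <- st$snp_id[st$p_value < 0.05]
  expect_true(all(sig_ids %in% sel))
  expect_equal(attr(sel, "n_significant"), 40)
  expect_equal(attr(sel, "n_random"), 20)
  # sorted by position
  pos <- st$pos_bp[match(sel, st$snp_id)]
  expect_true(!is.unsorted(pos))
  # determinism and seed sensitivity
  sel2 <- select_snps(st, 60, seed = 7)
  expect_identical(as.character(sel), as.character(sel2))
  sel3 <- select_snps(st, 60, seed = 8)
  expect_true(all(sig_ids %in% sel3))
  expect_false(identical(as.character(sel), as.character(sel3)))
  # exhaustive selection has no randomness
  sel_all <- select_snps(st, 100, seed = 1)
  expect_setequal(as.character(sel_all), st$snp_id)
  expect_error(select_snps(st, 101), "exceeds")
})
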