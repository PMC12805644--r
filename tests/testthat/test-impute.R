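test_that("gram_solve realizes the ridge pseudoinverse", {
  withr::with_seed(20, v <- rnorm(6))
  expect_equal(gram_solve(diag(6), v, 1e-6), v / (1 + 1e-6), tolerance = 1e-12)

  # random PSD system: residual check
  withr::with_seed(21, A <- crossprod(matrix(rnorm(400), 20, 20)))
  b <- rnorm(20)
  x <- gram_solve(A, b, 1e-6)
  expect_lt(sqrt(sum(((A + diag(1e-6, 20)) %*% x - b)^2)),
            1e-8 * sqrt(sum(b^2)))

  # rank-deficient Gram from duplicated rows matches an SVD pseudoinverse
  withr::with_seed(22, {
    X <- matrix(rnorm(30), 3, 10)
    X[3, ] <- X[1, ]
    w <- rnorm(10)
  })
  G <- tcrossprod(X)
  v2 <- drop(X %*% w)  # in the column space, where the ridge tracks the pinv
  sv <- svd(G)
  keep <- sv$d > 1e-10
  pinv_v <- sv$u[, keep] %*% ((crossprod(sv$v[, keep], v2)) / sv$d[keep])
  expect_lt(max(abs(gram_solve(G, v2, 1e-6) - pinv_v)), 1e-4)

  expect_error(gram_solve(matrix(c(1, 2, 0, 1), 2), c(1, 1)), "symmetric")
})

test_that("least-squares imputation is linear and recovers self-consistent traits", {
  g <- withr::with_seed(23, make_std_geno(matrix(rnorm(50 * 600), 50, 600)))
  withr::with_seed(23, beta <- rnorm(600, 0, 0.05))
  it <- ls_impute(g, beta)
  expect_s3_class(it, "imputed_trait")
  expect_identical(it$method, "single")
  # beta = 0 maps to 0
  expect_equal(ls_impute(g, rep(0, 600))$values, rep(0, 50))
  # linearity in beta
  expect_lt(max(abs(ls_impute(g, 3 * beta)$values - 3 * it$values)),
            1e-8 * max(1, max(abs(it$values))))
  # self-recovery: beta computed from (X, y) returns y up to the ridge
  withr::with_seed(24, y <- rnorm(50))
  y <- y - mean(y)  # the centered system recovers traits up to their mean
  b_self <- marginal_betas(g, y)
  rec <- ls_impute(g, b_self)
  expect_lt(sqrt(sum((rec$values - y)^2)) / sqrt(sum(y^2)), 1e-3)
  # beta as sumstats tibble in scrambled order aligns by snp_id
  st <- make_stats(g, beta)[sample(600), ]
  expect_equal(ls_impute(g, st)$values, it$values)
  # p <= n warns
  g2 <- make_std_geno(matrix(rnorm(30 * 10), 30, 10))
  expect_warning(ls_impute(g2, rep(0.1, 10)), "underdetermined")
})

test_that("combined imputation degenerates to single-ancestry at the endpoints", {
  X <- withr::with_seed(25, matrix(rnorm(40 * 500), 40, 500))
  g <- make_std_geno(X)
  g1 <- g[, 1:300]
  g2 <- g[, 150:500]
  withr::with_seed(25, {
    b1 <- rnorm(300, 0, 0.05)
    b2 <- rnorm(351, 0, 0.05)
  })
  c1 <- combined_impute(g1, b1, g2, b2, omega = 1)
  c0 <- combined_impute(g1, b1, g2, b2, omega = 0)
  expect_lt(max(abs(c1$values - ls_impute(g1, b1)$values)), 1e-10)
  expect_lt(max(abs(c0$values - ls_impute(g2, b2)$values)), 1e-10)
  # identical panels and betas: omega drops out
  vals <- sapply(seq(0, 1, 0.1), function(w) {
    combined_impute(g1, b1, g1, b1, w)$values
  })
  expect_lt(max(abs(sweep(vals, 1, vals[, 1]))), 1e-8)
  # sample misalignment errors
  g2b <- g2
  g2b$sample_ids <- rev(g2b$sample_ids)
  g2b$dosages <- g2b$dosages[rev(seq_len(40)), ]
  expect_error(combined_impute(g1, b1, genotype_matrix(
    g2b$dosages, g2b$snps, g2b$sample_ids, standardized = TRUE), b2, 0.5),
    "same samples")
})

test_that("transfer imputation converges to the target-only solution monotonically", {
  g <- withr::with_seed(26, make_std_geno(matrix(rnorm(60 * 800), 60, 800)))
  withr::with_seed(26, {
    beta <- rnorm(800, 0, 0.05)
    y0 <- rnorm(60)
    y0 <- y0 - mean(y0)  # standardized X is column-centered, so the
    # objective cannot see (or correct) a constant offset in Y
  })
  # zero epochs returns the initialization untouched
  cfg0 <- impute_config(max_epochs = 0)
  expect_identical(transfer_impute(g, beta, y0, cfg0)$values, y0)

  target <- ls_impute(g, beta)$values
  cfg <- impute_config(learning_rate = 2, max_epochs = 400, full_batch = TRUE)
  tr <- transfer_impute(g, beta, y0, cfg)
  expect_lt(sqrt(sum((tr$values - target)^2)) / sqrt(sum(target^2)), 1e-3)
  expect_true(all(diff(tr$trajectory$objective) <= 1e-10))
  # epoch-0 objective equals the objective at the initial value
  n <- 60
  obj0 <- sum((beta - drop(crossprod(g$dosages, y0)) / (n - 1))^2)
  expect_equal(tr$trajectory$objective[1], obj0, tolerance = 1e-10)

  # stochastic path is reproducible under the config seed
  cfg_s <- impute_config(learning_rate = 0.1, max_epochs = 20, seed = 99)
  t1 <- transfer_impute(g, beta, y0, cfg_s)
  t2 <- transfer_impute(g, beta, y0, cfg_s)
  expect_identical(t1$values, t2$values)

  # divergent learning rate aborts with the epoch in the condition
  cfg_bad <- impute_config(learning_rate = 1e8, max_epochs = 50)
  err <- tryCatch(transfer_impute(g, beta, y0, cfg_bad),
                  lsimpute_divergence = function(e) e)
  expect_s3_class(err, "lsimpute_divergence")
  expect_true(is.numeric(err$epoch) && err$epoch >= 1)
})

test_that("sample batching partitions cohorts and tracks the unbatched result", {
  g <- make_geno(100, 40, seed = 27)
  expect_length(split_batches(g, 2000), 1)
  b <- split_batches(make_geno(50, 5, seed = 28), 20)
  expect_equal(vapply(b, function(x) nrow(x$dosages), 0L), c(20L, 20L, 10L))
  expect_identical(unlist(lapply(b, function(x) x$sample_ids)),
                   make_geno(50, 5, seed = 28)$sample_ids)
  expect_error(split_batches(g, 1), ">= 2")

  # batched imputation correlates strongly with the unbatched run when the
  # SNP panel dwarfs the per-batch sample count (each batch solves its own
  # Gram system, so the results are close but not identical)
  graw <- make_geno(200, 8000, seed = 29, maf_range = c(0.05, 0.5))
  gs <- standardize_genotypes(graw)
  withr::with_seed(31, { y <- rnorm(200); y <- y - mean(y) })
  beta <- marginal_betas(gs, y)
  full <- ls_impute(gs, beta)
  batched <- ls_impute_batched(graw, beta, sample_batch_max = 100)
  expect_identical(batched$sample_ids, full$sample_ids)
  expect_gt(cor(batched$values, full$values), 0.99)
})
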