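test_that("trait correlation behaves like the textbook Pearson coefficient", {
  withr::with_seed(31, a <- rnorm(40))
  expect_equal(trait_cor(a, 2 * a + 1), 1)
  expect_equal(trait_cor(a, -a), -1)
  withr::with_seed(32, b <- rnorm(40))
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(trait_cor(a, b), manual, tolerance = 1e-12)
  expect_error(trait_cor(a, rep(1, 40)), "constant")
  expect_error(trait_cor(a[1:2], b[1:2]), "length")
})

test_that("AUC agrees with the ROC trapezoid and is rank-invariant", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(33, {
    labels <- rbinom(200, 1, 0.4)
    scores <- rnorm(200) + labels
  })
  a <- auc_score(scores, labels)
  pts <- roc_points(scores, labels)
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(a, trap, tolerance = 1e-10)
  # invariant under strictly increasing transforms
  expect_equal(auc_score(exp(scores), labels), a)
  expect_equal(auc_score(rank(scores), labels), a)
  expect_error(auc_score(scores, rep(1, 200)), "both classes")
  # independent oracle
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(a, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  sep <- roc_points(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  ties <- roc_points(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(ties), 2)
  expect_equal(ties$fpr, c(0, 1))
  expect_equal(ties$tpr, c(0, 1))
  withr::with_seed(34, {
    labels <- rbinom(50, 1, 0.5)
    scores <- rnorm(50)
  })
  pts <- roc_points(scores, labels)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(tail(pts$fpr, 1), 1); expect_equal(tail(pts$tpr, 1), 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("DeLong's paired test matches pROC and honors its conventions", {
  withr::with_seed(35, {
    labels <- rep(c(0, 1), each = 30)
    base <- rnorm(60)
    sa <- base + labels * 0.8
    sb <- 0.7 * base + rnorm(60, sd = 0.5) + labels * 0.5
  })
  res <- delong_test(sa, sb, labels)
  # identical scores: zero difference by convention
  same <- delong_test(sa, sa, labels)
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)
  # antisymmetry
  swapped <- delong_test(sb, sa, labels)
  expect_equal(swapped$z, -res$z, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  expect_gt(res$p_value, 0); expect_lte(res$p_value, 1)
  # independent oracle
  skip_if_not_installed("pROC")
  ra <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(unname(res$z), unname(as.numeric(ref$statistic)), tolerance = 1e-8)
  expect_equal(res$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("omega selection maximizes the validation metric with documented ties", {
  g <- make_std_geno(matrix(rnorm(40 * 300), 40, 300))
  withr::with_seed(36, {
    b1 <- rnorm(300, 0, 0.05)
    b2 <- rnorm(300, 0, 0.05)
    yv <- rnorm(40)
  })
  tr <- select_omega(g, b1, g, b2, yv, grid = seq(0, 1, 0.1))
  expect_s3_class(tr, "tuning_result")
  expect_equal(max(tr$grid$metric), tr$grid$metric[match(tr$selected, tr$grid$omega)])
  # identical statistics make every omega tie; the smaller one is selected
  tie <- select_omega(g, b1, g, b1, yv, grid = c(0.3, 0.7))
  expect_equal(tie$selected, 0.3)
  expect_error(select_omega(g, b1, g, b2, yv, grid = numeric(0)), "empty")
  # tidy/glance surfaces
  td <- tidy(tr)
  expect_true(all(c("omega", "metric", "selected") %in% names(td)))
  expect_equal(sum(td$selected), 1)
  gl <- glance(tr)
  expect_identical(gl$parameter, "omega")
})

test_that("epoch selection takes the argmax with earliest-epoch ties", {
  sel <- select_epochs(c(0.1, 0.3, 0.2))
  expect_equal(sel$selected, 2)
  expect_equal(select_epochs(c(0.5, 0.4, 0.3))$selected, 1)
  expect_equal(select_epochs(c(0.2, 0.4, 0.4))$selected, 2)
  # from a transfer trajectory, epoch 0 (the initialization) is a candidate
  traj <- tibble::tibble(epoch = 0:3, objective = c(4, 3, 2, 1),
                         metric = c(0.9, 0.5, 0.4, 0.3))
  expect_equal(select_epochs(traj)$selected, 0)
  expect_error(select_epochs(tibble::tibble(epoch = 1, metric = NA_real_)),
               "no recorded")
})
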