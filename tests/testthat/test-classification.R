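make_blobs <- function(n_per = 20, gap = 6, seed = 1, sd = 1) {
  set.seed(seed)
  tibble::tibble(
    group = factor(rep(c("HC", "RR"), each = n_per)),
    f1 = c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)),
    f2 = c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd))
  )
}

test_that("standardization uses training statistics only", {
  set.seed(2)
  train <- tibble::tibble(a = rnorm(100, 5, 3), b = rnorm(100, -2, 0.5))
  out <- standardize(train)
  expect_equal(unname(out$center), c(mean(train$a), mean(train$b)))
  expect_equal(unname(out$scale), c(sd(train$a), sd(train$b)))
  expect_equal(mean(out$train$a), 0, tolerance = 1e-12)
  expect_equal(sd(out$train$b), 1, tolerance = 1e-12)

  # already standardized -> near identity
  z <- tibble::tibble(a = as.numeric(scale(rnorm(50))))
  out2 <- standardize(z)
  expect_equal(out2$train$a, z$a, tolerance = 1e-8)

  # apply rows are transformed with train parameters, not their own
  apply_rows <- tibble::tibble(a = rep(1000, 3), b = rep(0, 3))
  out3 <- standardize(train, apply_rows)
  expect_equal(out3$apply$a, (1000 - mean(train$a)) / sd(train$a) + numeric(3))

  expect_warning(standardize(tibble::tibble(a = rep(4, 5))), "Constant")
  expect_error(standardize(tibble::tibble(a = numeric(0))),
               class = "connectoms_invalid_input")
})

test_that("the RBF kernel is a unit-diagonal symmetric similarity", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), log(2)), 0.5)
  set.seed(3)
  for (k in 1:10) {
    x <- rnorm(4); y <- rnorm(4); g <- runif(1, 0.01, 5)
    expect_equal(rbf_kernel(x, y, g), rbf_kernel(y, x, g))
    expect_lte(rbf_kernel(x, y, g), 1)
    expect_gt(rbf_kernel(x, y, g), 0)
  }
  expect_error(rbf_kernel(1, 1, 0), class = "connectoms_range_error")
  expect_error(rbf_kernel(c(1, 2), 1, 1), class = "connectoms_range_error")
})

test_that("the trained SVM satisfies the dual KKT contract", {
  blobs <- make_blobs(n_per = 20, gap = 6, seed = 11)
  fit <- train_svm(blobs, C = 1, gamma = 0.5)
  expect_equal(as.character(predict(fit, blobs)), as.character(blobs$group))
  expect_lte(max(fit$dual$alpha), fit$C + 1e-6)
  expect_gte(min(fit$dual$alpha), 0)
  expect_lt(abs(fit$dual$sum_alpha_y), 1e-6)

  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_lt(abs(gl$sum_alpha_y), 1e-6)
  expect_equal(nrow(tidy(fit)), fit$fit$tot.nSV)

  expect_error(train_svm(dplyr::filter(blobs, group == "HC"), 1, 1),
               "two classes", class = "connectoms_invalid_input")
})

test_that("the RBF kernel separates an XOR pattern a linear boundary cannot", {
  set.seed(21)
  n <- 25
  xor_df <- tibble::tibble(
    f1 = c(rnorm(n, 0, .3), rnorm(n, 3, .3), rnorm(n, 0, .3), rnorm(n, 3, .3)),
    f2 = c(rnorm(n, 0, .3), rnorm(n, 3, .3), rnorm(n, 3, .3), rnorm(n, 0, .3)),
    group = factor(rep(c("HC", "HC", "RR", "RR"), each = n))
  )
  fit <- train_svm(xor_df, C = 10, gamma = 1)
  acc <- mean(predict(fit, xor_df) == xor_df$group)
  expect_gt(acc, 0.95)
})

test_that("duplicating a separable training set leaves the decision function", {
  blobs <- make_blobs(n_per = 15, gap = 8, seed = 31)
  doubled <- dplyr::bind_rows(blobs, blobs)
  f1 <- train_svm(blobs, C = 100, gamma = 0.3)
  f2 <- train_svm(doubled, C = 100, gamma = 0.3)
  probe <- make_blobs(n_per = 10, gap = 8, seed = 32)
  d1 <- attr(predict(f1, probe, decision_values = TRUE), "decision.values")
  d2 <- attr(predict(f2, probe, decision_values = TRUE), "decision.values")
  # solver tolerance (libsvm eps) leaves sub-percent wiggle in the values
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 0.02)
  expect_identical(as.character(predict(f1, probe)),
                   as.character(predict(f2, probe)))
})

test_that("cross-validation folds partition the data with stratification", {
  y <- factor(rep(c("a", "b"), c(30, 18)))
  folds <- cv_folds(y, 6, seed = 5)
  expect_length(folds, 48)
  expect_setequal(unique(folds), 1:6)
  # each row in exactly one fold is implied by the assignment; check balance
  expect_true(all(table(folds, y)[, "a"] == 5))
  expect_true(all(table(folds, y)[, "b"] == 3))
  expect_identical(folds, cv_folds(y, 6, seed = 5))
  expect_error(cv_folds(factor("a"), 2), class = "connectoms_fold_error")
})

test_that("precision, recall and F follow their defining arithmetic", {
  expect_equal(unlist(precision_recall_f(3, 1, 0, 1)),
               c(precision = 0.75, recall = 0.75, f_measure = 0.75))
  expect_equal(precision_recall_f(1, 1, 0, 0)$f_measure, 2 / 3)
  expect_equal(precision_recall_f(1, 1, 0, 0)$precision, 0.5)
  expect_equal(precision_recall_f(0, 0, 5, 0)$f_measure, 0)
  expect_error(precision_recall_f(-1, 0, 0, 0), class = "connectoms_range_error")

  set.seed(8)
  for (k in 1:50) {
    cnt <- sample(0:20, 4, replace = TRUE)
    prf <- precision_recall_f(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(prf$f_measure, min(prf$precision, prf$recall) - 1e-12)
    expect_lte(prf$f_measure, max(prf$precision, prf$recall) + 1e-12)
    if (prf$precision == prf$recall) {
      expect_equal(prf$f_measure, prf$precision)
    }
  }
})

test_that("grid search returns the single pair of a singleton grid", {
  blobs <- make_blobs(seed = 41)
  g <- grid_spec(C = 4, gamma = 0.25, k = 5)
  res <- grid_search_cv(blobs, g, seed = 1)
  expect_equal(res$best_C, 4)
  expect_equal(res$best_gamma, 0.25)
  expect_equal(nrow(res$cv_results), 1)
})

test_that("grid search scores separable data near 1 and shuffled labels near 1/2", {
  blobs <- make_blobs(n_per = 30, gap = 6, seed = 51)
  res <- grid_search_cv(blobs, grid_spec(C = 2^c(-1, 3, 7),
                                         gamma = 2^c(-7, -3, 1), k = 10),
                        seed = 2)
  expect_gte(res$report$aggregate$f_measure, 0.95)

  # permutation null: mean best-F over shuffles sits near chance
  set.seed(61)
  null_f <- replicate(12, {
    shuffled <- blobs
    shuffled$group <- sample(shuffled$group)
    gs <- grid_search_cv(shuffled, grid_spec(C = 2^c(-1, 3, 7),
                                             gamma = 2^c(-7, -3, 1), k = 5),
                         seed = 3)
    gs$report$aggregate$f_measure
  })
  expect_gte(mean(null_f), 0.35)
  expect_lte(mean(null_f), 0.65)
})

test_that("preprocessing parameters come from the training folds only", {
  blobs <- make_blobs(n_per = 15, seed = 71)
  res <- grid_search_cv(blobs, grid_spec(C = 1, gamma = 0.5, k = 5),
                        seed = 4, diagnostics = TRUE)
  for (fold in 1:5) {
    tr <- blobs[res$folds != fold, c("f1", "f2")]
    expect_equal(unname(res$fold_prep[[fold]]$center),
                 unname(colMeans(tr)), tolerance = 1e-12)
    expect_equal(unname(res$fold_prep[[fold]]$scale),
                 unname(vapply(tr, sd, numeric(1))), tolerance = 1e-12)
  }
  # folds partition the rows
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_length(res$folds, nrow(blobs))
})

test_that("run_task validates names and reports one aggregate triple", {
  met <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:36),
    group = factor(rep(c("CIS", "RR", "SP"), each = 12)),
    D = rnorm(36), r = rnorm(36), T = rnorm(36),
    Eg = rnorm(36), Q = rnorm(36), CPL = rnorm(36)
  )
  expect_error(run_task(met, c("HC", "XX")), "Unknown group",
               class = "connectoms_invalid_input")
  expect_error(run_task(met, c("CIS", "RR"), features = c("Q", "bogus")),
               "Unknown metric", class = "connectoms_invalid_input")

  rep3 <- suppressWarnings(
    run_task(met, c("CIS", "RR", "SP"), features = "all",
             grid = grid_spec(C = 1, gamma = 0.1, k = 4), seed = 6)
  )
  expect_s3_class(rep3, "classification_report")
  expect_equal(nrow(rep3$aggregate), 1)
  expect_equal(nrow(rep3$per_class), 3)
  expect_equal(sum(rep3$per_class$support), 36)
  gl <- glance(rep3)
  expect_true(all(c("precision", "recall", "f_measure") %in% names(gl)))
  expect_equal(gl$task, "CIS-RR-SP")
})

test_that("missing feature values are imputed inside the folds with a warning", {
  blobs <- make_blobs(n_per = 15, seed = 81)
  blobs$f1[c(3, 20)] <- NA
  expect_warning(
    res <- grid_search_cv(blobs, grid_spec(C = 1, gamma = 0.5, k = 5), seed = 7),
    "imputed"
  )
  expect_equal(res$n_imputed, 2)
  expect_gte(res$report$aggregate$f_measure, 0.9)
})
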