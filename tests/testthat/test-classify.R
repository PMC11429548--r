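test_that("class weights balance the groups 1:1", {
  y <- rep(c("case", "control"), c(30, 70))
  w <- class_weights(y)
  expect_equal(unique(w[y == "case"]), 100 / 60)
  expect_equal(unique(w[y == "control"]), 100 / 140)
  expect_equal(sum(w[y == "case"]), sum(w[y == "control"]))
  expect_equal(sum(w), 100)
  expect_equal(class_weights(rep(0:1, 25)), rep(1, 50))
  # 71 vs 120: weight ratio is the inverse size ratio
  w2 <- class_weights(rep(c("a", "b"), c(71, 120)))
  expect_equal(unique(w2[1:71]) / unique(w2[72:191]), 120 / 71)
  expect_error(class_weights(rep("a", 5)), "two classes")
})

test_that("penalty limits behave as expected", {
  set.seed(42)
  X <- scale(matrix(rnorm(200), 50, 4))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(50, 0, 0.3) > 0)
  # heavy lasso zeroes every slope
  cf <- fit_regularized_logistic(X, y, alpha = 1, lambda = 50)
  expect_equal(unname(cf[-1]), rep(0, 4))
  # ridge coefficients shrink monotonically in lambda
  r_small <- fit_regularized_logistic(X, y, alpha = 0, lambda = 0.1)
  r_big <- fit_regularized_logistic(X, y, alpha = 0, lambda = 10)
  expect_lt(sum(r_big[-1]^2), sum(r_small[-1]^2))
  expect_error(fit_regularized_logistic(X, rep(1, 50), 0, 1), "class")
  expect_error(fit_regularized_logistic(X * NA, y, 0, 1), "finite")
})

test_that("a nearly unpenalized fit separates a separable toy set", {
  X <- scale(matrix(c(rnorm(25, -3), rnorm(25, 3)), ncol = 1))
  colnames(X) <- "f1"
  y <- rep(0:1, each = 25)
  cf <- fit_regularized_logistic(X, y, alpha = 0, lambda = 0.001)
  pred <- as.integer(cf[1] + X[, 1] * cf[2] > 0)
  expect_equal(mean(pred == y), 1)
})

test_that("confusion metrics follow their defining ratios", {
  out <- confusion_metrics(c(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(out$accuracy, 0.85)
  expect_equal(out$sensitivity, 0.8)
  expect_equal(out$specificity, 0.9)
  perfect <- confusion_metrics(c(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  # swapping class labels swaps sensitivity and specificity
  sw <- confusion_metrics(c(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(sw$sensitivity, out$specificity)
  expect_equal(sw$specificity, out$sensitivity)
  undef <- confusion_metrics(c(TP = 0, FN = 0, TN = 0, FP = 0))
  expect_true(all(is.na(unlist(undef))))
  expect_error(confusion_metrics(c(TP = -1, FN = 0, TN = 0, FP = 0)),
               "nonnegative")
})

test_that("grid search is deterministic and recovers separable structure", {
  set.seed(10)
  X <- scale(matrix(rnorm(200), 100, 2) +
               cbind(rep(c(0, 4), each = 50), rep(c(0, 4), each = 50)))
  colnames(X) <- c("f1", "f2")
  y <- rep(0:1, each = 50)
  cfg <- model_config(repeats = 3, seed = 123)
  a <- grid_search_cv(X, y, cfg)
  b <- grid_search_cv(X, y, cfg)
  expect_equal(a$alpha, b$alpha)
  expect_equal(a$lambda, b$lambda)
  expect_equal(a$cv_accuracy_mean, b$cv_accuracy_mean)
  expect_identical(a$coefficients, b$coefficients)
  expect_gt(a$cv_accuracy_mean, 0.95)
  # report arithmetic holds exactly
  cm <- a$confusion
  expect_equal(a$resubstitution$accuracy,
               (cm[["TP"]] + cm[["TN"]]) / sum(cm))
  expect_equal(a$resubstitution$sensitivity,
               cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]))
  expect_equal(a$resubstitution$specificity,
               cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]))
  # heavy regularization degrades towards the class-balanced 0.5 rate
  lam_sweep <- a$grid
  acc_10 <- lam_sweep$cv_accuracy[lam_sweep$alpha == 1 &
                                    lam_sweep$lambda == 10]
  expect_lt(acc_10, 0.6)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(11)
  X <- scale(matrix(rnorm(120), 60, 2) + rep(c(0, 3), each = 30))
  colnames(X) <- c("f1", "f2")
  fit <- grid_search_cv(X, rep(0:1, each = 30),
                        model_config(repeats = 2, seed = 3),
                        labels = c(positive = "SCLC", negative = "healthy"))
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(all(c("f1", "f2") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$positive, "SCLC")
  expect_true(gl$cv_accuracy >= 0 && gl$cv_accuracy <= 1)
})

test_that("balanced weights equal physically duplicating the minority", {
  set.seed(12)
  X <- scale(matrix(rnorm(60), 30, 2) + rep(c(0, 2), c(10, 20)))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(1, 0), c(10, 20))
  w <- class_weights(y)
  cf_w <- fit_regularized_logistic(X, y, alpha = 0, lambda = 0.5,
                                   weights = w)
  X_dup <- rbind(X, X[y == 1, ])
  y_dup <- c(y, rep(1, 10))
  cf_d <- fit_regularized_logistic(X_dup, y_dup, alpha = 0, lambda = 0.5,
                                   weights = rep(1, 40))
  expect_equal(unname(cf_w), unname(cf_d), tolerance = 1e-6)
})

test_that("backward elimination drops redundant and null features", {
  set.seed(13)
  n <- 80
  info <- matrix(rnorm(n * 2), n, 2) +
    cbind(rep(c(0, 2), each = n / 2), rep(c(0, 3.5), each = n / 2))
  X <- scale(cbind(info, dup = info[, 1]))
  colnames(X) <- c("f1", "f2", "f1_copy")
  y <- rep(0:1, each = n / 2)
  cfg <- model_config(repeats = 4, seed = 5)
  # tolerance sized to the CV noise of these small folds
  be <- backward_eliminate(X, y, cfg, tol = 0.02)
  # one of the duplicated pair goes, with no accuracy loss beyond tolerance
  expect_lt(length(be$panel), 3)
  expect_gte(be$fit$cv_accuracy_mean,
             max(be$path$cv_accuracy) - 0.02)
  # a single informative feature is a floor
  single <- backward_eliminate(X[, 1, drop = FALSE], y, cfg, tol = 0.02)
  expect_equal(single$panel, "f1")
  expect_error(backward_eliminate(X[, 0], y, cfg), "empty")
})

test_that("elimination discards planted null features", {
  set.seed(14)
  n <- 100
  X_info <- matrix(rnorm(n * 4), n, 4) + rep(c(0, 2.5), each = n / 2)
  X_null <- matrix(rnorm(n * 6), n, 6)
  X <- scale(cbind(X_info, X_null))
  colnames(X) <- c(paste0("info", 1:4), paste0("null", 1:6))
  y <- rep(0:1, each = n / 2)
  be <- backward_eliminate(X, y, model_config(repeats = 2, seed = 6))
  dropped <- setdiff(colnames(X), be$panel)
  expect_gte(sum(grepl("null", dropped)), 4)
  expect_true(any(grepl("info", be$panel)))
})
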