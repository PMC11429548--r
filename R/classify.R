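#' Configuration of the regularized-classifier grid search
#'
#' @param alphas Elastic-net mixing values to scan (0 = ridge, 1 = lasso).
#' @param lambdas Penalty strengths to scan. The penalty is
#'   `lambda * (alpha * ||b||_1 + (1 - alpha) * ||b||_2^2 / 2)` on top of
#'   the weighted binomial negative log-likelihood (glmnet's
#'   parameterization); the intercept is never penalized.
#' @param folds Cross-validation folds (stratified by class).
#' @param repeats Repetitions of the whole k-fold split.
#' @param seed Integer seed for fold assignment.
#' @return A list of class `model_config`.
#' @export
model_config <- function(alphas = c(0, 0.5, 1),
                         lambdas = c(0.001, 0.01, 0.1, 1, 10),
                         folds = 5, repeats = 10, seed = 1L) {
  if (folds < 2) abort("`folds` must be >= 2")
  if (any(alphas < 0 | alphas > 1)) abort("`alphas` must lie in [0, 1]")
  if (any(lambdas < 0)) abort("`lambdas` must be >= 0")
  structure(list(alphas = sort(unique(alphas)),
                 lambdas = sort(unique(lambdas)),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Per-sample weights balancing the two classes to a 1:1 ratio
#'
#' Each sample of class c receives weight `N / (2 * n_c)`, so both classes
#' contribute equal total weight and the weights average to 1.
#'
#' @param y Binary label vector (any two values).
#' @return Numeric weight per sample.
#' @export
#' @examples
#' table(class_weights(rep(c("a", "b"), c(30, 70))))
class_weights <- function(y) {
  tab <- table(y)
  if (length(tab) != 2) abort("`y` must contain exactly two classes")
  n <- length(y)
  as.numeric(n / (2 * tab[as.character(y)]))
}

#' Fit one weighted penalized logistic regression
#'
#' Thin wrapper around a binomial glmnet fit at a fixed (alpha, lambda),
#' with unpenalized intercept and no internal re-standardization (the
#' feature grid is expected to be z-scored already).
#'
#' @param X Complete numeric feature matrix (samples x metabolites).
#' @param y01 0/1 labels, 1 = positive (case) class.
#' @param alpha,lambda Elastic-net mixing and penalty strength.
#' @param weights Per-sample observation weights (default: balanced 1:1
#'   via [class_weights()]).
#' @return Named coefficient vector, first element `(Intercept)`.
#' @export
fit_regularized_logistic <- function(X, y01, alpha, lambda,
                                     weights = class_weights(y01)) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("`X` must be complete and finite")
  if (length(unique(y01)) != 2) abort("`y01` must contain both classes")
  fit <- glmnet_fit(X, y01, alpha, sort(unique(c(lambda, lambda * 10)),
                                        decreasing = TRUE), weights)
  drop_dummy(glmnet_coefs(fit, lambda), colnames(X))
}

# glmnet needs >= 2 columns; pad single-feature designs with an inert
# all-zero column whose coefficient stays 0
glmnet_fit <- function(X, y01, alpha, lambda_path, weights) {
  if (ncol(X) == 1) {
    X <- cbind(X, `.dummy.` = 0)
  }
  glmnet::glmnet(X, y01, family = "binomial", alpha = alpha,
                 lambda = lambda_path, weights = weights,
                 standardize = FALSE)
}

glmnet_coefs <- function(fit, lambda) {
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  setNames(cf[, 1], rownames(cf))
}

drop_dummy <- function(cf, feature_names) {
  cf[names(cf) != ".dummy."]
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' @param confusion Named numeric vector with elements `TP`, `FP`, `FN`,
#'   `TN` (positive = case class).
#' @return One-row tibble `accuracy`, `sensitivity`, `specificity`;
#'   undefined ratios (zero denominators) are returned as `NA`, never as
#'   errors or infinities.
#' @export
#' @examples
#' confusion_metrics(c(TP = 8, FP = 1, FN = 2, TN = 9))
confusion_metrics <- function(confusion) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(confusion)))
  if (any(confusion < 0)) abort("confusion cells must be nonnegative")
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  fn <- confusion[["FN"]]; tn <- confusion[["TN"]]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(accuracy = ratio(tp + tn, tp + fp + fn + tn),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp))
}

confusion_counts <- function(truth01, pred01) {
  c(TP = sum(truth01 == 1 & pred01 == 1),
    FP = sum(truth01 == 0 & pred01 == 1),
    FN = sum(truth01 == 1 & pred01 == 0),
    TN = sum(truth01 == 0 & pred01 == 0))
}

stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    if (length(idx) < k) {
      abort(paste0("class has only ", length(idx),
                   " samples; use fewer than ", k, " folds"))
    }
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Grid-searched, cross-validated regularized logistic classifier
#'
#' The second selection/modeling step: scans every (alpha, lambda) pair of
#' the [model_config()] grid with class-weighted binomial glmnet fits,
#' scoring each pair by stratified k-fold cross-validation repeated
#' `repeats` times (`folds * repeats` held-out estimates of accuracy,
#' sensitivity and specificity at the 0.5 probability threshold). The pair
#' with the highest mean CV accuracy wins; ties go to the larger lambda
#' (more regularization), then the larger alpha (sparser). The winning
#' model is refit on all samples and also evaluated on them
#' (resubstitution, reported as such).
#'
#' @inheritParams fit_regularized_logistic
#' @param config A [model_config()].
#' @param labels Optional c(positive, negative) class labels for reporting.
#' @return An object of class `nen_fit`; see [tidy.nen_fit()] and
#'   [glance.nen_fit()].
#' @export
grid_search_cv <- function(X, y01, config = model_config(),
                           labels = c(positive = "case", negative = "control")) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("`X` must be complete and finite")
  y01 <- as.integer(y01)
  if (!all(y01 %in% c(0L, 1L)) || length(unique(y01)) != 2) {
    abort("`y01` must be 0/1 with both classes present")
  }
  lam_path <- sort(config$lambdas, decreasing = TRUE)
  w_all <- class_weights(y01)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  cv <- vector("list", config$repeats * config$folds * length(config$alphas))
  slot <- 1L
  for (r in seq_len(config$repeats)) {
    fold <- stratified_folds(y01, config$folds)
    for (f in seq_len(config$folds)) {
      test <- fold == f
      wtr <- class_weights(y01[!test])
      for (a in config$alphas) {
        fit <- glmnet_fit(X[!test, , drop = FALSE], y01[!test], a,
                          lam_path, wtr)
        Xte <- X[test, , drop = FALSE]
        if (ncol(Xte) == 1) Xte <- cbind(Xte, `.dummy.` = 0)
        prob <- predict(fit, newx = Xte, s = lam_path, type = "response",
                        exact = FALSE)
        met <- lapply(seq_along(lam_path), function(li) {
          cm <- confusion_counts(y01[test], as.integer(prob[, li] >= 0.5))
          dplyr::bind_cols(tibble(repeat_ = r, fold = f, alpha = a,
                                  lambda = lam_path[li]),
                           confusion_metrics(cm))
        })
        cv[[slot]] <- bind_rows(met)
        slot <- slot + 1L
      }
    }
  }
  cv <- bind_rows(cv)

  grid <- cv %>%
    group_by(.data$alpha, .data$lambda) %>%
    summarise(cv_accuracy = mean(.data$accuracy),
              cv_accuracy_sd = sd(.data$accuracy),
              cv_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
              cv_specificity = mean(.data$specificity, na.rm = TRUE),
              .groups = "drop") %>%
    arrange(desc(.data$cv_accuracy), desc(.data$lambda), desc(.data$alpha))
  best <- grid[1, ]

  full <- glmnet_fit(X, y01, best$alpha, lam_path, w_all)
  coefs <- drop_dummy(glmnet_coefs(full, best$lambda), colnames(X))
  beta <- coefs[setdiff(names(coefs), "(Intercept)")]
  retained <- names(beta)[beta != 0]

  Xp <- if (ncol(X) == 1) cbind(X, `.dummy.` = 0) else X
  prob_full <- as.numeric(predict(full, newx = Xp, s = best$lambda,
                                  type = "response", exact = FALSE))
  confusion <- confusion_counts(y01, as.integer(prob_full >= 0.5))

  structure(list(
    labels = labels,
    alpha = best$alpha, lambda = best$lambda,
    family = if (best$alpha == 1) "lasso" else if (best$alpha == 0) "ridge" else "elastic net",
    coefficients = coefs, retained = retained,
    cv = cv, grid = grid,
    cv_accuracy_mean = best$cv_accuracy,
    cv_accuracy_sd = best$cv_accuracy_sd,
    cv_accuracy_ci = c(lower = best$cv_accuracy - 1.96 * best$cv_accuracy_sd,
                       upper = best$cv_accuracy + 1.96 * best$cv_accuracy_sd),
    cv_sensitivity = best$cv_sensitivity,
    cv_specificity = best$cv_specificity,
    confusion = confusion,
    resubstitution = confusion_metrics(confusion),
    n = length(y01), config = config
  ), class = "nen_fit")
}

#' Backward elimination over a metabolite panel
#'
#' Starting from the panel pre-selected by [bootstrap_select()],
#' repeatedly drops the feature with the smallest absolute standardized
#' coefficient in the current best grid-searched model, stopping when a
#' removal costs more than `tol` mean CV accuracy (or one feature
#' remains), and returns the smallest panel whose accuracy stays within
#' `tol` of the best seen.
#'
#' @inheritParams grid_search_cv
#' @param tol Tolerated drop in mean CV accuracy (default 0.005, i.e. half
#'   a percentage point).
#' @return A list: `panel` (retained metabolite names), `fit` (the
#'   `nen_fit` for that panel) and `path` (tibble of panel size vs
#'   accuracy).
#' @export
backward_eliminate <- function(X, y01, config = model_config(), tol = 0.005,
                               labels = c(positive = "case", negative = "control")) {
  X <- as.matrix(X)
  if (ncol(X) < 1) abort("initial panel is empty")
  panel <- colnames(X)
  fits <- list()
  steps <- list()
  best_acc <- -Inf
  repeat {
    fit <- grid_search_cv(X[, panel, drop = FALSE], y01, config, labels)
    fits[[length(fits) + 1L]] <- list(panel = panel, fit = fit)
    steps[[length(steps) + 1L]] <- tibble(n_features = length(panel),
                                          cv_accuracy = fit$cv_accuracy_mean)
    best_acc <- max(best_acc, fit$cv_accuracy_mean)
    if (length(panel) == 1 || fit$cv_accuracy_mean < best_acc - tol) break
    beta <- fit$coefficients[panel]
    drop <- panel[which.min(abs(beta))]
    panel <- setdiff(panel, drop)
  }
  path <- bind_rows(steps)
  ok <- which(path$cv_accuracy >= best_acc - tol)
  pick <- ok[which.min(path$n_features[ok])]
  list(panel = fits[[pick]]$panel, fit = fits[[pick]]$fit, path = path)
}

#' Fit the subtype-vs-control classifier from pipeline tables
#'
#' Convenience wrapper: restricts the concentration matrix to the given
#' samples and metabolites, z-scores the subset jointly, applies backward
#' elimination over the grid-searched weighted models, and labels the
#' report with the group names (case = positive class).
#'
#' @inheritParams fold_change
#' @param metabolites Character vector of pre-selected metabolites.
#' @param config A [model_config()].
#' @param eliminate Run [backward_eliminate()] (default) or keep the full
#'   panel.
#' @return An `nen_fit` object (with `$panel` attribute when eliminated).
#' @export
fit_group_classifier <- function(conc, samples, case, control, metabolites,
                                 config = model_config(), eliminate = TRUE) {
  if (length(metabolites) == 0) abort("initial panel is empty")
  ids <- samples$sample_id[samples$group %in% c(case, control)]
  sub <- conc[conc$sample_id %in% ids, c("sample_id", metabolites)]
  sub <- zscore_metabolites(impute_missing(sub))
  y01 <- as.integer(samples$group[match(sub$sample_id, samples$sample_id)]
                    %in% case)
  X <- as.matrix(sub[, metabolites, drop = FALSE])
  labels <- c(positive = paste(case, collapse = "+"),
              negative = paste(control, collapse = "+"))
  if (eliminate) {
    be <- backward_eliminate(X, y01, config, labels = labels)
    fit <- be$fit
    fit$panel_path <- be$path
    fit
  } else {
    grid_search_cv(X, y01, config, labels)
  }
}

#' @export
print.nen_fit <- function(x, ...) {
  cat("<nen_fit> ", x$labels[["positive"]], " vs ", x$labels[["negative"]],
      "\n", sep = "")
  cat("  model: ", x$family, " (alpha = ", x$alpha, ", lambda = ", x$lambda,
      "), ", length(x$retained), " metabolites retained\n", sep = "")
  cat(sprintf("  CV accuracy: %.2f%% (95%% CI %.2f%%-%.2f%%)\n",
              100 * x$cv_accuracy_mean,
              100 * max(0, x$cv_accuracy_ci[["lower"]]),
              100 * min(1, x$cv_accuracy_ci[["upper"]])))
  r <- x$resubstitution
  cat(sprintf("  resubstitution: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              100 * r$accuracy, 100 * r$sensitivity, 100 * r$specificity))
  invisible(x)
}

#' Tidy the coefficients of a fitted classifier
#'
#' @param x An `nen_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `retained`.
#' @method tidy nen_fit
#' @export
tidy.nen_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients)) %>%
    mutate(retained = .data$term %in% c("(Intercept)", x$retained))
}

#' One-row model summary of a fitted classifier
#'
#' @inheritParams tidy.nen_fit
#' @return A one-row tibble with the chosen hyperparameters, CV metrics
#'   and resubstitution metrics.
#' @method glance nen_fit
#' @export
glance.nen_fit <- function(x, ...) {
  tibble(
    positive = x$labels[["positive"]], negative = x$labels[["negative"]],
    family = x$family, alpha = x$alpha, lambda = x$lambda,
    n_retained = length(x$retained), n = x$n,
    cv_accuracy = x$cv_accuracy_mean, cv_accuracy_sd = x$cv_accuracy_sd,
    cv_ci_lower = x$cv_accuracy_ci[["lower"]],
    cv_ci_upper = x$cv_accuracy_ci[["upper"]],
    cv_sensitivity = x$cv_sensitivity, cv_specificity = x$cv_specificity,
    accuracy = x$resubstitution$accuracy,
    sensitivity = x$resubstitution$sensitivity,
    specificity = x$resubstitution$specificity
  )
}
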