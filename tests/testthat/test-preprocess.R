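test_that("missingness filter drops strictly-above-threshold metabolites", {
  # 4 samples: m1 complete, m2 missing 50% (kept), m3 missing 75% (dropped)
  conc <- conc_tibble(cbind(c(1, 2, 3, 4),
                            c(1, NA, 3, NA),
                            c(NA, NA, NA, 4)))
  out <- filter_missingness(conc)
  expect_equal(names(out), c("sample_id", "M001", "M002"))
  # identity on complete data, idempotence in general
  expect_equal(filter_missingness(conc_tibble(diag(3) + 1)),
               conc_tibble(diag(3) + 1))
  expect_equal(filter_missingness(out), out)
  all_gone <- conc_tibble(matrix(NA_real_, 4, 2))
  expect_error(filter_missingness(all_gone), "empty panel")
})

test_that("study-preset cohort filters from 166 to 153 metabolites", {
  co <- study_cohort()
  expect_equal(ncol(co$concentrations) - 1, 166)
  expect_equal(ncol(filter_missingness(co$concentrations)) - 1, 153)
})

test_that("half-minimum imputation fills gaps and leaves complete data alone", {
  conc <- conc_tibble(cbind(c(2, 4, NA), c(1, 2, 3)))
  out <- impute_missing(conc)
  expect_equal(out$M001, c(2, 4, 1))
  expect_equal(out$M002, conc$M002)
  complete <- conc_tibble(matrix(1:6, 3))
  expect_equal(impute_missing(complete), complete)
  expect_equal(impute_missing(conc, strategy = "none"), conc)
  expect_error(impute_missing(conc_tibble(matrix(NA_real_, 3, 1))),
               "filter")
})

test_that("z-scores have zero mean, unit n-1 SD, and reject degenerate input", {
  conc <- conc_tibble(matrix(rnorm(60, 5, 2), 20, 3))
  z <- zscore_metabolites(conc)
  for (j in 2:4) {
    expect_equal(mean(z[[j]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[j]]), 1, tolerance = 1e-12)
  }
  two <- zscore_metabolites(conc_tibble(matrix(c(1, 3), 2, 1)))
  expect_equal(two$M001, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_error(zscore_metabolites(conc_tibble(matrix(2, 3, 1))), "M001")
  expect_error(zscore_metabolites(conc_tibble(cbind(c(1, NA, 3)))), "missing")
})

test_that("fold change is the ratio of case to control means", {
  conc <- conc_tibble(cbind(c(1, 2, 3, 2, 4, 6)))
  samples <- sample_tibble(rep(c("control", "case"), each = 3))
  fc <- fold_change(conc, samples, "case", "control")
  expect_equal(fc$X, 2)
  expect_equal(fc$Y, 4)
  expect_equal(fc$fc, 2)
  expect_equal(fc$log2fc, 1)
  # identical groups give fc = 1; reversing roles inverts the ratio
  same <- conc_tibble(cbind(rep(c(5, 6, 7), 2)))
  expect_equal(fold_change(same, samples, "case", "control")$fc, 1)
  rev_fc <- fold_change(conc, samples, "control", "case")
  expect_equal(fc$fc * rev_fc$fc, 1)
  # zero control mean is flagged, never Inf
  zero <- conc_tibble(cbind(c(0, 0, 0, 1, 2, 3)))
  expect_warning(out <- fold_change(zero, samples, "case", "control"),
                 "undefined")
  expect_true(is.na(out$fc))
})

test_that("median summary for fold change is available", {
  conc <- conc_tibble(cbind(c(1, 2, 100, 2, 4, 6)))
  samples <- sample_tibble(rep(c("control", "case"), each = 3))
  expect_equal(fold_change(conc, samples, "case", "control",
                           summary = "median")$fc, 2)
})

test_that("demographics tests behave symmetrically and detect imbalance", {
  s <- sample_tibble(rep("a", 10))
  s$age <- seq(50, 70, length.out = 10)
  s$bmi <- seq(20, 30, length.out = 10)
  out <- compare_demographics(s, s)
  expect_equal(out$statistic[out$variable == "age"], 0)
  expect_equal(out$p[out$variable == "age"], 1)
  expect_equal(out$p[out$variable == "bmi"], 1)
  # fully imbalanced 2x2 sex table
  a <- sample_tibble(rep("a", 10)); a$sex <- "female"
  b <- sample_tibble(rep("b", 10)); b$sex <- "male"
  a$age <- seq(50, 70, length.out = 10); b$age <- seq(51, 72, length.out = 10)
  a$bmi <- seq(22, 30, length.out = 10); b$bmi <- seq(21, 31, length.out = 10)
  out2 <- compare_demographics(a, b)
  expect_lt(out2$p[out2$variable == "sex"], 0.01)
  # absent variable is omitted with a warning
  expect_warning(out3 <- compare_demographics(a[, names(a) != "bmi"], b),
                 "bmi")
  expect_false("bmi" %in% out3$variable)
})

test_that("rank-based testing is invariant to z-scoring", {
  co <- simulate_cohort(two_group_design(20, 25, n_metabolites = 8,
                                         log2fc = c(1, rep(0, 7))),
                        seed = 21)
  g <- co$samples$group
  z <- zscore_metabolites(co$concentrations)
  for (j in 2:9) {
    raw <- mann_whitney(co$concentrations[[j]][g == "case"],
                        co$concentrations[[j]][g == "control"])
    std <- mann_whitney(z[[j]][g == "case"], z[[j]][g == "control"])
    expect_equal(raw$U, std$U)
    expect_equal(raw$p, std$p)
  }
})
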