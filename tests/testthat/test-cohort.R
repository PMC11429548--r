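test_that("the default design matches the emulated study layout", {
  d <- cohort_design()
  expect_equal(nrow(d$panel), 166)
  expect_equal(unname(d$group_sizes["healthy"]), 71L)
  expect_equal(sum(d$group_sizes[c("carcinoid", "SCLC", "LCNEC")]), 120L)
  expect_equal(unname(d$group_sizes["NSCLC"]), 466L)
  expect_equal(sum(d$panel$missing_prob > 0.5), 13)
  # glucose is planted only for carcinoids
  glu <- d$effects[d$effects$metabolite == "Glucose", ]
  expect_equal(glu$group, "carcinoid")
  expect_true(glu$log2fc > 0)
  # subtype-unique amines
  expect_equal(d$effects$group[d$effects$metabolite == "N-acetylputrescine"],
               "SCLC")
  expect_equal(d$effects$group[d$effects$metabolite == "Spermine"], "LCNEC")
  # every effect refers to a panel metabolite and a known group
  expect_true(all(d$effects$metabolite %in% d$panel$metabolite))
  expect_true(all(d$effects$group %in% names(d$group_sizes)))
})

test_that("design validation names the offending field", {
  d <- cohort_design()
  d$group_sizes["SCLC"] <- 1L
  expect_error(validate_cohort_design(d), "group_sizes")
  d <- cohort_design()
  d$panel$log_sd[5] <- 0
  expect_error(validate_cohort_design(d), "log_sd")
  d <- cohort_design()
  d$effects$metabolite[1] <- "no such metabolite"
  expect_error(validate_cohort_design(d), "effects")
  expect_error(
    simulate_cohort(cohort_design(group_sizes = c(healthy = 1L, SCLC = 40L)),
                    seed = 1),
    "group_sizes")
})

test_that("simulation is deterministic in (design, seed)", {
  d <- two_group_design(n_case = 10, n_control = 12, n_metabolites = 5,
                        missing_prob = 0.2)
  a <- simulate_cohort(d, seed = 99)
  b <- simulate_cohort(d, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_cohort(d, seed = 100)
  expect_false(identical(a$concentrations, c2$concentrations))
})

test_that("planted log2 fold changes are realized on the concentration scale", {
  d <- two_group_design(n_case = 500, n_control = 500, n_metabolites = 6,
                        log2fc = c(1, 1, -1, 0, 0, 2))
  co <- simulate_cohort(d, seed = 7)
  g <- co$samples$group
  for (j in c(1, 2, 3, 6)) {
    x <- co$concentrations[[j + 1]]
    ratio <- exp(mean(log(x[g == "case"])) - mean(log(x[g == "control"])))
    planted <- c(1, 1, -1, 0, 0, 2)[j]
    expect_lt(abs(log2(ratio) - planted), 0.1)
  }
  # a planted log2FC of 1 realizes a geometric-mean ratio near 2
  x <- co$concentrations[[2]]
  ratio <- exp(mean(log(x[g == "case"])) - mean(log(x[g == "control"])))
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("both missingness mechanisms realize their design probability", {
  for (mech in c("mcar", "lod")) {
    d <- two_group_design(n_case = 300, n_control = 300, n_metabolites = 3,
                          missing_prob = c(0, 0.3, 0.7), mechanism = mech)
    co <- simulate_cohort(d, seed = 11)
    frac <- vapply(co$concentrations[-1], function(x) mean(is.na(x)),
                   numeric(1))
    expect_equal(unname(frac), c(0, 0.3, 0.7), tolerance = 0.05)
  }
})

test_that("left-censoring removes the low tail, not random cells", {
  d <- two_group_design(n_case = 200, n_control = 200, n_metabolites = 1,
                        missing_prob = 0.4, mechanism = "lod")
  co <- simulate_cohort(d, seed = 5)
  x <- co$concentrations[[2]]
  # reconstruct the censored draws by re-simulating without missingness
  d0 <- two_group_design(n_case = 200, n_control = 200, n_metabolites = 1,
                         missing_prob = 0)
  full <- simulate_cohort(d0, seed = 5)$concentrations[[2]]
  expect_true(all(full[is.na(x)] < min(x, na.rm = TRUE)))
})

test_that("under the null, pooled per-metabolite p-values are uniform", {
  d <- two_group_design(n_case = 200, n_control = 200, n_metabolites = 100,
                        log2fc = 0)
  co <- simulate_cohort(d, seed = 12)
  g <- co$samples$group
  p <- vapply(co$concentrations[-1], function(x) {
    mann_whitney(x[g == "case"], x[g == "control"])$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("cohort fixtures round-trip through CSV exactly", {
  d <- two_group_design(n_case = 3, n_control = 2, n_metabolites = 4,
                        missing_prob = c(0, 0.5, 0, 0))
  co <- simulate_cohort(d, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- read_concentrations(paths[["concentrations"]])
  expect_equal(back, co$concentrations)
  expect_equal(read_samples(paths[["samples"]]), co$samples)
  lines <- readLines(paths[["concentrations"]])
  expect_length(lines, 6)  # header + 5 samples
  if (anyNA(co$concentrations)) {
    expect_match(paste(lines, collapse = "\n"), "NA")
    expect_false(any(grepl(",0,|,0$", lines[-1])))
  }
})
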