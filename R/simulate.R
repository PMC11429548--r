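#' Simulate a synthetic plasma metabolomics cohort
#'
#' Draws a complete case-control cohort from a [cohort_design()]:
#' per-sample metadata (group, age, sex, smoking status, BMI, stage) from
#' the design's per-group covariate distributions, and a samples-by-
#' metabolites concentration matrix. Concentrations are log-normal: the
#' natural-log concentration of metabolite *j* in a sample of group *g* is
#' `log_mean_j + log(2) * log2fc_{j,g} + N(0, log_sd_j)`, so planted
#' effects are multiplicative on the concentration (uM) scale and the
#' case/control ratio of geometric means equals `2^log2fc` in expectation.
#' Missing values are then introduced per metabolite, either completely at
#' random (`"mcar"`, each cell independently with the design probability)
#' or by left-censoring below a limit of detection (`"lod"`, the lowest
#' fraction of that metabolite's draws is removed).
#'
#' The same `(design, seed)` pair always yields bit-identical output.
#'
#' @param design A validated [cohort_design()].
#' @param seed Integer seed controlling every random draw.
#' @return A list with components `concentrations` (tibble: `sample_id`
#'   plus one numeric column per panel metabolite, `NA` marking missing
#'   cells) and `samples` (tibble: `sample_id`, `group`, `age`, `sex`,
#'   `smoking`, `bmi`, `stage`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_design(), seed = 1)
#' dim(cohort$concentrations)  # 657 x 167
simulate_cohort <- function(design, seed) {
  validate_cohort_design(design)
  if (length(seed) != 1 || !is.finite(seed)) abort("`seed` must be a single integer")

  gs <- design$group_sizes
  n <- sum(gs)
  pan <- design$panel
  m <- nrow(pan)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  group <- rep(names(gs), times = gs)
  sample_id <- sprintf("S%04d", seq_len(n))

  cov <- design$covariates
  idx <- match(group, cov$group)
  age <- round(rnorm(n, cov$age_mean[idx], cov$age_sd[idx]), 1)
  bmi <- round(pmax(rnorm(n, cov$bmi_mean[idx], cov$bmi_sd[idx]), 15), 1)
  sex <- ifelse(stats::runif(n) < cov$p_female[idx], "female", "male")
  smoke_p <- as.matrix(cov[idx, c("p_current", "p_ex", "p_non", "p_passive")])
  smoke_lev <- c("current", "ex", "non", "passive")
  smoking <- vapply(seq_len(n), function(i) {
    sample(smoke_lev, 1L, prob = smoke_p[i, ])
  }, character(1))
  stage <- vapply(seq_len(n), function(i) {
    p <- cov$p_stage[[idx[i]]]
    if (is.null(p)) NA_character_ else sample(names(p), 1L, prob = p)
  }, character(1))

  samples <- tibble(sample_id = sample_id, group = group, age = age,
                    sex = sex, smoking = smoking, bmi = bmi, stage = stage)

  # planted log2 effects as an m x groups lookup, zero by default
  eff <- matrix(0, nrow = m, ncol = length(gs),
                dimnames = list(pan$metabolite, names(gs)))
  if (nrow(design$effects) > 0) {
    eff[cbind(match(design$effects$metabolite, pan$metabolite),
              match(design$effects$group, names(gs)))] <- design$effects$log2fc
  }

  logc <- matrix(rnorm(n * m), nrow = n, ncol = m)
  logc <- sweep(logc, 2, pan$log_sd, `*`)
  logc <- sweep(logc, 2, pan$log_mean, `+`)
  logc <- logc + log(2) * t(eff[, group, drop = FALSE])

  if (design$confounded) {
    # optional confound: current smoking raises a few amines by ~log2(1.5)
    conf <- pan$metabolite %in% c("Putrescine", "Spermidine", "Kynurenine")
    logc[smoking == "current", conf] <- logc[smoking == "current", conf] +
      log(1.5)
  }

  conc <- exp(logc)

  for (j in seq_len(m)) {
    p <- pan$missing_prob[j]
    if (p <= 0) next
    if (pan$missing_mechanism[j] == "mcar") {
      conc[stats::runif(n) < p, j] <- NA_real_
    } else {
      k <- round(p * n)
      if (k > 0) conc[order(conc[, j])[seq_len(k)], j] <- NA_real_
    }
  }

  colnames(conc) <- pan$metabolite
  concentrations <- dplyr::bind_cols(tibble(sample_id = sample_id),
                                     as_tibble(conc))
  list(concentrations = concentrations, samples = samples)
}

#' Write a simulated cohort to CSV fixtures
#'
#' Writes `concentrations.csv` (first column `sample_id`, one column per
#' metabolite, missing cells as the literal token `NA`) and `samples.csv`
#' in the dialect the preprocessing functions read back. Values round-trip
#' exactly (shortest round-trippable decimal representation).
#'
#' @param cohort A list with `concentrations` and `samples` tibbles, as
#'   returned by [simulate_cohort()].
#' @param dir Directory to write into (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort),
            all(c("concentrations", "samples") %in% names(cohort)))
  if (!identical(cohort$concentrations$sample_id, cohort$samples$sample_id)) {
    abort("concentrations and samples disagree on sample_id")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(concentrations = file.path(dir, "concentrations.csv"),
             samples = file.path(dir, "samples.csv"))
  readr::write_csv(cohort$concentrations, paths[["concentrations"]], na = "NA")
  readr::write_csv(cohort$samples, paths[["samples"]], na = "NA")
  invisible(paths)
}

#' Read a concentration matrix / sample table written by [write_cohort()]
#'
#' @param path Path to `concentrations.csv` or `samples.csv`.
#' @return A tibble; all metabolite columns numeric, `NA` for missing.
#' @export
read_concentrations <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = "NA",
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           .default = readr::col_double()))
  if (!"sample_id" %in% names(out)) abort("no sample_id column in file")
  strip_readr_attrs(out)
}

#' @rdname read_concentrations
#' @export
read_samples <- function(path) {
  strip_readr_attrs(
    readr::read_csv(path, show_col_types = FALSE, na = "NA",
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      group = readr::col_character(),
                      age = readr::col_double(),
                      sex = readr::col_character(),
                      smoking = readr::col_character(),
                      bmi = readr::col_double(),
                      stage = readr::col_character())))
}

strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}
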