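#' Drop metabolites with excessive missingness
#'
#' Removes every metabolite whose missing fraction across all samples is
#' strictly greater than `max_missing_frac` (default 0.5: metabolites with
#' more than 50% missing values are excluded; a metabolite missing in
#' exactly half the samples is retained). Samples and column order are
#' untouched, so the operation is idempotent.
#'
#' @param conc Concentration tibble: `sample_id` plus numeric metabolite
#'   columns, `NA` marking missing values.
#' @param max_missing_frac Highest tolerated missing fraction.
#' @return The filtered concentration tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_design(), seed = 1)
#' ncol(filter_missingness(cohort$concentrations)) - 1  # 153
filter_missingness <- function(conc, max_missing_frac = 0.5) {
  mets <- metabolite_cols(conc)
  if (length(mets) == 0) abort("`conc` has no metabolite columns")
  frac <- vapply(conc[mets], function(x) mean(is.na(x)), numeric(1))
  keep <- mets[frac <= max_missing_frac]
  if (length(keep) == 0) {
    abort("empty panel: every metabolite exceeds the missingness threshold")
  }
  dplyr::select(conc, "sample_id", all_of(keep))
}

#' Impute residual missing concentrations
#'
#' `"halfmin"` (default) replaces each missing cell with half the smallest
#' observed concentration of that metabolite — the usual stand-in for
#' values below the limit of detection. `"none"` passes missing values
#' through unchanged (rank-based selection tolerates them; the classifier
#' does not).
#'
#' @inheritParams filter_missingness
#' @param strategy `"halfmin"` or `"none"`.
#' @return A concentration tibble with no missing cells (for `"halfmin"`).
#' @export
impute_missing <- function(conc, strategy = c("halfmin", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(conc)
  mets <- metabolite_cols(conc)
  for (mcol in mets) {
    x <- conc[[mcol]]
    if (anyNA(x)) {
      if (all(is.na(x))) {
        abort(paste0("metabolite '", mcol,
                     "' has no observed values; filter it out first"))
      }
      x[is.na(x)] <- min(x, na.rm = TRUE) / 2
      conc[[mcol]] <- x
    }
  }
  conc
}

#' Standardize each metabolite to z-scores
#'
#' Centers and scales every metabolite column to mean 0 and sample
#' (n - 1) standard deviation 1, computed jointly over all samples in the
#' table (cases and controls together). Requires complete data.
#'
#' @inheritParams filter_missingness
#' @return The standardized tibble.
#' @export
zscore_metabolites <- function(conc) {
  mets <- metabolite_cols(conc)
  for (mcol in mets) {
    x <- conc[[mcol]]
    if (anyNA(x)) abort(paste0("metabolite '", mcol,
                               "' has missing values; impute or filter first"))
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(paste0("metabolite '", mcol, "' has zero variance"))
    }
    conc[[mcol]] <- (x - mean(x)) / s
  }
  conc
}

#' Case/control fold changes per metabolite
#'
#' Computes FC = Y/X per metabolite, where Y is the case-group and X the
#' control-group summary of the raw (never z-scored) concentrations over
#' observed values only. The arithmetic mean is the default summary; the
#' median is available as an option.
#'
#' @inheritParams filter_missingness
#' @param samples Sample table with `sample_id` and `group`.
#' @param case,control Group label(s); several labels pool into one group
#'   (e.g. `c("carcinoid", "SCLC", "LCNEC")` for all NENs).
#' @param summary `"mean"` (default) or `"median"`.
#' @return A tibble with columns `metabolite`, `X` (control summary), `Y`
#'   (case summary), `fc` and `log2fc`. An undefined ratio (X = 0) yields
#'   `NA` with a warning, never a silent infinity.
#' @export
fold_change <- function(conc, samples, case, control,
                        summary = c("mean", "median")) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  case_ids <- samples$sample_id[samples$group %in% case]
  ctrl_ids <- samples$sample_id[samples$group %in% control]
  if (length(case_ids) == 0) abort("case group is empty")
  if (length(ctrl_ids) == 0) abort("control group is empty")
  mets <- metabolite_cols(conc)
  in_case <- conc$sample_id %in% case_ids
  in_ctrl <- conc$sample_id %in% ctrl_ids
  Y <- vapply(conc[mets], function(x) fun(x[in_case]), numeric(1))
  X <- vapply(conc[mets], function(x) fun(x[in_ctrl]), numeric(1))
  fc <- ifelse(is.finite(X) & X > 0, Y / X, NA_real_)
  if (anyNA(fc)) {
    warn(paste0("fold change undefined (control summary 0 or missing) for: ",
                paste(mets[is.na(fc)], collapse = ", ")))
  }
  tibble(metabolite = mets, X = unname(X), Y = unname(Y),
         fc = unname(fc), log2fc = log2(unname(fc)))
}

#' Compare cohort demographics between two sample tables
#'
#' Welch two-sample t-tests for age and BMI; chi-square tests on the sex
#' and smoking contingency tables (categories absent from both tables are
#' dropped first). Variables missing from either table are omitted with a
#' warning.
#'
#' @param samples_a,samples_b Sample tables (see [simulate_cohort()]).
#' @return A tibble with columns `variable`, `test`, `statistic`, `p`.
#' @export
compare_demographics <- function(samples_a, samples_b) {
  if (nrow(samples_a) == 0 || nrow(samples_b) == 0) {
    abort("both sample tables must be non-empty")
  }
  rows <- list()
  for (v in c("age", "bmi")) {
    if (!v %in% names(samples_a) || !v %in% names(samples_b)) {
      warn(paste0("variable '", v, "' absent; omitted"))
      next
    }
    tt <- t.test(samples_a[[v]], samples_b[[v]])
    rows[[v]] <- tibble(variable = v, test = "Welch t",
                        statistic = unname(tt$statistic), p = tt$p.value)
  }
  for (v in c("sex", "smoking")) {
    if (!v %in% names(samples_a) || !v %in% names(samples_b)) {
      warn(paste0("variable '", v, "' absent; omitted"))
      next
    }
    lev <- union(unique(samples_a[[v]]), unique(samples_b[[v]]))
    tab <- rbind(table(factor(samples_a[[v]], levels = lev)),
                 table(factor(samples_b[[v]], levels = lev)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    ct <- suppressWarnings(chisq.test(tab))
    rows[[v]] <- tibble(variable = v, test = "chi-square",
                        statistic = unname(ct$statistic), p = ct$p.value)
  }
  bind_rows(rows)
}

metabolite_cols <- function(conc) {
  if (!"sample_id" %in% names(conc)) abort("`conc` must have a sample_id column")
  setdiff(names(conc), "sample_id")
}
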