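#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test as used inside the bootstrap selection loop. The exact
#' null distribution is used when both samples have at most 8 observations
#' and the data contain no ties; otherwise the normal approximation with
#' midranks, tie-corrected variance and continuity correction applies.
#' Missing values are dropped. U is reported for `x`.
#'
#' @param x,y Numeric vectors of concentrations (each with at least one
#'   observed value).
#' @return A named list with elements `U` and `p`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney <- function(x, y) {
  if (length(x[!is.na(x)]) < 1 || length(y[!is.na(y)]) < 1) {
    abort("both samples need at least one observed value")
  }
  out <- mw_test_cpp(as.numeric(x), as.numeric(y))
  list(U = unname(out[["U"]]), p = unname(out[["p"]]))
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha_family Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (metabolites after filtering).
#' @return `alpha_family / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 153)  # ~0.000327, i.e. 0.0003 to 1 s.f.
bonferroni_threshold <- function(alpha_family, n_tests) {
  if (length(alpha_family) != 1 || alpha_family <= 0 || alpha_family >= 1) {
    abort("`alpha_family` must be in (0, 1)")
  }
  if (length(n_tests) != 1 || n_tests < 1) {
    abort("`n_tests` must be a positive count")
  }
  alpha_family / n_tests
}

#' Configuration of the bootstrap Mann-Whitney selection
#'
#' @param n_boot Number of bootstrap iterations (10,000 in the full-scale
#'   procedure; reduce for quick runs).
#' @param resample_size Draws per group and iteration; `NULL` (default)
#'   means "equal to the smallest of the two groups", the balanced
#'   resampling rule.
#' @param alpha_family Family-wise error rate (0.05).
#' @param n_tests Number of tests for the Bonferroni correction; `NULL`
#'   (default) means the number of metabolites in the matrix at hand.
#' @param replace Resample with replacement (`TRUE`, the bootstrap) or
#'   without (subsampling).
#' @param seed Integer seed for the resampling stream.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 10000, resample_size = NULL,
                             alpha_family = 0.05, n_tests = NULL,
                             replace = TRUE, seed = 1L) {
  if (n_boot < 1) abort("`n_boot` must be >= 1")
  if (!is.null(resample_size) && resample_size < 2) {
    abort("`resample_size` must be >= 2")
  }
  structure(list(n_boot = as.integer(n_boot), resample_size = resample_size,
                 alpha_family = alpha_family, n_tests = n_tests,
                 replace = isTRUE(replace), seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap-resampled Mann-Whitney marker selection
#'
#' The first selection step of the workflow: for each of `n_boot`
#' iterations, draw `resample_size` samples with replacement independently
#' from the case and the control group, run a two-sided Mann-Whitney test
#' per metabolite on the resampled concentrations, and record the U
#' statistic and p-value. A metabolite is flagged significant when the
#' median p-value over iterations falls below the Bonferroni threshold
#' `alpha_family / n_tests`. Direction calls (increased/decreased) come
#' from the fold change of raw concentrations relative to 1. Because the
#' test is rank-based, results are identical on raw and z-scored data.
#'
#' @inheritParams fold_change
#' @param config A [bootstrap_config()].
#' @return A tibble of class `nen_selection` with one row per metabolite:
#'   `metabolite`, `median_U`, `median_p`, `X`, `Y`, `fc`, `log2fc`,
#'   `direction`, `significant`; attributes `comparison` (case/control
#'   labels), `threshold`, `n_boot`, `resample_size`.
#' @export
bootstrap_select <- function(conc, samples, case, control,
                             config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  mets <- metabolite_cols(conc)
  case_ids <- samples$sample_id[samples$group %in% case]
  ctrl_ids <- samples$sample_id[samples$group %in% control]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    abort("both groups need at least 2 samples")
  }
  resample <- config$resample_size %||% min(length(case_ids), length(ctrl_ids))
  n_tests <- config$n_tests %||% length(mets)
  threshold <- bonferroni_threshold(config$alpha_family, n_tests)

  case_m <- as.matrix(conc[conc$sample_id %in% case_ids, mets])
  ctrl_m <- as.matrix(conc[conc$sample_id %in% ctrl_ids, mets])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  boot <- boot_mw_cpp(case_m, ctrl_m, config$n_boot, as.integer(resample),
                      config$replace, keep = FALSE)

  fc <- fold_change(conc, samples, case, control)
  out <- tibble(
    metabolite = mets,
    median_U = boot$median_U,
    median_p = boot$median_p
  ) %>%
    left_join(fc, by = "metabolite") %>%
    mutate(
      direction = ifelse(.data$fc > 1, "increased", "decreased"),
      significant = .data$median_p < threshold
    )
  structure(out,
            comparison = c(case = paste(case, collapse = "+"),
                           control = paste(control, collapse = "+")),
            threshold = threshold, n_boot = config$n_boot,
            resample_size = resample,
            class = c("nen_selection", class(out)))
}

#' Venn partition of significant marker sets
#'
#' Given the per-comparison sets of significant metabolites (as character
#' vectors or `nen_selection` tibbles), computes every region of the Venn
#' partition: which metabolites are exclusive to each comparison, shared
#' by each pair, by each triple, and so on.
#'
#' @param sets Named list of character vectors or `nen_selection` objects.
#' @return A tibble with one row per non-empty-by-construction region:
#'   `region` (labels joined by `&`), `degree` (number of sets in the
#'   region), `n` and `members` (list column).
#' @export
#' @examples
#' overlap_sets(list(A = c("a", "b"), B = c("b", "c"), C = "b"))
overlap_sets <- function(sets) {
  if (length(sets) < 2) abort("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be named")
  }
  sets <- lapply(sets, function(s) {
    if (inherits(s, "nen_selection")) s$metabolite[s$significant] else as.character(s)
  })
  k <- length(sets)
  labels <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- labels
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    in_region <- if (length(universe)) {
      apply(membership, 1, function(mm) all(mm == pat))
    } else {
      logical(0)
    }
    tibble(region = paste(labels[pat], collapse = " & "),
           degree = sum(pat), n = sum(in_region),
           members = list(sort(universe[in_region])))
  })
  bind_rows(rows) %>% arrange(desc(.data$degree), .data$region)
}
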