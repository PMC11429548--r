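# Shared small fixtures, built in code.

# A concentration tibble from a plain matrix.
conc_tibble <- function(values, metabolites = NULL) {
  values <- as.matrix(values)
  metabolites <- metabolites %||% sprintf("M%03d", seq_len(ncol(values)))
  colnames(values) <- metabolites
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%04d", seq_len(nrow(values)))),
    tibble::as_tibble(values)
  )
}

# Matching minimal sample table.
sample_tibble <- function(groups) {
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_along(groups)),
    group = groups,
    age = 60, sex = "female", smoking = "non", bmi = 27,
    stage = NA_character_
  )
}

`%||%` <- rlang::`%||%`

# One simulated study-preset cohort reused by several test files.
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_design(), seed = 424242)
    cache
  }
})

# Planted marker names for one subtype, |log2FC| >= 1 only.
planted_markers <- function(group) {
  eff <- study_effects()
  eff$metabolite[eff$group == group & abs(eff$log2fc) >= 1]
}
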