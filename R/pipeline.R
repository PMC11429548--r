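#' The six case/control contrasts of the default analysis
#'
#' Each NEN subtype and the pooled NEN group against healthy controls,
#' plus the two neuroendocrine carcinomas against the NSCLC outgroup.
#' Models and enrichment are run for the versus-healthy contrasts.
#'
#' @return A list of comparison descriptors (`label`, `case`, `control`,
#'   `model`).
#' @export
default_comparisons <- function() {
  nen <- c("carcinoid", "SCLC", "LCNEC")
  list(
    list(label = "NEN_vs_healthy", case = nen, control = "healthy",
         model = TRUE),
    list(label = "carcinoid_vs_healthy", case = "carcinoid",
         control = "healthy", model = TRUE),
    list(label = "SCLC_vs_healthy", case = "SCLC", control = "healthy",
         model = TRUE),
    list(label = "LCNEC_vs_healthy", case = "LCNEC", control = "healthy",
         model = TRUE),
    list(label = "SCLC_vs_NSCLC", case = "SCLC", control = "NSCLC",
         model = FALSE),
    list(label = "LCNEC_vs_NSCLC", case = "LCNEC", control = "NSCLC",
         model = FALSE)
  )
}

#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates every stage on a (simulated or supplied) cohort:
#' missingness filtering, demographics, bootstrap Mann-Whitney selection
#' per comparison, Venn overlaps across the three subtypes, backward-
#' eliminated regularized classifiers for the versus-healthy contrasts,
#' non-lipid metabolite-set enrichment, and the clustered marker heatmap.
#' All tabular outputs are written as TSV, models and the run manifest as
#' JSON. A given (configuration, seed) pair reproduces every output byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [cohort_design()]; ignored when `cohort` is supplied.
#' @param cohort Optional list with `concentrations` and `samples`
#'   tibbles; by default a cohort is simulated from `design`.
#' @param seed Root integer seed; stage seeds are fixed offsets from it.
#' @param n_boot,n_perm Bootstrap iterations and enrichment permutations.
#' @param folds,repeats Cross-validation design.
#' @param comparisons List of comparison descriptors, see
#'   [default_comparisons()].
#' @param gmt Path to the pathway library; defaults to the packaged
#'   synthetic 99-set SMPDB-style GMT.
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(out_dir, design = cohort_design(), cohort = NULL,
                         seed = 1L, n_boot = 10000, n_perm = 9999,
                         folds = 5, repeats = 10,
                         comparisons = default_comparisons(),
                         gmt = default_gmt()) {
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  incomplete <- file.path(out_dir, "INCOMPLETE")
  file.create(incomplete)
  stage <- "validate"
  on_fail <- function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  }
  manifest <- tryCatch({
    cohort <- cohort %||% simulate_cohort(design, seed = seed)
    groups <- unique(cohort$samples$group)
    for (cmp in comparisons) {
      missing <- setdiff(c(cmp$case, cmp$control), groups)
      if (length(missing) > 0) {
        abort(paste0("comparison '", cmp$label, "' names group(s) absent ",
                     "from the sample table: ",
                     paste(missing, collapse = ", ")))
      }
    }
    library <- read_gmt(gmt)
    outputs <- character()
    # manifest records paths relative to out_dir so that identical runs
    # into different directories stay byte-identical
    emit <- function(tab, name) {
      path <- file.path(out_dir, name)
      readr::write_tsv(tab, path, na = "NA")
      outputs[[name]] <<- name
      path
    }

    stage <- "preprocess"
    conc <- filter_missingness(cohort$concentrations)
    samples <- cohort$samples
    nen <- c("carcinoid", "SCLC", "LCNEC")
    demo <- bind_rows(
      mutate(compare_demographics(
        samples[samples$group %in% nen, ],
        samples[samples$group == "healthy", ]), contrast = "NEN_vs_healthy"),
      mutate(compare_demographics(
        samples[samples$group %in% nen, ],
        samples[samples$group == "NSCLC", ]), contrast = "NEN_vs_NSCLC")
    )
    emit(demo, "demographics.tsv")

    stage <- "selection"
    selections <- list()
    for (i in seq_along(comparisons)) {
      cmp <- comparisons[[i]]
      sel <- bootstrap_select(
        conc, samples, cmp$case, cmp$control,
        config = bootstrap_config(n_boot = n_boot, seed = seed + 100L + i))
      selections[[cmp$label]] <- sel
      emit(as_tibble(sel), paste0("selection_", cmp$label, ".tsv"))
      emit(export_volcano(sel), paste0("volcano_", cmp$label, ".tsv"))
    }

    stage <- "overlap"
    subtype_labels <- paste0(nen, "_vs_healthy")
    venn <- NULL
    if (all(subtype_labels %in% names(selections))) {
      venn <- overlap_sets(setNames(selections[subtype_labels], nen))
      venn_flat <- venn %>%
        mutate(members = vapply(.data$members, paste, "", collapse = ", ")) %>%
        as_tibble()
      emit(venn_flat, "venn_subtypes.tsv")
    }

    stage <- "classify"
    fits <- list()
    for (i in seq_along(comparisons)) {
      cmp <- comparisons[[i]]
      if (!isTRUE(cmp$model)) next
      sel <- selections[[cmp$label]]
      sig <- sel$metabolite[sel$significant]
      if (length(sig) == 0) {
        inform(paste0("no significant metabolites for ", cmp$label,
                      "; skipping model"))
        next
      }
      fit <- fit_group_classifier(
        conc, samples, cmp$case, cmp$control, sig,
        config = model_config(folds = folds, repeats = repeats,
                              seed = seed + 200L + i))
      fits[[cmp$label]] <- fit
      model_json <- list(
        comparison = unclass(fit$labels),
        family = fit$family, alpha = fit$alpha, lambda = fit$lambda,
        coefficients = as.list(fit$coefficients),
        retained = fit$retained,
        cv = list(accuracy_mean = fit$cv_accuracy_mean,
                  accuracy_sd = fit$cv_accuracy_sd,
                  ci = as.list(fit$cv_accuracy_ci),
                  sensitivity = fit$cv_sensitivity,
                  specificity = fit$cv_specificity),
        confusion = as.list(fit$confusion),
        resubstitution = as.list(fit$resubstitution)
      )
      path <- file.path(out_dir, paste0("model_", cmp$label, ".json"))
      jsonlite::write_json(model_json, path, auto_unbox = TRUE, digits = NA)
      outputs[[basename(path)]] <- basename(path)
      emit(fit$cv, paste0("cv_", cmp$label, ".tsv"))
    }

    stage <- "enrich"
    enrichments <- list()
    for (i in seq_along(comparisons)) {
      cmp <- comparisons[[i]]
      if (!isTRUE(cmp$model)) next
      sel <- selections[[cmp$label]]
      if (!any(sel$significant)) next
      enr <- msea(sel, conc, samples, cmp$case, cmp$control, library,
                  panel = design$panel, n_perm = n_perm,
                  seed = seed + 300L + i)
      enrichments[[cmp$label]] <- enr
      enr_flat <- enr %>%
        mutate(members_hit = vapply(.data$members_hit, paste, "",
                                    collapse = ", ")) %>%
        as_tibble()
      emit(enr_flat, paste0("enrichment_", cmp$label, ".tsv"))
    }

    stage <- "heatmap"
    hm_orders <- NULL
    if (!is.null(venn)) {
      markers <- sort(unique(unlist(venn$members)))
      if (length(markers) >= 2) {
        ids <- samples$sample_id[samples$group %in% c("healthy", nen)]
        sub <- conc[conc$sample_id %in% ids, c("sample_id", markers)]
        sub <- zscore_metabolites(impute_missing(sub))
        hm <- cluster_heatmap(sub, samples)
        hm_orders <- tibble(
          kind = c(rep("metabolite", length(hm$metabolite_order)),
                   rep("sample", length(hm$sample_order))),
          position = c(seq_along(hm$metabolite_order),
                       seq_along(hm$sample_order)),
          id = c(hm$metabolite_order, hm$sample_order))
        emit(hm_orders, "heatmap_orders.tsv")
      }
    }

    stage <- "manifest"
    config <- list(seed = seed, n_boot = n_boot, n_perm = n_perm,
                   folds = folds, repeats = repeats,
                   comparisons = comparisons, design = unclass(design))
    manifest <- list(
      package = "nenplasma",
      version = as.character(utils::packageVersion("nenplasma")),
      seed = seed,
      config_hash = rlang::hash(config),
      n_samples = nrow(samples),
      n_metabolites_assayed = ncol(cohort$concentrations) - 1L,
      n_metabolites_retained = ncol(conc) - 1L,
      n_significant = lapply(selections, function(s) sum(s$significant)),
      models = lapply(fits, function(f) list(
        family = f$family, alpha = f$alpha, lambda = f$lambda,
        n_retained = length(f$retained),
        cv_accuracy = f$cv_accuracy_mean)),
      n_enriched_significant = lapply(enrichments,
                                      function(e) sum(e$significant)),
      outputs = as.list(outputs)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = on_fail)
  unlink(incomplete)
  invisible(manifest)
}

#' Path of the packaged synthetic SMPDB-style pathway library
#'
#' A 99-set GMT library in the style (size, naming, set composition) of a
#' small-molecule pathway database. It is a synthetic stand-in
#' constructed for this package, not a copy of SMPDB; supply your own
#' GMT export for real analyses.
#'
#' @return File path.
#' @export
default_gmt <- function() {
  system.file("extdata", "smpdb_like_99_synthetic.gmt",
              package = "nenplasma", mustWork = TRUE)
}
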