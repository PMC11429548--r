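#' The targeted metabolite panel used by the synthetic cohort generator
#'
#' Returns the registry of the 166 metabolites quantified by a targeted
#' LC-MS/MS plasma assay of the kind used in neuroendocrine-neoplasm
#' biomarker studies: amino acids, biogenic amines, organic acids and sugars
#' (non-lipids), plus acylcarnitines, lysophosphatidylcholines,
#' diacyl/acyl-alkyl phosphatidylcholines and sphingomyelins (lipids).
#' Baseline abundances are log-normal on the concentration (uM) scale;
#' `log_mean`/`log_sd` parameterize the natural-log concentration of a
#' healthy-control sample. Thirteen low-abundance analytes carry a missing
#' probability above 0.5 so that the standard "drop metabolites missing in
#' more than half the samples" filter reduces the panel from 166 to 153.
#'
#' @return A tibble with one row per metabolite and columns `metabolite`,
#'   `class` (`"lipid"` or `"non_lipid"`), `subclass`, `log_mean`, `log_sd`
#'   (natural-log uM), `missing_prob` and `missing_mechanism` (`"mcar"` or
#'   `"lod"`, i.e. left-censoring below a limit of detection).
#' @export
#' @examples
#' panel <- metabolite_panel()
#' nrow(panel)              # 166
#' sum(panel$missing_prob > 0.5)  # 13
metabolite_panel <- function() {
  amino <- c(
    "Alanine", "Arginine", "Asparagine", "Aspartic acid", "Citrulline",
    "Glutamic acid", "Glutamine", "Glycine", "Histidine", "Isoleucine",
    "Leucine", "Lysine", "Methionine", "Ornithine", "Phenylalanine",
    "Proline", "Serine", "Threonine", "Tryptophan", "Tyrosine", "Valine"
  )
  amine <- c(
    "ADMA", "SDMA", "alpha-Aminoadipic acid", "Creatinine", "Histamine",
    "Kynurenine", "N-acetylputrescine", "Putrescine", "Sarcosine",
    "Serotonin", "Spermidine", "Spermine", "Taurine",
    "trans-4-Hydroxyproline"
  )
  organic <- c(
    "alpha-Ketoglutaric acid", "beta-Hydroxybutyric acid", "Citric acid",
    "Fumaric acid", "Glucose", "Hippuric acid",
    "5-Hydroxy-indoleacetic acid", "Indolepropionic acid",
    "Indoleacetic acid", "Isobutyric acid", "Lactic acid", "Malic acid",
    "Methylmalonic acid", "Propionic acid", "Pyruvic acid", "Succinic acid",
    "Uric acid", "Butyric acid", "p-Hydroxyhippuric acid",
    "Homovanillic acid"
  )
  acylcarnitine <- c(
    "C0", "C2", "C3", "C4", "C5", "C5:1", "C5DC", "C5-OH", "C6", "C7DC",
    "C8", "C9", "C10", "C10:1", "C10:2", "C12", "C12:1", "C14", "C14:1",
    "C14:2", "C16", "C16:1", "C18", "C18:1"
  )
  lysopc <- paste("lysoPC a", c(
    "C14:0", "C16:0", "C16:1", "C17:0", "C18:0", "C18:1", "C18:2", "C20:3",
    "C20:4", "C24:0", "C26:0", "C26:1", "C28:0", "C28:1"
  ))
  pc_aa <- paste("PC aa", c(
    "C24:0", "C26:0", "C28:1", "C30:0", "C32:0", "C32:1", "C32:2", "C34:1",
    "C34:2", "C34:3", "C34:4", "C36:0", "C36:1", "C36:2", "C36:3", "C36:4",
    "C36:5", "C36:6", "C38:0", "C38:3", "C38:4", "C38:5", "C38:6", "C40:2",
    "C40:3", "C40:4", "C40:5", "C40:6", "C42:0", "C42:1"
  ))
  pc_ae <- paste("PC ae", c(
    "C30:0", "C30:2", "C32:1", "C32:2", "C34:0", "C34:1", "C34:2", "C34:3",
    "C36:0", "C36:1", "C36:2", "C36:3", "C36:4", "C36:5", "C38:0", "C38:1",
    "C38:2", "C38:3", "C38:4", "C38:5", "C38:6", "C40:1", "C40:2", "C40:3",
    "C40:4", "C40:5", "C40:6", "C42:1"
  ))
  sm <- paste("SM", c(
    "C16:0", "C16:1", "C18:0", "C18:1", "C20:2", "C22:3", "C24:0", "C24:1",
    "C26:0", "C26:1", "(OH) C14:1", "(OH) C16:1", "(OH) C22:1",
    "(OH) C22:2", "(OH) C24:1"
  ))

  subclass <- c(
    rep("amino acid", length(amino)),
    rep("biogenic amine", length(amine)),
    rep("organic acid/sugar", length(organic)),
    rep("acylcarnitine", length(acylcarnitine)),
    rep("lysoPC", length(lysopc)),
    rep("PC aa", length(pc_aa)),
    rep("PC ae", length(pc_ae)),
    rep("sphingomyelin", length(sm))
  )
  name <- c(amino, amine, organic, acylcarnitine, lysopc, pc_aa, pc_ae, sm)
  cls <- ifelse(
    subclass %in% c("amino acid", "biogenic amine", "organic acid/sugar"),
    "non_lipid", "lipid"
  )

  # class-typical plasma abundances (log uM); a fixed within-class ramp
  # spreads metabolites over a realistic dynamic range
  base <- c(
    "amino acid" = log(150), "biogenic amine" = log(1.5),
    "organic acid/sugar" = log(15), "acylcarnitine" = log(0.3),
    "lysoPC" = log(8), "PC aa" = log(10), "PC ae" = log(2),
    "sphingomyelin" = log(20)
  )[subclass]
  idx <- stats::ave(seq_along(name), subclass, FUN = seq_along)
  log_mean <- unname(base) + 0.25 * ((idx %% 7) - 3)
  log_mean[name == "Glucose"] <- log(5000)
  log_mean[name == "C0"] <- log(35)
  log_mean[name == "lysoPC a C16:0"] <- log(100)

  high_missing <- c(
    "Histamine", "Propionic acid", "Butyric acid", "C5:1", "C14:2",
    "lysoPC a C26:0", "lysoPC a C28:1", "PC aa C42:0", "PC aa C42:1",
    "PC ae C40:1", "PC ae C42:1", "SM C26:0", "SM (OH) C22:2"
  )
  stopifnot(all(high_missing %in% name), length(high_missing) == 13L)
  missing_prob <- ifelse(name %in% high_missing, 0.7, 0.05)
  mechanism <- ifelse(name %in% high_missing, "lod", "mcar")

  tibble(
    metabolite = name, class = cls, subclass = subclass,
    log_mean = log_mean, log_sd = 0.35,
    missing_prob = missing_prob, missing_mechanism = mechanism
  )
}

#' Planted group effects of the default cohort design
#'
#' One row per (metabolite, tumor group) pair with a non-zero planted
#' log2 fold change relative to healthy controls. The marker set and its
#' directions reflect the reported plasma alterations in pulmonary
#' neuroendocrine neoplasms: fumaric acid and lysoPC a C16:0 altered in all
#' three subtypes, glucose raised only in carcinoids, N-acetylputrescine
#' only in SCLC, spermine only in LCNEC, and so on; NSCLC carries a partly
#' overlapping "generic lung cancer" signature so that NEC-versus-NSCLC
#' contrasts are sparse.
#'
#' @return A tibble with columns `metabolite`, `group`, `log2fc`.
#' @export
study_effects <- function() {
  eff <- function(metabolite, groups, log2fc) {
    tibble(metabolite = metabolite, group = groups, log2fc = log2fc)
  }
  all3 <- c("carcinoid", "SCLC", "LCNEC")
  bind_rows(
    # altered in all three NEN subtypes
    eff("Fumaric acid", all3, -1.2),
    eff("lysoPC a C16:0", all3, -1.0),
    # shared carcinoid + SCLC
    eff("Uric acid", c("carcinoid", "SCLC"), -1.0),
    eff("beta-Hydroxybutyric acid", c("carcinoid", "SCLC"), 1.2),
    # shared carcinoid + LCNEC
    eff("lysoPC a C18:0", c("carcinoid", "LCNEC"), -1.0),
    eff("lysoPC a C18:2", c("carcinoid", "LCNEC"), -1.1),
    eff("PC aa C40:2", c("carcinoid", "LCNEC"), -1.0),
    eff("5-Hydroxy-indoleacetic acid", c("carcinoid", "LCNEC"), 1.0),
    # carcinoid only
    eff("Glucose", "carcinoid", 1.0),
    eff("Citric acid", "carcinoid", -1.0),
    eff("Phenylalanine", "carcinoid", 1.0),
    eff("ADMA", "carcinoid", 1.0),
    eff("Serotonin", "carcinoid", 1.3),
    eff("C9", "carcinoid", -1.0),
    eff("C10", "carcinoid", -1.1),
    eff("C10:1", "carcinoid", -1.0),
    eff("C10:2", "carcinoid", -1.2),
    eff("C18:1", "carcinoid", -1.0),
    # SCLC only
    eff("N-acetylputrescine", "SCLC", 1.2),
    # LCNEC only
    eff("Spermine", "LCNEC", 1.2),
    eff("Indolepropionic acid", "LCNEC", -1.2),
    eff("C5DC", "LCNEC", 1.0),
    eff("alpha-Ketoglutaric acid", "LCNEC", -1.0),
    # NSCLC outgroup: overlapping generic signature
    eff("Fumaric acid", "NSCLC", -1.2),
    eff("lysoPC a C16:0", "NSCLC", -1.0),
    eff("lysoPC a C18:0", "NSCLC", -1.0),
    eff("lysoPC a C18:2", "NSCLC", -1.1)
  )
}

#' Per-group covariate distributions of the default cohort design
#'
#' Age and BMI are normal with the published per-group means and SDs; sex
#' and smoking status are categorical with the published frequencies
#' (subtypes share the pooled NEN case frequencies). Pathological stage
#' probabilities are invented for annotation realism only and do not
#' influence concentrations.
#'
#' @return A tibble with one row per group.
#' @export
study_covariates <- function() {
  tibble(
    group = c("healthy", "carcinoid", "SCLC", "LCNEC", "NSCLC"),
    age_mean = c(56.7, 59.3, 63.3, 64.1, 65.2),
    age_sd = c(10.7, 11.2, 8.1, 8.9, 8.1),
    bmi_mean = c(26.7, 27.8, 27.8, 27.8, 27.1),
    bmi_sd = c(6.0, 4.7, 4.7, 4.7, 5.1),
    p_female = c(0.549, 0.633, 0.633, 0.633, 0.499),
    p_current = c(0.084, 0.233, 0.233, 0.233, 0.228),
    p_ex = c(0.352, 0.583, 0.583, 0.583, 0.722),
    p_non = c(0.563, 0.183, 0.183, 0.183, 0.046),
    p_passive = c(0.001, 0.001, 0.001, 0.001, 0.004),
    p_stage = list(
      NULL,
      c(I = 0.60, II = 0.25, III = 0.10, IV = 0.05),
      c(I = 0.15, II = 0.20, III = 0.40, IV = 0.25),
      c(I = 0.30, II = 0.30, III = 0.30, IV = 0.10),
      c(I = 0.45, II = 0.25, III = 0.25, IV = 0.05)
    )
  )
}

#' Construct a synthetic cohort design
#'
#' A cohort design bundles everything the simulator needs: group sizes,
#' per-group covariate distributions, the metabolite panel with baseline
#' log-normal parameters and missingness model, and the table of planted
#' per-group concentration effects (log2 fold changes relative to healthy).
#'
#' The `"study"` preset emulates the published study design: five groups of
#' 71 healthy controls, 50 carcinoids, 40 SCLC, 30 LCNEC and 466 NSCLC; a
#' 166-metabolite panel of which 13 exceed 50% missingness (so the standard
#' filter retains 153); and planted subtype marker effects
#' (see [study_effects()]). The `"null"` preset keeps the published group
#' sizes but uses a featureless 153-metabolite panel with no planted
#' effects and no missingness — the global-null configuration used for
#' type-I-error calibration.
#'
#' @param preset `"study"` (default) or `"null"`.
#' @param group_sizes Named integer vector overriding the preset sizes.
#' @param covariates,panel,effects Tibbles overriding the preset components
#'   (see [study_covariates()], [metabolite_panel()], [study_effects()]).
#' @param confounded If `TRUE`, current smoking additionally raises a small
#'   set of amine concentrations (a deliberate confound for robustness
#'   checks); default `FALSE`, in which case covariates never influence
#'   concentrations.
#' @return An object of class `cohort_design`.
#' @export
#' @examples
#' d <- cohort_design()
#' sum(d$group_sizes[c("carcinoid", "SCLC", "LCNEC")])  # 120 cases
cohort_design <- function(preset = c("study", "null"), group_sizes = NULL,
                          covariates = NULL, panel = NULL, effects = NULL,
                          confounded = FALSE) {
  preset <- match.arg(preset)
  if (preset == "study") {
    sizes <- c(healthy = 71L, carcinoid = 50L, SCLC = 40L, LCNEC = 30L,
               NSCLC = 466L)
    pan <- metabolite_panel()
    eff <- study_effects()
  } else {
    sizes <- c(healthy = 71L, carcinoid = 50L, SCLC = 40L, LCNEC = 30L,
               NSCLC = 466L)
    pan <- tibble(
      metabolite = sprintf("M%03d", seq_len(153)),
      class = "non_lipid", subclass = "synthetic",
      log_mean = 1, log_sd = 0.35,
      missing_prob = 0, missing_mechanism = "mcar"
    )
    eff <- tibble(metabolite = character(), group = character(),
                  log2fc = numeric())
  }
  design <- structure(
    list(
      group_sizes = group_sizes %||% sizes,
      covariates = covariates %||% study_covariates(),
      panel = panel %||% pan,
      effects = effects %||% eff,
      confounded = isTRUE(confounded)
    ),
    class = "cohort_design"
  )
  validate_cohort_design(design)
  design
}

#' The published-study preset design
#'
#' Convenience wrapper equivalent to `cohort_design("study")`.
#' @return A `cohort_design` object.
#' @export
default_study_design <- function() cohort_design("study")

#' Validate a cohort design
#'
#' Checks the structural invariants of a [cohort_design()]: all group sizes
#' at least 2, positive log-SDs, missing probabilities in \[0, 1\], and
#' referential integrity of the effects table (every metabolite in the
#' panel, every group among the design's groups). Errors name the
#' offending field.
#'
#' @param design A `cohort_design`.
#' @return `design`, invisibly.
#' @export
validate_cohort_design <- function(design) {
  if (!inherits(design, "cohort_design")) {
    abort("`design` must be a cohort_design object")
  }
  gs <- design$group_sizes
  if (is.null(names(gs)) || any(!nzchar(names(gs)))) {
    abort("invalid design field `group_sizes`: must be a named vector")
  }
  if (any(gs < 2)) {
    abort(paste0("invalid design field `group_sizes`: all sizes must be >= 2 (",
                 paste(names(gs)[gs < 2], collapse = ", "), ")"))
  }
  pan <- design$panel
  req <- c("metabolite", "class", "log_mean", "log_sd", "missing_prob",
           "missing_mechanism")
  if (!all(req %in% names(pan))) {
    abort(paste0("invalid design field `panel`: missing columns ",
                 paste(setdiff(req, names(pan)), collapse = ", ")))
  }
  if (anyDuplicated(pan$metabolite)) {
    abort("invalid design field `panel`: duplicated metabolite names")
  }
  if (any(pan$log_sd <= 0)) {
    abort("invalid design field `panel`: all log_sd must be > 0")
  }
  if (any(pan$missing_prob < 0 | pan$missing_prob > 1)) {
    abort("invalid design field `panel`: missing_prob must be in [0, 1]")
  }
  if (!all(pan$missing_mechanism %in% c("mcar", "lod"))) {
    abort("invalid design field `panel`: missing_mechanism must be 'mcar' or 'lod'")
  }
  eff <- design$effects
  if (!all(eff$metabolite %in% pan$metabolite)) {
    abort(paste0("invalid design field `effects`: unknown metabolites ",
                 paste(unique(setdiff(eff$metabolite, pan$metabolite)),
                       collapse = ", ")))
  }
  if (!all(eff$group %in% names(gs))) {
    abort(paste0("invalid design field `effects`: unknown groups ",
                 paste(unique(setdiff(eff$group, names(gs))), collapse = ", ")))
  }
  cov <- design$covariates
  if (!all(names(gs) %in% cov$group)) {
    abort(paste0("invalid design field `covariates`: no covariate row for ",
                 paste(setdiff(names(gs), cov$group), collapse = ", ")))
  }
  invisible(design)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat("  groups: ",
      paste0(names(x$group_sizes), "=", x$group_sizes, collapse = ", "), "\n")
  cat("  panel: ", nrow(x$panel), " metabolites (",
      sum(x$panel$class == "lipid"), " lipid)\n", sep = "")
  cat("  planted effects: ", nrow(x$effects), " (metabolite, group) pairs\n",
      sep = "")
  invisible(x)
}

#' Minimal two-group design for calibration and power studies
#'
#' Builds a case/control [cohort_design()] with a featureless synthetic
#' panel — handy for null-calibration and power experiments around the
#' bootstrap selection, and used extensively in the package's own tests.
#'
#' @param n_case,n_control Group sizes.
#' @param n_metabolites Panel size; metabolites are named `M001`, `M002`,
#'   ...
#' @param log2fc Planted case-vs-control log2 fold change; scalar
#'   (recycled) or one value per metabolite.
#' @param log_sd Within-group SD of natural-log concentrations.
#' @param missing_prob Per-metabolite missing probability (scalar or
#'   vector).
#' @param mechanism `"mcar"` or `"lod"` (scalar or vector).
#' @return A `cohort_design` with groups `"case"` and `"control"`.
#' @export
two_group_design <- function(n_case = 30, n_control = 71,
                             n_metabolites = 100, log2fc = 0,
                             log_sd = 0.35, missing_prob = 0,
                             mechanism = "mcar") {
  m <- n_metabolites
  panel <- tibble(
    metabolite = sprintf("M%03d", seq_len(m)),
    class = "non_lipid", subclass = "synthetic",
    log_mean = 1, log_sd = rep_len(log_sd, m),
    missing_prob = rep_len(missing_prob, m),
    missing_mechanism = rep_len(mechanism, m)
  )
  l2 <- rep_len(log2fc, m)
  effects <- tibble(metabolite = panel$metabolite[l2 != 0],
                    group = "case", log2fc = l2[l2 != 0])
  covariates <- tibble(
    group = c("case", "control"),
    age_mean = 60, age_sd = 10, bmi_mean = 27, bmi_sd = 5,
    p_female = 0.5, p_current = 0.25, p_ex = 0.25, p_non = 0.25,
    p_passive = 0.25, p_stage = list(NULL, NULL)
  )
  cohort_design(group_sizes = c(case = n_case, control = n_control),
                covariates = covariates, panel = panel, effects = effects)
}
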