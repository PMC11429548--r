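#' Read a pathway library in GMT format
#'
#' GMT is the tab-separated set-library format: one set per line, fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member
#' names within a set are deduplicated; a duplicated set name or a line
#' with fewer than three fields is an error naming the line.
#'
#' @param path Path to a `.gmt` file. The package ships a synthetic
#'   99-set SMPDB-style library: `system.file("extdata",
#'   "smpdb_like_99_synthetic.gmt", package = "nenplasma")`.
#' @return A tibble of class `nen_pathways`: `pathway`, `description`,
#'   `members` (list column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty pathway library")
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      abort(paste0("malformed GMT line ", i,
                   ": need name, description and >= 1 member"))
    }
    tibble(pathway = fields[1], description = fields[2],
           members = list(unique(fields[-(1:2)])))
  })
  out <- bind_rows(rows)
  dup <- unique(out$pathway[duplicated(out$pathway)])
  if (length(dup) > 0) {
    abort(paste0("duplicate pathway name(s): ", paste(dup, collapse = ", ")))
  }
  structure(out, class = c("nen_pathways", class(out)))
}

#' Canonicalize metabolite names for pathway matching
#'
#' Case-folds and strips punctuation and whitespace so that e.g.
#' `"Fumaric acid"`, `"fumaric-acid"` and `"FUMARIC ACID"` all match.
#'
#' @param x Character vector of names.
#' @return Canonical forms.
#' @export
canonical_name <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Global-test Q statistic for one metabolite set
#'
#' The set-level association statistic of the generalized-linear-model
#' global test: with an intercept-only binomial null (fitted mean
#' `mu = mean(y)`), residuals `r = y - mu`, and the z-scored data matrix
#' `X` of the set's `m` matched metabolites,
#' `Q = r' X X' r / (m * mu * (1 - mu))`.
#' Q is nonnegative, invariant to swapping the class labels, and
#' unchanged when every column of the set is duplicated.
#'
#' @param X_set Numeric matrix (samples x matched metabolites), z-scored.
#' @param y Binary 0/1 outcome (case = 1).
#' @return The scalar Q statistic.
#' @export
#' @examples
#' globaltest_q(matrix(c(-1, -1, 1, 1)), c(0, 0, 1, 1))  # 16
globaltest_q <- function(X_set, y) {
  X_set <- as.matrix(X_set)
  y <- as.numeric(y)
  if (nrow(X_set) != length(y)) abort("X_set and y sizes differ")
  mu <- mean(y)
  if (mu <= 0 || mu >= 1) abort("`y` is constant: null variance is zero")
  r <- y - mu
  m <- ncol(X_set)
  if (m < 1) abort("need at least one matched metabolite")
  sum(as.numeric(crossprod(X_set, r))^2) / (m * mu * (1 - mu))
}

#' Permutation p-value for a global-test Q statistic
#'
#' Recomputes Q under `n_perm` random permutations of the class labels and
#' returns the add-one-corrected upper-tail p-value
#' `(1 + #\{Q_perm >= Q_obs\}) / (1 + n_perm)`, which is never exactly 0.
#'
#' @inheritParams globaltest_q
#' @param n_perm Number of label permutations (9999 at full scale).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
permutation_p <- function(X_set, y, n_perm = 9999, seed = 1L) {
  X_set <- as.matrix(X_set)
  y <- as.numeric(y)
  if (n_perm < 99) {
    warn("fewer than 99 permutations: p-value resolution is very coarse")
  }
  q_obs <- globaltest_q(X_set, y)
  mu <- mean(y)
  denom <- ncol(X_set) * mu * (1 - mu)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  # residuals of permuted y = permutation of residuals; vectorize as
  # colSums over the permuted residual matrix
  R <- vapply(seq_len(n_perm), function(i) sample(y) - mu, numeric(length(y)))
  q_perm <- colSums(crossprod(X_set, R)^2) / denom
  (1 + sum(q_perm >= q_obs)) / (1 + n_perm)
}

#' Metabolite-set enrichment analysis (MSEA) with the global test
#'
#' Matches a query panel of selected metabolites against every set of a
#' pathway library and, for each set with at least one hit, computes the
#' global-test Q statistic and its permutation p-value on the z-scored
#' concentrations of the matched metabolites over the case and control
#' samples. Lipid-class metabolites (acylcarnitines,
#' glycerophospholipids, lysoPCs, sphingomyelins) are excluded from the
#' query by default, restricting enrichment to the non-lipid markers.
#' Unmatched sets are reported with zero hits and no test.
#'
#' @param metabolites Character vector of selected metabolites (e.g.
#'   `significant_markers()` of a selection), or an `nen_selection`.
#' @inheritParams fold_change
#' @param library An `nen_pathways` library from [read_gmt()].
#' @param panel Panel metadata with `metabolite` and `class` columns used
#'   for the lipid exclusion; defaults to [metabolite_panel()].
#' @param lipid_exclusion Drop lipid-class metabolites first (default
#'   `TRUE`).
#' @param n_perm,seed Permutation settings, see [permutation_p()].
#' @return A tibble of class `nen_enrichment`: `pathway`, `set_size`,
#'   `hits`, `members_hit` (list), `Q`, `p`, `significant` (p < 0.05).
#' @export
msea <- function(metabolites, conc, samples, case, control, library,
                 panel = metabolite_panel(), lipid_exclusion = TRUE,
                 n_perm = 9999, seed = 1L) {
  if (inherits(metabolites, "nen_selection")) {
    metabolites <- metabolites$metabolite[metabolites$significant]
  }
  query <- unique(metabolites)
  if (lipid_exclusion) {
    lipids <- panel$metabolite[panel$class == "lipid"]
    query <- setdiff(query, lipids)
  }
  if (length(query) == 0) {
    warn("no non-lipid metabolites in the query; empty enrichment result")
    return(structure(
      tibble(pathway = character(), set_size = integer(), hits = integer(),
             members_hit = list(), Q = numeric(), p = numeric(),
             significant = logical()),
      class = c("nen_enrichment", class(tibble()))))
  }

  ids <- samples$sample_id[samples$group %in% c(case, control)]
  sub <- conc[conc$sample_id %in% ids, c("sample_id", intersect(query, names(conc)))]
  sub <- zscore_metabolites(impute_missing(sub))
  y <- as.integer(samples$group[match(sub$sample_id, samples$sample_id)]
                  %in% case)
  canon_query <- canonical_name(names(sub)[-1])

  rows <- lapply(seq_len(nrow(library)), function(i) {
    members <- library$members[[i]]
    hit <- names(sub)[-1][canon_query %in% canonical_name(members)]
    if (length(hit) == 0) {
      return(tibble(pathway = library$pathway[i],
                    set_size = length(members), hits = 0L,
                    members_hit = list(character()),
                    Q = NA_real_, p = NA_real_, significant = FALSE))
    }
    X_set <- as.matrix(sub[, hit, drop = FALSE])
    Q <- globaltest_q(X_set, y)
    p <- permutation_p(X_set, y, n_perm = n_perm, seed = seed + i)
    tibble(pathway = library$pathway[i], set_size = length(members),
           hits = length(hit), members_hit = list(hit),
           Q = Q, p = p, significant = p < 0.05)
  })
  out <- bind_rows(rows) %>% arrange(.data$p)
  structure(out, comparison = c(case = paste(case, collapse = "+"),
                                control = paste(control, collapse = "+")),
            class = c("nen_enrichment", class(out)))
}
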