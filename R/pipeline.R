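# End-to-end workflow drivers: simulate inputs, screen a library,
# validate candidates in the EHR extract, compare two validation
# summaries. Each driver is a plain function over a run-configuration
# list (usually loaded from YAML) so the whole pipeline is scriptable
# and deterministic under the configured seed.

#' Load a YAML run configuration
#'
#' Reads the scenario configuration, fills defaults and resolves
#' relative paths against the configuration file's directory.
#'
#' @param path Path to `config.yaml` (or a list already in config
#'   form, returned unchanged after default-filling).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(path) {
  if (is.character(path)) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    for (key in c("deg_table", "library", "ehr_dir", "approved_drugs",
                  "ingredient_map", "elixhauser_map", "out_dir")) {
      if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
        cfg[[key]] <- file.path(base, cfg[[key]])
    }
  } else cfg <- path
  defaults <- list(K = 50, q = 0.05, alpha_screen = 0.05,
                   alpha_validate = 0.05, min_cohort = 20,
                   induction_days = 30, max_window_days = 365,
                   end_impute_days = 90, min_age = 18, max_age = 90,
                   route_filter = FALSE, seed = 1L,
                   biomarker = "LDL-C", disease = "disease")
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  stopifnot(cfg$q > 0, cfg$q < 1, cfg$alpha_screen > 0,
            cfg$alpha_screen <= 1, cfg$K >= 1, cfg$min_cohort >= 1)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Generate a scenario bundle (simulate step)
#'
#' Thin wrapper over [gen_scenario()] writing a complete input bundle.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [gen_scenario()].
#' @return The run configuration for the bundle, invisibly.
#' @export
simulate_inputs <- function(dir, seed = 1L, ...) {
  gen_scenario(dir, seed = seed, ...)
}

#' Screen the perturbation library against both disease signatures
#'
#' Builds the top-K and FDR disease signatures from the configured DEG
#' table, screens the configured library with each, merges the two
#' candidate lists and applies the ingredient/prescription filter.
#' Writes `candidates.tsv` to the output directory.
#'
#' @param config A [run_config()] (or path to one).
#' @return The filtered `candidate_list` (invisibly `NULL` rows when no
#'   drug passes; the file is still written).
#' @export
screen_candidates <- function(config) {
  cfg <- run_config(config)
  degs <- read_deg_table(cfg$deg_table)
  restrict <- NULL
  if (!is.null(cfg$restrict_to))
    restrict <- readLines(cfg$restrict_to, warn = FALSE)
  sig_k <- select_topk(degs, k = cfg$K, disease = cfg$disease,
                       restrict_to = restrict)
  sig_q <- select_fdr(degs, q = cfg$q, disease = cfg$disease,
                      restrict_to = restrict)
  lib <- read_drug_library(cfg$library)
  scr_k <- screen_library(sig_k, lib, alpha = cfg$alpha_screen)
  scr_q <- screen_library(sig_q, lib, alpha = cfg$alpha_screen)
  cands <- combine_candidates(scr_k, scr_q, disease = cfg$disease)
  imap <- utils::read.table(cfg$ingredient_map, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  filtered <- filter_candidates(cands, imap)
  if (nrow(filtered) == 0L)
    warning("empty candidate list after screening and filtering")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(filtered, file.path(cfg$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  filtered
}

#' Full SCCS validation of one drug
#'
#' Runs the complete clinical-validation pipeline for a single drug:
#' observation windows, exclusion cascade, per-period medians, outlier
#' removal, model-table assembly and the mixed-model fit.
#'
#' @param ehr An [read_ehr()] list.
#' @param ingredient Tested drug.
#' @param concept Biomarker concept.
#' @param approved_drugs Ingredients approved for the disease.
#' @param code_map Elixhauser prefix map.
#' @param min_cohort Minimum testable cohort size (default 20).
#' @param induction_days,max_window_days,end_impute_days Window
#'   conventions (30 / 365 / 90).
#' @param min_age,max_age Age bounds at index (18, 90).
#' @param route_filter Restrict to systemic-route exposures.
#' @param approved_filter Apply the approved-drug exclusion (step 3).
#' @param elix_weights Optional Elixhauser category weights.
#' @return List of class `drug_validation`: `drug`, `effect`
#'   (`treatment_effect` or `NULL` when untestable), `attrition`,
#'   `n` (final cohort size), `untestable`, `model_table`,
#'   `outliers_dropped`.
#' @export
validate_drug <- function(ehr, ingredient, concept, approved_drugs,
                          code_map, min_cohort = 20, induction_days = 30,
                          max_window_days = 365, end_impute_days = 90,
                          min_age = 18, max_age = 90,
                          route_filter = FALSE, approved_filter = TRUE,
                          elix_weights = NULL) {
  windows <- build_windows(ehr, ingredient, induction_days,
                           max_window_days, end_impute_days)
  out <- list(drug = ingredient, effect = NULL, attrition = NULL,
              n = 0L, untestable = TRUE, model_table = NULL,
              outliers_dropped = character())
  class(out) <- "drug_validation"
  if (nrow(windows) == 0L) {
    out$attrition <- data.frame(step = "exposed", persons_remaining = 0L)
    return(out)
  }
  exc <- apply_exclusions(ehr, windows, approved_drugs, ingredient,
                          concept, min_age = min_age, max_age = max_age,
                          min_cohort = min_cohort,
                          route_filter = route_filter,
                          approved_filter = approved_filter,
                          end_impute_days = end_impute_days)
  out$attrition <- exc$attrition
  out$removed <- exc$removed
  if (exc$untestable) { out$n <- length(exc$retained); return(out) }
  med <- period_medians(ehr, windows, concept, exc$retained)
  ol <- remove_outliers(med)
  out$outliers_dropped <- ol$dropped
  out$attrition <- rbind(exc$attrition,
                         data.frame(step = "outlier_removal",
                                    persons_remaining = nrow(ol$kept)))
  out$n <- nrow(ol$kept)
  if (out$n < min_cohort) return(out)
  tab <- assemble_model_table(ehr, windows, ol$kept, code_map,
                              weights = elix_weights)
  out$model_table <- tab
  out$effect <- fit_sccs_lmm(tab, drug = ingredient)
  out$untestable <- FALSE
  out
}

#' Validate every candidate drug in the EHR extract (validate step)
#'
#' Runs [validate_drug()] for every candidate ingredient (plus any
#' `positive_controls` listed in the configuration), classifies the
#' testable effects against the Bonferroni threshold and writes
#' `summary.tsv`, `untestable.tsv`, one attrition file per drug and a
#' forest-plot export to the output directory.
#'
#' @param config A [run_config()] (or path).
#' @param candidates Optional `candidate_list` or data frame with an
#'   `ingredient` column; defaults to `candidates.tsv` in the output
#'   directory.
#' @return List of class `validation_run`: `summary`
#'   (a `screen_summary` or `NULL`), `results` (per-drug
#'   `drug_validation`s), `untestable` (data frame), `status`
#'   (`"ok"` or `"no testable drugs"`).
#' @export
validate_candidates <- function(config, candidates = NULL) {
  cfg <- run_config(config)
  set.seed(cfg$seed)
  if (is.null(candidates)) {
    cand_path <- file.path(cfg$out_dir, "candidates.tsv")
    stopifnot(file.exists(cand_path))
    candidates <- utils::read.table(cand_path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  drugs <- unique(c(candidates$ingredient, cfg$positive_controls))
  ehr <- read_ehr(cfg$ehr_dir)
  approved_tab <- utils::read.table(cfg$approved_drugs, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
  approved <- approved_tab$ingredient[approved_tab$disease == cfg$disease]
  code_map <- utils::read.table(cfg$elixhauser_map, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE,
                                colClasses = "character")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- lapply(drugs, function(d)
    validate_drug(ehr, d, cfg$biomarker, approved, code_map,
                  min_cohort = cfg$min_cohort,
                  induction_days = cfg$induction_days,
                  max_window_days = cfg$max_window_days,
                  end_impute_days = cfg$end_impute_days,
                  min_age = cfg$min_age, max_age = cfg$max_age,
                  route_filter = isTRUE(cfg$route_filter)))
  names(results) <- drugs
  for (res in results) {
    utils::write.table(res$attrition,
                       file.path(cfg$out_dir,
                                 paste0("attrition_", res$drug, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  testable <- results[!vapply(results, `[[`, logical(1), "untestable")]
  untestable <- do.call(rbind, lapply(
    results[vapply(results, `[[`, logical(1), "untestable")],
    function(r) data.frame(drug = r$drug, n = r$n,
                           stringsAsFactors = FALSE)))
  if (is.null(untestable))
    untestable <- data.frame(drug = character(), n = integer())
  utils::write.table(untestable, file.path(cfg$out_dir, "untestable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(testable) == 0L) {
    message("no testable drugs")
    return(structure(list(summary = NULL, results = results,
                          untestable = untestable,
                          status = "no testable drugs"),
                     class = "validation_run"))
  }
  summary <- classify_effects(lapply(testable, `[[`, "effect"),
                              n_tested = length(testable),
                              alpha = cfg$alpha_validate,
                              approved_for_disease = approved,
                              disease = cfg$disease,
                              biomarker = cfg$biomarker)
  utils::write.table(summary$effects, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  forest <- data.frame(drug = summary$effects$drug,
                       estimate = summary$effects$beta1,
                       ci_low = summary$effects$ci_low,
                       ci_high = summary$effects$ci_high,
                       source = cfg$disease, stringsAsFactors = FALSE)
  utils::write.table(forest, file.path(cfg$out_dir, "forest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(summary = summary, results = results,
                 untestable = untestable, status = "ok"),
            class = "validation_run")
}

#' Compare validation summaries from two databases (compare step)
#'
#' Per-drug replication flags across two validation runs: `replicated`
#' when the drug is therapeutic (negative estimate, `p < 0.05`) in
#' both sources, `ci_overlap` when the 95% CIs intersect and the point
#' estimates share a sign. Drugs present in only one summary are
#' listed as untested in the other.
#'
#' @param summary_a,summary_b `screen_summary` objects (or
#'   `validation_run`s, or paths to `summary.tsv` files).
#' @param labels Length-2 source labels for the forest export.
#' @return List: `report` (per-shared-drug flags), `only_a`, `only_b`
#'   (drug ids), `forest` (stacked forest-plot data).
#' @export
compare_summaries <- function(summary_a, summary_b,
                              labels = c("A", "B")) {
  get_df <- function(x) {
    if (is.character(x)) return(utils::read.table(x, header = TRUE,
                                                  sep = "\t",
                                                  stringsAsFactors = FALSE))
    if (inherits(x, "validation_run")) x <- x$summary
    if (inherits(x, "screen_summary")) return(x$effects)
    x
  }
  a <- get_df(summary_a); b <- get_df(summary_b)
  shared <- intersect(a$drug, b$drug)
  if (length(shared) == 0L) warning("no shared drugs between summaries")
  ia <- match(shared, a$drug); ib <- match(shared, b$drug)
  ther <- function(df, i) df$beta1[i] < 0 & df$p[i] < 0.05
  report <- data.frame(
    drug = shared,
    beta1_a = a$beta1[ia], beta1_b = b$beta1[ib],
    p_a = a$p[ia], p_b = b$p[ib],
    replicated = ther(a, ia) & ther(b, ib),
    ci_overlap = a$ci_low[ia] <= b$ci_high[ib] &
      b$ci_low[ib] <= a$ci_high[ia] &
      sign(a$beta1[ia]) == sign(b$beta1[ib]),
    stringsAsFactors = FALSE)
  forest <- rbind(
    data.frame(drug = a$drug, estimate = a$beta1, ci_low = a$ci_low,
               ci_high = a$ci_high, source = labels[1],
               stringsAsFactors = FALSE),
    data.frame(drug = b$drug, estimate = b$beta1, ci_low = b$ci_low,
               ci_high = b$ci_high, source = labels[2],
               stringsAsFactors = FALSE))
  list(report = report, only_a = setdiff(a$drug, b$drug),
       only_b = setdiff(b$drug, a$drug), forest = forest)
}
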