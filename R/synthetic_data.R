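# Synthetic inputs for every pipeline stage: imputed DEG tables,
# perturbation libraries with planted reversers, and longitudinal EHR
# extracts with known injected treatment effects. Everything is
# deterministic under the configured seed, and a truth manifest records
# what was planted so tests can compare pipeline output against ground
# truth exactly.

#' Simulation configuration
#'
#' Bundles every generator parameter with the shipped study-condition
#' defaults. Biomarker value model per measurement:
#' `value = concept mean + person intercept + covariate terms +
#' delta * (exposed, post-induction) + residual noise`.
#'
#' @param seed Integer seed (mandatory); every generator derives its
#'   random stream from it.
#' @param n_genes Genes in a DEG table (default 5000).
#' @param n_causal Causal genes with shifted |Z| (default 100).
#' @param causal_z_mean,causal_z_sd Magnitude distribution of causal
#'   Z-scores (default 6 and 1, giving near-complete FDR recovery).
#' @param n_reversers,n_decoys Planted reversers and null drugs in a
#'   perturbation library (defaults 5 and 500).
#' @param reverser_fidelity Target |correlation| of a planted reverser
#'   with the negated signature, in (0, 1] (default 0.9).
#' @param library_overlap Fraction of signature genes covered by each
#'   library drug (default 1).
#' @param n_extra_genes Library genes outside the signature
#'   (default 200).
#' @param n_persons Persons per drug cohort (default 300).
#' @param visits_per_year Poisson rate of extra outpatient biomarker
#'   measurements (default 6).
#' @param concept Biomarker concept, `"LDL-C"` (mg/dL) or `"SBP"`
#'   (mmHg).
#' @param baseline_mean Concept population mean (130 for both shipped
#'   concepts).
#' @param person_sd Between-person random-intercept SD (default 10).
#' @param residual_sd Within-person measurement SD (default 5).
#' @param age_effect,gender_effect,ethnicity_effect,comorbidity_effect
#'   Covariate effects on the biomarker (units per year-over-50, per
#'   female, per not-white, per comorbidity category).
#' @param exposure_days_range Tested-drug exposure duration range in
#'   days (default 90 to 365, so every eligible window clears the
#'   30-day induction).
#' @param missing_end_frac Fraction of tested-drug exposures with a
#'   missing end date (default 0.1; durations never fall below the
#'   90-day imputation default, so the analysis window stays inside the
#'   true exposure).
#' @param inpatient_frac,inpatient_shift Fraction of extra measurements
#'   taken inpatient and their additive shift (defaults 0.15 and 25);
#'   these must be filtered out by the cohort stage.
#' @param nonsystemic_frac Fraction of persons whose tested-drug
#'   exposures are non-systemic route (default 0).
#' @param n_underage,n_coexposed,n_missing_period Planted
#'   exclusion-violating persons added per drug on top of `n_persons`
#'   (defaults 0; the bundled scenario plants 3, 5 and 4).
#' @param confound_frac,confound_effect Confounding-by-indication
#'   stressor: when enabled, this fraction of the cohort is co-exposed
#'   to an approved drug whose own effect (`confound_effect`, default
#'   -20) contaminates their treatment-period measurements.
#' @param nonadherence_frac Fraction of persons whose injected effect is
#'   attenuated by half (medication non-adherence; default 0).
#' @param induction_days,max_window_days,end_impute_days Window
#'   conventions shared with the cohort stage (30, 365, 90).
#' @param ramp_in If `TRUE` the injected effect ramps linearly over the
#'   induction period instead of switching on after it (stress test for
#'   induction handling; default `FALSE`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 5000, n_causal = 100,
                       causal_z_mean = 6, causal_z_sd = 1,
                       n_reversers = 5, n_decoys = 500,
                       reverser_fidelity = 0.9, library_overlap = 1,
                       n_extra_genes = 200,
                       n_persons = 300, visits_per_year = 6,
                       concept = "LDL-C", baseline_mean = 130,
                       person_sd = 10, residual_sd = 5,
                       age_effect = 0.3, gender_effect = -5,
                       ethnicity_effect = 3, comorbidity_effect = 2,
                       exposure_days_range = c(90, 365),
                       missing_end_frac = 0.1,
                       inpatient_frac = 0.15, inpatient_shift = 25,
                       nonsystemic_frac = 0,
                       n_underage = 0, n_coexposed = 0,
                       n_missing_period = 0,
                       confound_frac = 0.3, confound_effect = -20,
                       nonadherence_frac = 0,
                       induction_days = 30, max_window_days = 365,
                       end_impute_days = 90, ramp_in = FALSE) {
  if (missing(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(cfg$person_sd > 0, cfg$residual_sd > 0,
            cfg$n_genes >= 2 * cfg$n_causal,
            cfg$missing_end_frac >= 0, cfg$missing_end_frac <= 1,
            cfg$confound_frac >= 0, cfg$confound_frac <= 1,
            cfg$nonsystemic_frac >= 0, cfg$nonsystemic_frac <= 1)
  if (cfg$reverser_fidelity <= 0 || cfg$reverser_fidelity > 1)
    stop("sim_config: reverser_fidelity must be in (0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic imputed DEG table
#'
#' Causal genes receive Z-scores with magnitude
#' `Normal(causal_z_mean, causal_z_sd)` and random sign; null genes
#' draw `Z ~ Normal(0, 1)`. All p-values are the matching two-tailed
#' normal tail probabilities.
#'
#' @param cfg A [sim_config()].
#' @return List: `degs` (a `deg_table`), `truth` (data frame of causal
#'   genes with their true sign).
#' @export
gen_deg_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  causal <- sort(sample.int(cfg$n_genes, cfg$n_causal))
  z <- stats::rnorm(cfg$n_genes)
  sgn <- sample(c(-1, 1), cfg$n_causal, replace = TRUE)
  z[causal] <- sgn * abs(stats::rnorm(cfg$n_causal, cfg$causal_z_mean,
                                      cfg$causal_z_sd))
  p <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  degs <- as_deg_table(data.frame(gene = genes, zscore = z, pvalue = p,
                                  stringsAsFactors = FALSE))
  list(degs = degs,
       truth = data.frame(gene = genes[causal], sign = sgn,
                          stringsAsFactors = FALSE))
}

#' Generate a perturbation library with planted reversers
#'
#' Planted reversers carry the negated signature scores plus Gaussian
#' noise scaled so their expected correlation with the signature is
#' `-reverser_fidelity`; decoys are independent standard-normal values
#' over the same gene universe (signature genes, thinned to
#' `library_overlap`, plus `n_extra_genes` off-signature genes).
#'
#' @param sig A `disease_signature`.
#' @param cfg A [sim_config()].
#' @return List: `library` (named list of [drug_signature()]), `truth`
#'   (list with `reversers`, the planted drug names).
#' @export
gen_perturbation_library <- function(sig, cfg) {
  stopifnot(inherits(sig, "disease_signature"), inherits(cfg, "sim_config"))
  if (nrow(sig$entries) == 0L) stop("empty signature", call. = FALSE)
  set.seed(cfg$seed + 2L)
  s <- signature_scores(sig)
  extra <- if (cfg$n_extra_genes > 0)
    sprintf("X%04d", seq_len(cfg$n_extra_genes)) else character()
  # noise scale giving expected correlation -fidelity with the signature
  noise_sd <- stats::sd(s) * sqrt(1 / cfg$reverser_fidelity^2 - 1)
  pick_genes <- function() {
    k <- max(2L, round(cfg$library_overlap * length(s)))
    names(s)[sort(sample.int(length(s), k))]
  }
  lib <- list()
  for (i in seq_len(cfg$n_reversers)) {
    g <- pick_genes()
    vals <- c(-s[g] + stats::rnorm(length(g), 0, noise_sd),
              stats::setNames(stats::rnorm(length(extra)), extra))
    lib[[sprintf("REV%d", i)]] <-
      drug_signature(sprintf("REV%d", i), vals, "synthetic-reverser")
  }
  for (i in seq_len(cfg$n_decoys)) {
    g <- pick_genes()
    vals <- stats::setNames(stats::rnorm(length(g) + length(extra)),
                            c(g, extra))
    lib[[sprintf("DEC%03d", i)]] <-
      drug_signature(sprintf("DEC%03d", i), vals, "synthetic-decoy")
  }
  list(library = lib,
       truth = list(reversers = sprintf("REV%d", seq_len(cfg$n_reversers))))
}

#' Default Elixhauser-style prefix map
#'
#' A compact ICD-prefix to comorbidity-category map covering ten common
#' Elixhauser categories with ICD-9-CM and ICD-10-CM style prefixes.
#' Synthetic; intended for simulation and as a schema example, not as a
#' complete clinical grouper.
#'
#' @return Data frame with columns `prefix`, `category`.
#' @export
default_elixhauser_map <- function() {
  data.frame(
    prefix = c("428", "I50", "250", "E11", "401", "I10", "496", "J44",
               "571", "K70", "585", "N18", "290", "F03", "280", "D50",
               "493", "J45", "715", "M15"),
    category = rep(c("chf", "diabetes", "hypertension", "copd",
                     "liver_disease", "renal_failure", "dementia",
                     "anemia", "asthma", "arthritis"), each = 2),
    stringsAsFactors = FALSE)
}

#' Generate a longitudinal EHR extract with injected effects
#'
#' For each drug, generates `n_persons` clean persons plus any planted
#' exclusion violations, with first-exposure index dates, exposure
#' records (some with missing end dates), outpatient and inpatient
#' biomarker measurements across baseline and treatment periods, and
#' diagnosis codes drawn from the Elixhauser map. The injected effect
#' `delta` enters measurements taken while exposed and after the
#' induction period. Planted violations and all true per-person
#' intercepts are recorded in the manifest.
#'
#' @param cfg A [sim_config()].
#' @param drugs Data frame with columns `ingredient`, `delta` and
#'   optionally `n_persons` (per-drug override).
#' @param confounding Enable the confounding-by-indication stressor
#'   (default `FALSE`): `confound_frac` of each cohort is co-exposed to
#'   the approved drug `"approvedstatin"` whose `confound_effect`
#'   contaminates their treatment-period measurements.
#' @return List of class `ehr_tables` (the four tables) with attribute
#'   `manifest`: list with `drugs`, `violations` (person, ingredient,
#'   reason), `intercepts`, `approved_drug`.
#' @export
gen_ehr <- function(cfg, drugs, confounding = FALSE) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("ingredient", "delta") %in% names(drugs)))
  set.seed(cfg$seed + 3L)
  origin <- as.Date("2012-01-01")
  code_map <- default_elixhauser_map()
  persons_l <- list(); expo_l <- list(); meas_l <- list(); cond_l <- list()
  viol_l <- list(); icept_l <- list()

  for (d in seq_len(nrow(drugs))) {
    ing <- drugs$ingredient[d]
    delta <- drugs$delta[d]
    n_clean <- if ("n_persons" %in% names(drugs) &&
                   !is.na(drugs$n_persons[d])) drugs$n_persons[d]
               else cfg$n_persons
    n_conf <- if (confounding) round(cfg$confound_frac * n_clean) else 0L
    roles <- c(rep("clean", n_clean - n_conf), rep("confounded", n_conf),
               rep("underage", cfg$n_underage),
               rep("coexposed", cfg$n_coexposed),
               rep("missing_period", cfg$n_missing_period))
    n <- length(roles)
    pid <- sprintf("%s_P%04d", ing, seq_len(n))
    age <- stats::runif(n, 25, 80)
    age[roles == "underage"] <- stats::runif(sum(roles == "underage"),
                                             10, 16)
    index <- origin + sample.int(2190, n, replace = TRUE)
    birth <- index - round(age * 365.25)
    female <- stats::rbinom(n, 1, 0.5)
    nonwhite <- stats::rbinom(n, 1, 0.3)
    icept <- stats::rnorm(n, 0, cfg$person_sd)
    n_cats <- sample(0:3, n, replace = TRUE)
    dur <- round(stats::runif(n, cfg$exposure_days_range[1],
                              cfg$exposure_days_range[2]))
    end_missing <- stats::rbinom(n, 1, cfg$missing_end_frac) == 1
    nonsys <- stats::rbinom(n, 1, cfg$nonsystemic_frac) == 1
    attenuate <- stats::rbinom(n, 1, cfg$nonadherence_frac) == 1
    eff <- ifelse(attenuate, 0.5 * delta, delta)

    persons_l[[length(persons_l) + 1L]] <- data.frame(
      person_id = pid, birth_date = birth,
      gender = ifelse(female == 1, "female", "male"),
      ethnicity = ifelse(nonwhite == 1, "other", "white"),
      stringsAsFactors = FALSE)
    icept_l[[length(icept_l) + 1L]] <- data.frame(
      person_id = pid, intercept = icept, stringsAsFactors = FALSE)

    expo_l[[length(expo_l) + 1L]] <- data.frame(
      person_id = pid, ingredient = ing, start_date = index,
      end_date = as.Date(ifelse(end_missing, NA,
                                as.character(index + dur))),
      setting = "outpatient",
      route = ifelse(nonsys, "non-systemic", "systemic"),
      stringsAsFactors = FALSE)
    co <- roles %in% c("confounded", "coexposed")
    if (any(co)) {
      expo_l[[length(expo_l) + 1L]] <- data.frame(
        person_id = pid[co], ingredient = "approvedstatin",
        start_date = index[co] - 100, end_date = index[co] + 200,
        setting = "outpatient", route = "systemic",
        stringsAsFactors = FALSE)
    }

    # measurements: guaranteed offsets keep every clean person eligible
    # (two baseline dates, one induction date, two post-induction dates
    # inside the 90-day imputation window), plus Poisson extras
    fixed_off <- c(-200, -100, -30, 15, 45, 75)
    n_extra <- stats::rpois(n, 2 * cfg$visits_per_year)
    off_l <- lapply(seq_len(n), function(i) {
      off <- c(fixed_off,
               round(stats::runif(n_extra[i], -350, dur[i])))
      if (roles[i] == "missing_period") off <- off[off <= 0]
      off
    })
    k <- lengths(off_l)
    pi <- rep(seq_len(n), k)
    off <- unlist(off_l)
    inpat <- stats::rbinom(length(off), 1, cfg$inpatient_frac) == 1
    inpat[off %in% fixed_off & off <= 75] <- FALSE  # keep guarantees
    exposed <- if (cfg$ramp_in) {
      pmin(pmax(off / cfg$induction_days, 0), 1) * (off <= dur[pi])
    } else {
      as.numeric(off > cfg$induction_days & off <= dur[pi])
    }
    confd <- roles[pi] == "confounded" & off > 0
    # comorbidity gained during treatment raises post-induction values
    gain <- stats::rbinom(n, 1, 0.2) == 1 & n_cats < 8
    comorb <- n_cats[pi] + (gain[pi] & off > cfg$induction_days)
    # covariates enter at the person-period level (age at period end),
    # mirroring the paired estimand the validation model targets
    val <- cfg$baseline_mean + icept[pi] +
      cfg$age_effect * (age[pi] + (off > 0) * dur[pi] / 365.25 - 50) +
      cfg$gender_effect * female[pi] +
      cfg$ethnicity_effect * nonwhite[pi] +
      cfg$comorbidity_effect * comorb +
      eff[pi] * exposed +
      cfg$confound_effect * confd +
      cfg$inpatient_shift * inpat +
      stats::rnorm(length(off), 0, cfg$residual_sd)
    val <- if (cfg$concept == "SBP") pmin(pmax(val, 60), 260)
           else pmax(val, 20)
    meas_l[[length(meas_l) + 1L]] <- data.frame(
      person_id = pid[pi], concept = cfg$concept, date = index[pi] + off,
      value = round(val, 1),
      setting = ifelse(inpat, "inpatient", "outpatient"),
      stringsAsFactors = FALSE)

    # diagnosis codes: n_cats baseline categories; persons flagged above
    # gain one genuinely new category during the treatment period
    cats <- unique(code_map$category)
    pick_code <- function(cc)
      sample(code_map$prefix[code_map$category == cc], 1)
    cond_rows <- lapply(seq_len(n), function(i) {
      base_cats <- if (n_cats[i] > 0) sample(cats, n_cats[i])
                   else character()
      rows <- NULL
      if (n_cats[i] > 0) {
        rows <- data.frame(
          person_id = pid[i],
          code = vapply(base_cats, pick_code, character(1)),
          date = index[i] - sample(30:300, n_cats[i], replace = TRUE),
          stringsAsFactors = FALSE)
      }
      if (gain[i]) {
        new_cat <- sample(setdiff(cats, base_cats), 1)
        rows <- rbind(rows, data.frame(
          person_id = pid[i], code = pick_code(new_cat),
          date = index[i] + 60, stringsAsFactors = FALSE))
      }
      rows
    })
    cond_l[[length(cond_l) + 1L]] <- do.call(rbind, cond_rows)

    reason <- c(clean = NA, confounded = "approved_coexposure",
                underage = "age", coexposed = "approved_coexposure",
                missing_period = "missing_period_measurement")[roles]
    if (any(!is.na(reason))) {
      viol_l[[length(viol_l) + 1L]] <- data.frame(
        person_id = pid[!is.na(reason)], ingredient = ing,
        reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
    }
  }

  ehr <- structure(list(persons = do.call(rbind, persons_l),
                        drug_exposures = do.call(rbind, expo_l),
                        measurements = do.call(rbind, meas_l),
                        conditions = do.call(rbind, cond_l)),
                   class = c("ehr_tables", "list"))
  attr(ehr, "manifest") <- list(
    drugs = drugs, violations = do.call(rbind, viol_l),
    intercepts = do.call(rbind, icept_l),
    approved_drug = "approvedstatin")
  ehr
}

#' Write EHR tables to a directory of CSV files
#'
#' @param ehr An `ehr_tables` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(ehr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in EHR_TABLES)
    utils::write.csv(ehr[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(dir)
}

#' Generate a complete input bundle on disk
#'
#' Composes the three generators into a ready-to-run scenario
#' directory: a DEG table, a perturbation library whose planted
#' reversers map to EHR drug ingredients with injected effects of
#' clinically realistic magnitudes (one strong at -30, one weak at -5, nulls at
#' 0, plus one under-sized 19-person cohort to exercise the minimum
#' cohort rule), reference tables, a YAML run configuration and a YAML
#' truth manifest.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param cfg Optional [sim_config()]; defaults to `sim_config(seed)`
#'   with scenario planting (3 underage, 5 approved-co-exposed, 4
#'   single-period persons per drug).
#' @param deltas Injected effects for the planted reversers (recycled
#'   or truncated to `cfg$n_reversers`).
#' @param confounding Passed to [gen_ehr()].
#' @return The run-configuration list, invisibly; all files are under
#'   `dir`.
#' @export
gen_scenario <- function(dir, seed = 1L, cfg = NULL,
                         deltas = c(-30, -5, 0, 0, -10),
                         confounding = FALSE) {
  if (is.null(cfg))
    cfg <- sim_config(seed, n_underage = 3, n_coexposed = 5,
                      n_missing_period = 4)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  deg <- gen_deg_table(cfg)
  deg_path <- file.path(dir, "degs.tsv")
  utils::write.table(deg$degs, deg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sig <- select_topk(deg$degs, k = 50, disease = "synthetic-disease")
  lib <- gen_perturbation_library(sig, cfg)
  lib_long <- do.call(rbind, lapply(lib$library, function(ds)
    data.frame(drug = ds$drug, gene = names(ds$values),
               value = unname(ds$values), stringsAsFactors = FALSE)))
  lib_path <- file.path(dir, "library.tsv")
  utils::write.table(lib_long, lib_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  revs <- lib$truth$reversers
  deltas <- rep_len(deltas, length(revs))
  drugs <- data.frame(ingredient = tolower(revs), delta = deltas,
                      n_persons = cfg$n_persons, stringsAsFactors = FALSE)
  if (nrow(drugs) >= 5L) drugs$n_persons[5L] <- 19L  # under-sized cohort
  ehr <- gen_ehr(cfg, drugs, confounding = confounding)
  ehr_dir <- file.path(dir, "ehr")
  write_ehr(ehr, ehr_dir)

  # reference tables: the strong reverser plays the already-approved
  # drug role, alongside the synthetic approved co-medication
  approved <- data.frame(disease = "synthetic-disease",
                         ingredient = c("approvedstatin", drugs$ingredient[1]),
                         stringsAsFactors = FALSE)
  utils::write.table(approved, file.path(dir, "approved_drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dec <- setdiff(names(lib$library), revs)
  imap <- data.frame(
    drug = c(revs, dec),
    ingredient = c(tolower(revs), tolower(dec)),
    prescription = TRUE, stringsAsFactors = FALSE)
  if (length(dec)) imap$prescription[match(dec[1], imap$drug)] <- FALSE
  utils::write.table(imap, file.path(dir, "ingredient_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(default_elixhauser_map(),
                     file.path(dir, "elixhauser_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  config <- list(disease = "synthetic-disease", biomarker = cfg$concept,
                 deg_table = "degs.tsv", library = "library.tsv",
                 ehr_dir = "ehr", approved_drugs = "approved_drugs.tsv",
                 ingredient_map = "ingredient_map.tsv",
                 elixhauser_map = "elixhauser_map.tsv",
                 K = 50, q = 0.05, alpha_screen = 0.05,
                 alpha_validate = 0.05, min_cohort = 20,
                 induction_days = cfg$induction_days,
                 max_window_days = cfg$max_window_days,
                 end_impute_days = cfg$end_impute_days,
                 seed = cfg$seed, out_dir = "out")
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  # in-memory copy with absolute paths, ready for the pipeline drivers
  for (key in c("deg_table", "library", "ehr_dir", "approved_drugs",
                "ingredient_map", "elixhauser_map", "out_dir"))
    config[[key]] <- file.path(normalizePath(dir), config[[key]])

  manifest <- attr(ehr, "manifest")
  yaml::write_yaml(list(
    drugs = manifest$drugs, reversers = revs,
    violations = manifest$violations,
    approved_drug = manifest$approved_drug),
    file.path(dir, "manifest.yaml"))
  saveRDS(manifest, file.path(dir, "manifest.rds"))
  invisible(config)
}
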