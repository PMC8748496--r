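# Self-controlled case-series cohort construction.
#
# Each person exposed to the tested drug contributes a baseline period
# (up to 365 days before the first exposure, closed on both ends and
# including the index date) and a treatment period (after the index
# date up to the last exposure date, capped at 365 days, with the first
# 30 days discarded as a pharmacological induction period). All
# interval arithmetic is in whole days; a "year" is 365 days.

EHR_TABLES <- c("persons", "drug_exposures", "measurements", "conditions")

#' Read a minimal longitudinal EHR extract
#'
#' Reads four CSV tables from a directory: `persons.csv` (person_id,
#' birth_date, gender, ethnicity), `drug_exposures.csv` (person_id,
#' ingredient, start_date, end_date, setting, route),
#' `measurements.csv` (person_id, concept, date, value, setting) and
#' `conditions.csv` (person_id, code, date). Dates are ISO-8601 and
#' parsed to `Date`; an empty `end_date` is kept as `NA` (it is imputed
#' at window-building time).
#'
#' @param dir Directory containing the four CSV files.
#' @return Named list of four data frames, class `ehr_tables`.
#' @export
read_ehr <- function(dir) {
  stopifnot(dir.exists(dir))
  out <- lapply(EHR_TABLES, function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop("missing EHR table: ", f, call. = FALSE)
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(out) <- EHR_TABLES
  out$persons$birth_date <- as.Date(out$persons$birth_date)
  out$drug_exposures$start_date <- as.Date(out$drug_exposures$start_date)
  out$drug_exposures$end_date <- as.Date(
    ifelse(out$drug_exposures$end_date %in% c("", NA), NA,
           out$drug_exposures$end_date))
  out$measurements$date <- as.Date(out$measurements$date)
  out$conditions$date <- as.Date(out$conditions$date)
  structure(out, class = c("ehr_tables", "list"))
}

#' Build the observation window for one person
#'
#' The index date is the first outpatient exposure date; the baseline
#' period is `[index - max_len_days, index]` (closed, including the
#' index date) and the raw treatment period is
#' `(index, min(last exposure end, index + max_len_days)]`. Exposures
#' with a missing end date are imputed as `start + end_impute_days`.
#' A person is ineligible when the last exposure end is less than
#' `induction_days` after the index date, or when there is no
#' outpatient exposure at all.
#'
#' @param exposures Data frame of exposure records for one person and
#'   one ingredient (columns `start_date`, `end_date`, `setting`).
#' @param induction_days Induction period length (default 30); the
#'   effective treatment period starts strictly after
#'   `index + induction_days`.
#' @param max_len_days Maximum period length (default 365).
#' @param end_impute_days Imputed days supply for missing end dates
#'   (default 90).
#' @return A list of class `observation_window` with fields `index`,
#'   `baseline_start`, `treatment_end`, `effective_start`, `eligible`,
#'   `reason`; `eligible = FALSE` carries a reason code
#'   (`"no_outpatient_exposure"` or `"window_too_short"`).
#' @export
build_window <- function(exposures, induction_days = 30,
                         max_len_days = 365, end_impute_days = 90) {
  out <- exposures[exposures$setting == "outpatient", , drop = FALSE]
  win <- structure(list(index = as.Date(NA), baseline_start = as.Date(NA),
                        treatment_end = as.Date(NA),
                        effective_start = as.Date(NA),
                        eligible = FALSE, reason = NA_character_),
                   class = "observation_window")
  if (nrow(out) == 0L) { win$reason <- "no_outpatient_exposure"; return(win) }
  index <- min(out$start_date)
  end <- out$end_date
  end[is.na(end)] <- out$start_date[is.na(end)] + end_impute_days
  last <- max(end)
  if (as.numeric(last - index) < induction_days) {
    win$reason <- "window_too_short"
    return(win)
  }
  win$index <- index
  win$baseline_start <- index - max_len_days
  win$treatment_end <- min(last, index + max_len_days)
  win$effective_start <- index + induction_days
  win$eligible <- TRUE
  win
}

#' Build observation windows for every person exposed to an ingredient
#'
#' Vectorised counterpart of [build_window()]: one row per person with
#' any exposure record for the ingredient (eligible or not).
#'
#' @param ehr An [read_ehr()] list (or equivalent in-memory tables).
#' @param ingredient Tested drug ingredient.
#' @inheritParams build_window
#' @return Data frame: `person_id`, `index`, `baseline_start`,
#'   `treatment_end`, `effective_start`, `eligible`, `reason`.
#' @export
build_windows <- function(ehr, ingredient, induction_days = 30,
                          max_len_days = 365, end_impute_days = 90) {
  ex <- ehr$drug_exposures
  ex <- ex[ex$ingredient == ingredient, , drop = FALSE]
  all_pid <- unique(ex$person_id)
  out <- ex[ex$setting == "outpatient", , drop = FALSE]
  n <- length(all_pid)
  blank <- rep(as.Date(NA), n)
  res <- data.frame(person_id = all_pid, index = blank,
                    baseline_start = blank, treatment_end = blank,
                    effective_start = blank,
                    eligible = rep(FALSE, n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    end <- out$end_date
    end[is.na(end)] <- out$start_date[is.na(end)] + end_impute_days
    index <- as.Date(tapply(as.numeric(out$start_date), out$person_id, min),
                     origin = "1970-01-01")
    last <- as.Date(tapply(as.numeric(end), out$person_id, max),
                    origin = "1970-01-01")
    i <- match(names(index), res$person_id)
    res$index[i] <- index
    res$baseline_start[i] <- index - max_len_days
    res$treatment_end[i] <- pmin(last, index + max_len_days)
    res$effective_start[i] <- index + induction_days
    ok <- as.numeric(last - index) >= induction_days
    res$eligible[i] <- ok
    res$reason[i][!ok] <- "window_too_short"
  }
  res$reason[is.na(res$index)] <- "no_outpatient_exposure"
  res
}

#' Apply the cohort exclusion cascade
#'
#' Runs the fixed-order exclusion cascade on persons with eligible
#' observation windows and records attrition after every step:
#' \enumerate{
#'   \item adults: age at the index date in `[min_age, max_age)`;
#'   \item at least one outpatient biomarker measurement in the
#'     baseline period and one in the effective (post-induction)
#'     treatment period;
#'   \item no exposure to any approved drug for the disease (other than
#'     the tested drug itself) overlapping the observation window;
#'   \item at least two distinct outpatient biomarker measurement dates
#'     within a 730-day span inside the window (information-leakage
#'     guard);
#'   \item optionally, only systemic-route exposures to the tested drug.
#' }
#'
#' @param ehr An [read_ehr()] list.
#' @param windows Output of [build_windows()].
#' @param approved_drugs Character vector of ingredients approved for
#'   the disease of interest.
#' @param tested_drug Ingredient under test; if itself approved, its own
#'   exposures never trigger step 3.
#' @param concept Biomarker concept name (e.g. `"LDL-C"`).
#' @param min_age,max_age Age bounds in years at index; the lower bound
#'   is inclusive, the upper exclusive (defaults 18 and 90).
#' @param min_cohort Minimum cohort size for a testable drug
#'   (default 20).
#' @param route_filter If `TRUE`, apply step 5 (systemic route only).
#' @param end_impute_days Imputed days supply for co-exposure records
#'   with a missing end date (default 90).
#' @param approved_filter If `FALSE`, step 3 is skipped (kept as an
#'   explicit switch so the confounding-by-indication stressor can be
#'   demonstrated); attrition still records the step with zero removals.
#' @return List with `retained` (person ids), `attrition` (data frame
#'   `step`, `persons_remaining`), `removed` (named list of person ids
#'   removed at each step), `untestable` (final n below `min_cohort`).
#' @export
apply_exclusions <- function(ehr, windows, approved_drugs, tested_drug,
                             concept, min_age = 18, max_age = 90,
                             min_cohort = 20, route_filter = FALSE,
                             approved_filter = TRUE, end_impute_days = 90) {
  w <- windows[windows$eligible, , drop = FALSE]
  attr_steps <- c("exposed", "eligible_window")
  attr_n <- c(nrow(windows), nrow(w))
  removed <- list()
  keep <- w$person_id

  drop_step <- function(step, bad_ids) {
    removed[[step]] <<- intersect(keep, bad_ids)
    keep <<- setdiff(keep, bad_ids)
    attr_steps <<- c(attr_steps, step)
    attr_n <<- c(attr_n, length(keep))
  }

  # step 1: adult age at index
  birth <- ehr$persons$birth_date[match(w$person_id, ehr$persons$person_id)]
  age <- as.numeric(w$index - birth) / 365.25
  drop_step("age", w$person_id[is.na(age) | age < min_age | age >= max_age])

  # step 2: >=1 outpatient biomarker in both periods
  pm <- measurement_flags(ehr, w, concept)
  drop_step("missing_period_measurement",
            w$person_id[!(w$person_id %in%
                            pm$person_id[pm$has_baseline & pm$has_treatment])])

  # step 3: approved-drug co-exposure overlapping the window
  blocked <- setdiff(approved_drugs, tested_drug)
  if (approved_filter && length(blocked)) {
    ex <- ehr$drug_exposures
    ex <- ex[ex$ingredient %in% blocked & ex$person_id %in% keep, ,
             drop = FALSE]
    bad <- character()
    if (nrow(ex)) {
      i <- match(ex$person_id, w$person_id)
      end <- ex$end_date
      end[is.na(end)] <- ex$start_date[is.na(end)] + end_impute_days
      overlap <- ex$start_date <= w$treatment_end[i] &
        end >= w$baseline_start[i]
      bad <- unique(ex$person_id[overlap])
    }
    drop_step("approved_coexposure", bad)
  } else {
    drop_step("approved_coexposure", character())
  }

  # step 4: >=2 distinct outpatient measurement dates within 730 days
  m <- ehr$measurements
  m <- m[m$setting == "outpatient" & m$concept == concept &
           m$person_id %in% keep, , drop = FALSE]
  i <- match(m$person_id, w$person_id)
  inside <- m$date >= w$baseline_start[i] & m$date <= w$treatment_end[i]
  m <- m[inside, , drop = FALSE]
  nd <- tapply(as.numeric(m$date), m$person_id,
               function(d) length(unique(d)))
  span <- tapply(as.numeric(m$date), m$person_id,
                 function(d) diff(range(d)))
  good <- names(nd)[nd >= 2 & span <= 730]
  drop_step("two_visit_guard", setdiff(keep, good))

  # step 5 (optional): systemic route only
  if (route_filter) {
    ex <- ehr$drug_exposures
    ex <- ex[ex$ingredient == tested_drug & ex$person_id %in% keep, ,
             drop = FALSE]
    bad <- unique(ex$person_id[!is.na(ex$route) & ex$route != "systemic"])
    drop_step("non_systemic_route", bad)
  }

  attrition <- data.frame(step = attr_steps, persons_remaining = attr_n,
                          stringsAsFactors = FALSE)
  list(retained = keep, attrition = attrition, removed = removed,
       untestable = length(keep) < min_cohort)
}

# per-person indicators of outpatient biomarker presence in each period
measurement_flags <- function(ehr, w, concept) {
  m <- ehr$measurements
  m <- m[m$setting == "outpatient" & m$concept == concept &
           m$person_id %in% w$person_id, , drop = FALSE]
  i <- match(m$person_id, w$person_id)
  in_base <- m$date >= w$baseline_start[i] & m$date <= w$index[i]
  in_treat <- m$date > w$effective_start[i] & m$date <= w$treatment_end[i]
  hb <- tapply(in_base, m$person_id, any)
  ht <- tapply(in_treat, m$person_id, any)
  data.frame(person_id = names(hb), has_baseline = as.logical(hb),
             has_treatment = as.logical(ht[names(hb)]),
             stringsAsFactors = FALSE)
}

#' Per-period median biomarker values
#'
#' For each retained person, the median of all qualifying outpatient
#' biomarker values per period. The baseline period includes the index
#' date; treatment values must fall strictly after the 30-day induction
#' period and on or before the treatment end.
#'
#' @param ehr An [read_ehr()] list.
#' @param windows [build_windows()] output.
#' @param concept Biomarker concept.
#' @param persons Person ids to compute medians for (typically the
#'   `retained` set from [apply_exclusions()]).
#' @return Data frame `person_id`, `baseline`, `treatment` (medians).
#' @export
period_medians <- function(ehr, windows, concept, persons) {
  w <- windows[match(persons, windows$person_id), , drop = FALSE]
  m <- ehr$measurements
  m <- m[m$setting == "outpatient" & m$concept == concept &
           m$person_id %in% persons, , drop = FALSE]
  i <- match(m$person_id, w$person_id)
  in_base <- m$date >= w$baseline_start[i] & m$date <= w$index[i]
  in_treat <- m$date > w$effective_start[i] & m$date <= w$treatment_end[i]
  med <- function(flag) {
    mm <- m[flag, , drop = FALSE]
    v <- tapply(mm$value, mm$person_id, stats::median)
    as.numeric(v[persons])
  }
  out <- data.frame(person_id = persons, baseline = med(in_base),
                    treatment = med(in_treat), stringsAsFactors = FALSE)
  if (anyNA(out$baseline) || anyNA(out$treatment))
    stop("internal error: person with empty measurement period survived ",
         "exclusion step 2", call. = FALSE)
  out
}

#' Remove per-period median outliers (Tukey fences)
#'
#' Computes `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` fences separately for the
#' baseline medians and the treatment medians across the cohort
#' (quartiles by linear interpolation, the type-7 default) and drops a
#' person when either of their medians falls outside its period's
#' fences. Cohorts smaller than 4 are returned unchanged with a
#' warning.
#'
#' @param medians [period_medians()] output.
#' @return List: `kept` (filtered data frame), `dropped` (person ids),
#'   `fences` (2x2 matrix of bounds).
#' @export
remove_outliers <- function(medians) {
  if (nrow(medians) < 4L) {
    warning("cohort below 4 persons; outlier removal skipped")
    return(list(kept = medians, dropped = character(),
                fences = NULL))
  }
  fence <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  }
  fb <- fence(medians$baseline); ft <- fence(medians$treatment)
  out <- medians$baseline < fb["lower"] | medians$baseline > fb["upper"] |
    medians$treatment < ft["lower"] | medians$treatment > ft["upper"]
  list(kept = medians[!out, , drop = FALSE],
       dropped = medians$person_id[out],
       fences = rbind(baseline = fb, treatment = ft))
}

#' Elixhauser comorbidity index for one person
#'
#' Matches diagnosis codes (ICD-9/10-CM style strings) against a
#' prefix-to-category map. A category is present when at least one code
#' dated in `[obs_start, as_of]` starts with one of its prefixes. The
#' default index is the unweighted category count; a named weight
#' vector (e.g. van Walraven) yields a weighted sum.
#'
#' @param codes,dates Condition codes and their dates for one person.
#' @param obs_start,as_of Date bounds (both inclusive); codes outside
#'   are ignored.
#' @param code_map Data frame with columns `prefix`, `category`.
#' @param weights Optional named numeric vector `category -> weight`.
#' @return List: `index` (numeric), `categories` (character vector).
#' @export
elixhauser_index <- function(codes, dates, obs_start, as_of, code_map,
                             weights = NULL) {
  if (!is.data.frame(code_map) || nrow(code_map) == 0L ||
      !all(c("prefix", "category") %in% names(code_map)))
    stop("elixhauser config error: empty or malformed code map",
         call. = FALSE)
  keep <- dates >= obs_start & dates <= as_of
  codes <- codes[keep]
  cats <- character()
  if (length(codes)) {
    hit <- vapply(code_map$prefix,
                  function(p) any(startsWith(codes, p)), logical(1))
    cats <- sort(unique(code_map$category[hit]))
  }
  idx <- if (is.null(weights)) length(cats)
         else sum(weights[cats], na.rm = TRUE)
  list(index = idx, categories = cats)
}

# vectorised person x category presence flags up to an as-of date per person
elixhauser_flags <- function(conditions, persons, obs_start, as_of,
                             code_map) {
  co <- conditions[conditions$person_id %in% persons, , drop = FALSE]
  i <- match(co$person_id, persons)
  co <- co[co$date >= obs_start[i] & co$date <= as_of[i], , drop = FALSE]
  cats <- sort(unique(code_map$category))
  flags <- matrix(FALSE, nrow = length(persons), ncol = length(cats),
                  dimnames = list(persons, cats))
  if (nrow(co)) {
    for (j in seq_len(nrow(code_map))) {
      hit <- startsWith(co$code, code_map$prefix[j])
      if (any(hit))
        flags[cbind(match(co$person_id[hit], persons),
                    match(code_map$category[j], cats))] <- TRUE
    }
  }
  flags
}

z_norm <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Assemble the two-row-per-person model table
#'
#' Builds the paired table the mixed model is fitted on: one baseline
#' row (`drugExposure = 0`) and one treatment row (`drugExposure = 1`)
#' per person. `Age` is the age at the end of each period and
#' `Comorbidity` the Elixhauser index accumulated from the start of the
#' observation period to the end of each period; both are z-normalised
#' across all rows of the final table. `Gender` is 1 for female,
#' `Ethnicity` 1 for not white. Raw (unnormalised) age and comorbidity
#' values and per-category flags are attached as attributes for the
#' demographics report.
#'
#' @param ehr An [read_ehr()] list.
#' @param windows [build_windows()] output.
#' @param medians Per-person medians, after outlier removal.
#' @param code_map Elixhauser prefix map.
#' @param weights Optional Elixhauser category weights.
#' @return Data frame of class `cohort_model_table` with columns
#'   `person_id`, `period`, `biomarkerVal`, `drugExposure`, `Age`,
#'   `Gender`, `Ethnicity`, `Comorbidity`.
#' @export
assemble_model_table <- function(ehr, windows, medians, code_map,
                                 weights = NULL) {
  persons <- medians$person_id
  p <- ehr$persons[match(persons, ehr$persons$person_id), , drop = FALSE]
  miss <- is.na(p$birth_date) | is.na(p$gender) | is.na(p$ethnicity)
  if (any(miss)) {
    message(sum(miss), " person(s) dropped for missing demographics")
    persons <- persons[!miss]
    medians <- medians[!miss, , drop = FALSE]
    p <- p[!miss, , drop = FALSE]
  }
  w <- windows[match(persons, windows$person_id), , drop = FALSE]
  age_b <- as.numeric(w$index - p$birth_date) / 365.25
  age_t <- as.numeric(w$treatment_end - p$birth_date) / 365.25
  fl_b <- elixhauser_flags(ehr$conditions, persons, w$baseline_start,
                           w$index, code_map)
  fl_t <- elixhauser_flags(ehr$conditions, persons, w$baseline_start,
                           w$treatment_end, code_map)
  cidx <- function(fl) {
    if (is.null(weights)) rowSums(fl)
    else as.numeric(fl %*% weights[colnames(fl)])
  }
  n <- length(persons)
  tab <- data.frame(
    person_id = rep(persons, 2L),
    period = rep(c("baseline", "treatment"), each = n),
    biomarkerVal = c(medians$baseline, medians$treatment),
    drugExposure = rep(c(0, 1), each = n),
    age_raw = c(age_b, age_t),
    Gender = rep(as.numeric(p$gender == "female"), 2L),
    Ethnicity = rep(as.numeric(p$ethnicity != "white"), 2L),
    comorbidity_raw = c(cidx(fl_b), cidx(fl_t)),
    stringsAsFactors = FALSE)
  tab$Age <- z_norm(tab$age_raw)
  tab$Comorbidity <- z_norm(tab$comorbidity_raw)
  tab <- tab[order(tab$person_id, tab$period), ]
  rownames(tab) <- NULL
  attr(tab, "elixhauser_baseline") <- fl_b
  attr(tab, "elixhauser_treatment") <- fl_t
  class(tab) <- c("cohort_model_table", "data.frame")
  tab
}
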