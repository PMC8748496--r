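# Treatment-effect estimation on the paired cohort table.
#
# The model is
#   biomarkerVal ~ b0 + b1 drugExposure + b2 Age + b3 Gender +
#                  b4 Ethnicity + b5 Comorbidity + (1 | person)
# fitted by REML; each person contributes a baseline and a treatment
# row, so b1 is the covariate-adjusted within-person biomarker change.
# Inference on b1 is Wald with normal quantiles. Reported p-values are
# floored at 2.2e-16.

P_FLOOR <- 2.2e-16

#' Fit the paired random-intercept treatment-effect model
#'
#' Fits the linear mixed model above with [lme4::lmer()] (REML) on a
#' two-row-per-person cohort table. Constant or aliased covariate
#' columns are dropped before fitting (with a message) so the fixed
#' design is full rank. If the mixed-model fit fails outright the
#' function falls back to the paired-difference estimate (flagged
#' `converged = FALSE`).
#'
#' @param tab A `cohort_model_table` (or any data frame with columns
#'   `person_id`, `biomarkerVal`, `drugExposure` and optionally `Age`,
#'   `Gender`, `Ethnicity`, `Comorbidity`).
#' @param drug Drug label stored on the result.
#' @param covariates Character vector of fixed-effect adjusters to
#'   include beyond `drugExposure`. Defaults to the four model
#'   covariates; use `character()` for the unadjusted paired model.
#' @return A list of class `treatment_effect`: `drug`, `beta1`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n_persons`, `fixed_effects`, `sigma_u`,
#'   `sigma_e`, `converged`, `method`.
#' @export
fit_sccs_lmm <- function(tab, drug = "drug",
                         covariates = c("Age", "Gender", "Ethnicity",
                                        "Comorbidity")) {
  stopifnot(all(c("person_id", "biomarkerVal", "drugExposure") %in%
                  names(tab)))
  n_persons <- length(unique(tab$person_id))
  covariates <- intersect(covariates, names(tab))
  # drop constant covariates (zero variance makes the design singular)
  const <- vapply(covariates,
                  function(v) stats::var(tab[[v]]) == 0, logical(1))
  if (any(const)) {
    message("dropping constant covariate(s): ",
            paste(covariates[const], collapse = ", "))
    covariates <- covariates[!const]
  }
  # drop aliased columns so the fixed design is full rank
  X <- as.matrix(cbind(1, tab[, c("drugExposure", covariates),
                              drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_idx <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- setdiff(colnames(X), colnames(X)[keep_idx])
    aliased <- setdiff(aliased, c("1", "drugExposure"))
    if (length(aliased)) {
      message("dropping aliased covariate(s): ",
              paste(aliased, collapse = ", "))
      covariates <- setdiff(covariates, aliased)
    }
  }
  rhs <- paste(c("drugExposure", covariates, "(1 | person_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("biomarkerVal ~", rhs))
  fit_warnings <- character()
  fit <- withCallingHandlers(
    tryCatch(
      suppressMessages(lme4::lmer(form, data = tab, REML = TRUE,
                                  control = lme4::lmerControl(
                                    check.conv.singular = "ignore"))),
      error = function(e) e),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    warning("mixed-model fit failed (", conditionMessage(fit),
            "); falling back to the paired-difference estimate")
    po <- paired_difference_oracle(tab)
    return(structure(list(drug = drug, beta1 = po$estimate, se = po$se,
                          ci_low = po$ci_low, ci_high = po$ci_high,
                          p = po$p, n_persons = n_persons,
                          fixed_effects = c(drugExposure = po$estimate),
                          sigma_u = NA_real_, sigma_e = NA_real_,
                          converged = FALSE, method = "paired_fallback"),
                     class = "treatment_effect"))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  b1 <- beta[["drugExposure"]]
  s1 <- se[[which(names(beta) == "drugExposure")]]
  z <- b1 / s1
  p <- max(2 * stats::pnorm(-abs(z)), P_FLOOR)
  vc <- lme4::VarCorr(fit)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    drug = drug, beta1 = b1, se = s1,
    ci_low = b1 - stats::qnorm(0.975) * s1,
    ci_high = b1 + stats::qnorm(0.975) * s1,
    p = p, n_persons = n_persons, fixed_effects = beta,
    sigma_u = sqrt(vc$person_id[1, 1]),
    sigma_e = stats::sigma(fit),
    converged = is.null(conv_msgs) && length(fit_warnings) == 0L,
    method = "lmm_reml_wald"),
    class = "treatment_effect")
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf("%s: beta1 = %.3f [%.3f, %.3f], p = %.3g, n = %d (%s)\n",
              x$drug, x$beta1, x$ci_low, x$ci_high, x$p, x$n_persons,
              x$method))
  invisible(x)
}

#' Paired-difference reference estimate
#'
#' The mean within-person difference (treatment minus baseline) with a
#' paired t-test CI and p-value. On a balanced paired table this equals
#' the covariate-free mixed-model treatment estimate, so it serves as
#' an independent check and as the non-convergence fallback.
#'
#' @param tab Two-row-per-person table as in [fit_sccs_lmm()].
#' @return List: `estimate`, `se`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
paired_difference_oracle <- function(tab) {
  b <- tab[tab$drugExposure == 0, ]
  t <- tab[tab$drugExposure == 1, ]
  d <- t$biomarkerVal[match(b$person_id, t$person_id)] - b$biomarkerVal
  n <- length(d)
  if (n < 2L) stop("paired difference undefined for n < 2", call. = FALSE)
  if (stats::sd(d) == 0) {
    est <- mean(d)
    return(list(estimate = est, se = 0, ci_low = est, ci_high = est,
                p = if (est == 0) 1 else P_FLOOR, n = n))
  }
  tt <- stats::t.test(d)
  list(estimate = unname(tt$estimate), se = unname(tt$stderr),
       ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
       p = max(tt$p.value, P_FLOOR), n = n)
}

#' Classify per-drug treatment effects
#'
#' Flags each drug as therapeutic (negative point estimate with
#' `p < alpha`) and as Bonferroni-significant (`p` below
#' `alpha / n_tested`), and splits counts by approval status for the
#' target disease.
#'
#' @param results List of `treatment_effect` objects (or a data frame
#'   with columns `drug`, `beta1`, `p`, `n_persons`).
#' @param n_tested Number of drugs tested (the Bonferroni family size);
#'   defaults to the number of results.
#' @param alpha Family-wise significance level (default 0.05).
#' @param approved_for_disease Ingredients approved for the target
#'   disease.
#' @param disease,biomarker Labels stored on the summary.
#' @return A list of class `screen_summary`: `disease`, `biomarker`,
#'   `effects` (data frame with flag columns), `n_tested`,
#'   `bonferroni_threshold`, `counts` (classification table).
#' @export
classify_effects <- function(results, n_tested = NULL, alpha = 0.05,
                             approved_for_disease = character(),
                             disease = "disease", biomarker = "biomarker") {
  if (is.data.frame(results)) df <- results
  else df <- do.call(rbind, lapply(results, function(x)
    data.frame(drug = x$drug, beta1 = x$beta1, se = x$se,
               ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
               n_persons = x$n_persons, converged = x$converged,
               stringsAsFactors = FALSE)))
  if (is.null(n_tested)) n_tested <- nrow(df)
  stopifnot(n_tested >= 1)
  thr <- alpha / n_tested
  df$therapeutic <- df$beta1 < 0 & df$p < alpha
  df$bonferroni_significant <- df$therapeutic & df$p < thr
  df$approved_for_disease <- df$drug %in% approved_for_disease
  df <- df[order(df$p, df$drug), ]
  rownames(df) <- NULL
  counts <- data.frame(
    class = c("tested", "therapeutic_p05", "therapeutic_p05_approved",
              "therapeutic_p05_other", "bonferroni",
              "bonferroni_approved", "bonferroni_other"),
    n = c(n_tested, sum(df$therapeutic),
          sum(df$therapeutic & df$approved_for_disease),
          sum(df$therapeutic & !df$approved_for_disease),
          sum(df$bonferroni_significant),
          sum(df$bonferroni_significant & df$approved_for_disease),
          sum(df$bonferroni_significant & !df$approved_for_disease)))
  structure(list(disease = disease, biomarker = biomarker, effects = df,
                 n_tested = n_tested, bonferroni_threshold = thr,
                 counts = counts),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary:", x$disease, "/", x$biomarker, "\n")
  cat(sprintf("  %d drugs tested; Bonferroni threshold %.3g\n",
              x$n_tested, x$bonferroni_threshold))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Cohort demographics comparison tables
#'
#' Baseline-versus-treatment comparisons for a single drug cohort:
#' paired Wilcoxon signed-rank tests for age and the Elixhauser index,
#' a continuity-corrected McNemar test per comorbidity category, and
#' count summaries for gender and ethnicity. Any subgroup count below
#' `suppression_n` is suppressed (reported as `NA` with
#' `suppressed = TRUE`), mirroring small-cell privacy reporting rules.
#'
#' @param tab A `cohort_model_table` from [assemble_model_table()].
#' @param suppression_n Minimum reportable subgroup size (default 20).
#' @param exact_mcnemar Use the exact binomial McNemar variant instead
#'   of the continuity-corrected chi-square (default `FALSE`).
#' @return List of class `demographics_report` with elements
#'   `continuous` (age/comorbidity medians, IQRs and Wilcoxon p),
#'   `categorical` (per-category counts and McNemar p) and `counts`
#'   (gender/ethnicity subgroup counts with suppression flags).
#' @export
demographics_report <- function(tab, suppression_n = 20,
                                exact_mcnemar = FALSE) {
  b <- tab[tab$period == "baseline", ]
  t <- tab[tab$period == "treatment", ]
  t <- t[match(b$person_id, t$person_id), ]
  n <- nrow(b)

  paired_wilcoxon <- function(x0, x1) {
    d <- x1 - x0
    if (all(d == 0)) return(NA_real_)  # degenerate: no paired differences
    suppressWarnings(stats::wilcox.test(x1, x0, paired = TRUE)$p.value)
  }
  summ <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                              stats::quantile(x, 0.25),
                              stats::quantile(x, 0.75))
  continuous <- data.frame(
    variable = c("age", "elixhauser_index"),
    baseline = c(summ(b$age_raw), summ(b$comorbidity_raw)),
    treatment = c(summ(t$age_raw), summ(t$comorbidity_raw)),
    p_wilcoxon = c(paired_wilcoxon(b$age_raw, t$age_raw),
                   paired_wilcoxon(b$comorbidity_raw, t$comorbidity_raw)),
    stringsAsFactors = FALSE)

  fb <- attr(tab, "elixhauser_baseline")
  ft <- attr(tab, "elixhauser_treatment")
  categorical <- NULL
  if (!is.null(fb) && !is.null(ft)) {
    ft <- ft[rownames(fb), , drop = FALSE]
    categorical <- do.call(rbind, lapply(colnames(fb), function(cat) {
      x0 <- fb[, cat]; x1 <- ft[, cat]
      bc <- sum(x0 & !x1); cc <- sum(!x0 & x1)  # discordant pairs
      p <- if (bc + cc == 0) NA_real_
           else if (exact_mcnemar)
             stats::binom.test(bc, bc + cc)$p.value
           else mcnemar_cc(bc, cc)
      data.frame(category = cat, n_baseline = sum(x0),
                 n_treatment = sum(x1), p_mcnemar = p,
                 suppressed = sum(x0) < suppression_n &
                   sum(x1) < suppression_n,
                 stringsAsFactors = FALSE)
    }))
    categorical$n_baseline[categorical$suppressed] <- NA_integer_
    categorical$n_treatment[categorical$suppressed] <- NA_integer_
  }

  count_row <- function(label, k) {
    data.frame(subgroup = label,
               n = if (k < suppression_n) NA_integer_ else k,
               suppressed = k < suppression_n, stringsAsFactors = FALSE)
  }
  counts <- rbind(count_row("female", sum(b$Gender == 1)),
                  count_row("male_or_other", sum(b$Gender == 0)),
                  count_row("white", sum(b$Ethnicity == 0)),
                  count_row("not_white", sum(b$Ethnicity == 1)))
  structure(list(n = n, continuous = continuous,
                 categorical = categorical, counts = counts),
            class = "demographics_report")
}

# continuity-corrected McNemar chi-square on the discordant counts
mcnemar_cc <- function(b, c) {
  if (b + c == 0) return(NA_real_)
  stat <- (abs(b - c) - 1)^2 / (b + c)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
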