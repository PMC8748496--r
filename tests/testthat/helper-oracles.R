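# Independent brute-force oracles and small fixture builders used
# across the suite. These deliberately avoid the package's own code
# paths (and stats::p.adjust) so they can serve as references.

# Benjamini-Hochberg by direct construction: rank the p-values, scale
# by m / rank, then take the cumulative minimum from the largest rank
# down; return on the original order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson correlation and two-tailed p by explicit sums, with optional
# non-negative weights (normalised internally).
pearson_brute <- function(x, y, w = NULL) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  r <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# quick DEG table from parallel vectors
deg_fix <- function(gene, z, p) {
  as_deg_table(data.frame(gene = gene, zscore = z, pvalue = p,
                          stringsAsFactors = FALSE))
}

# balanced two-row-per-person table with known per-person differences
paired_table_fix <- function(baseline, diff, covariates = FALSE,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(baseline)
  id <- sprintf("P%03d", seq_len(n))
  tab <- data.frame(
    person_id = rep(id, 2),
    period = rep(c("baseline", "treatment"), each = n),
    biomarkerVal = c(baseline, baseline + diff),
    drugExposure = rep(c(0, 1), each = n),
    stringsAsFactors = FALSE)
  if (covariates) {
    tab$Age <- rep(rnorm(n), 2)
    tab$Gender <- rep(rbinom(n, 1, 0.5), 2)
    tab$Ethnicity <- rep(rbinom(n, 1, 0.3), 2)
    tab$Comorbidity <- rep(rnorm(n), 2)
  }
  tab
}

# minimal hand-built EHR list for cohort unit tests
ehr_fix <- function(persons, exposures, measurements,
                    conditions = NULL) {
  if (is.null(conditions))
    conditions <- data.frame(person_id = character(), code = character(),
                             date = as.Date(character()),
                             stringsAsFactors = FALSE)
  structure(list(persons = persons, drug_exposures = exposures,
                 measurements = measurements, conditions = conditions),
            class = c("ehr_tables", "list"))
}
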