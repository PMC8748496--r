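expo_row <- function(pid, start, end = NA, ingredient = "drugx",
                     setting = "outpatient", route = "systemic") {
  data.frame(person_id = pid, ingredient = ingredient,
             start_date = as.Date(start),
             end_date = as.Date(end), setting = setting, route = route,
             stringsAsFactors = FALSE)
}

meas_row <- function(pid, date, value, concept = "LDL-C",
                     setting = "outpatient") {
  data.frame(person_id = pid, concept = concept, date = as.Date(date),
             value = value, setting = setting, stringsAsFactors = FALSE)
}

test_that("observation windows follow the index/baseline/treatment
           date arithmetic", {
  w <- build_window(expo_row("p1", "2010-01-01", "2010-06-30"))
  expect_true(w$eligible)
  expect_equal(w$index, as.Date("2010-01-01"))
  expect_equal(w$baseline_start, as.Date("2009-01-01"))
  expect_equal(w$effective_start, as.Date("2010-01-31"))
  expect_equal(w$treatment_end, as.Date("2010-06-30"))

  # below the 30-day induction minimum
  short <- build_window(expo_row("p1", "2010-01-01", "2010-01-16"))
  expect_false(short$eligible)
  expect_equal(short$reason, "window_too_short")

  # treatment capped at one year
  long <- build_window(expo_row("p1", "2010-01-01", "2011-12-01"))
  expect_equal(long$treatment_end, as.Date("2010-01-01") + 365)

  # missing end date imputed as start + 90 days
  open <- build_window(expo_row("p1", "2010-01-01"))
  expect_equal(open$treatment_end, as.Date("2010-04-01"))

  # inpatient-only exposure is ineligible with a reason
  inpat <- build_window(expo_row("p1", "2010-01-01", "2010-06-30",
                                 setting = "inpatient"))
  expect_equal(inpat$reason, "no_outpatient_exposure")

  # record order does not matter
  two <- rbind(expo_row("p1", "2010-03-01", "2010-06-30"),
               expo_row("p1", "2010-01-01", "2010-02-15"))
  expect_equal(build_window(two), build_window(two[2:1, ]))
  expect_equal(build_window(two)$index, as.Date("2010-01-01"))
})

test_that("exclusion cascade removes planted violations step by step", {
  ehr <- gen_ehr(sim_config(41, n_persons = 40, n_underage = 3,
                            n_coexposed = 5, n_missing_period = 4),
                 data.frame(ingredient = "drugx", delta = 0))
  manifest <- attr(ehr, "manifest")
  windows <- build_windows(ehr, "drugx")
  exc <- apply_exclusions(ehr, windows, "approvedstatin", "drugx",
                          "LDL-C")
  viol <- manifest$violations
  for (rs in c("age", "missing_period_measurement",
               "approved_coexposure")) {
    expect_setequal(exc$removed[[rs]],
                    viol$person_id[viol$reason == rs])
  }
  expect_true(all(diff(exc$attrition$persons_remaining) <= 0))
  expect_equal(length(exc$retained),
               utils::tail(exc$attrition$persons_remaining, 1))
  expect_false(exc$untestable)

  # retained persons have no approved co-exposure inside the window
  ex <- ehr$drug_exposures
  expect_false(any(ex$ingredient == "approvedstatin" &
                     ex$person_id %in% exc$retained))
})

test_that("the tested drug itself being approved does not exclude its
           own users, and small cohorts are untestable", {
  ehr <- gen_ehr(sim_config(43, n_persons = 30),
                 data.frame(ingredient = "drugx", delta = 0))
  windows <- build_windows(ehr, "drugx")
  # drugx approved for the disease: its own exposures never trigger
  # the approved-drug exclusion
  exc <- apply_exclusions(ehr, windows, c("approvedstatin", "drugx"),
                          "drugx", "LDL-C")
  expect_equal(length(exc$removed$approved_coexposure), 0L)
  expect_equal(length(exc$retained), 30L)

  ehr19 <- gen_ehr(sim_config(44, n_persons = 19),
                   data.frame(ingredient = "drugx", delta = 0))
  exc19 <- apply_exclusions(ehr19, build_windows(ehr19, "drugx"),
                            "approvedstatin", "drugx", "LDL-C")
  expect_true(exc19$untestable)
})

test_that("period medians respect period bounds and the induction
           period", {
  persons <- data.frame(person_id = "p1",
                        birth_date = as.Date("1960-01-01"),
                        gender = "female", ethnicity = "white",
                        stringsAsFactors = FALSE)
  ex <- expo_row("p1", "2010-01-01", "2010-12-01")
  meas <- rbind(
    meas_row("p1", "2009-06-01", 130), meas_row("p1", "2009-08-01", 150),
    meas_row("p1", "2009-10-01", 170),
    meas_row("p1", "2010-01-11", 80),    # induction: excluded
    meas_row("p1", "2010-03-01", 100), meas_row("p1", "2010-05-01", 110),
    meas_row("p1", "2010-04-01", 500, setting = "inpatient"),  # excluded
    meas_row("p1", "2010-04-02", 500, concept = "SBP"))        # excluded
  ehr <- ehr_fix(persons, ex, meas)
  windows <- build_windows(ehr, "drugx")
  med <- period_medians(ehr, windows, "LDL-C", "p1")
  expect_equal(med$baseline, 150)   # median of 130/150/170
  expect_equal(med$treatment, 105)  # median of 100/110 only
})

test_that("outlier removal uses 1.5 IQR fences per period", {
  set.seed(7)
  base <- round(rnorm(20, 100, 3), 1)
  med <- data.frame(person_id = sprintf("p%02d", 1:21),
                    baseline = c(base, 500),
                    treatment = c(base - 5, 90),
                    stringsAsFactors = FALSE)
  out <- remove_outliers(med)
  # hand-computed fence for the baseline column
  q <- quantile(med$baseline, c(0.25, 0.75), type = 7, names = FALSE)
  hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_true(500 > hi)
  expect_equal(out$dropped, "p21")
  expect_equal(nrow(out$kept), 20L)

  # degenerate: all equal medians, fences collapse, nobody dropped
  same <- data.frame(person_id = sprintf("p%d", 1:6), baseline = 100,
                     treatment = 95)
  expect_equal(nrow(remove_outliers(same)$kept), 6L)

  # cohorts below 4 are returned unchanged with a warning
  expect_warning(tiny <- remove_outliers(med[1:3, ]), "skipped")
  expect_equal(nrow(tiny$kept), 3L)
})

test_that("Elixhauser index counts categories by prefix up to the
           as-of date", {
  map <- default_elixhauser_map()
  none <- elixhauser_index(character(), as.Date(character()),
                           as.Date("2009-01-01"), as.Date("2010-01-01"),
                           map)
  expect_equal(none$index, 0)

  codes <- c("428.0", "I50.9", "250.00", "V99")
  dates <- as.Date(c("2009-05-01", "2009-06-01", "2009-07-01",
                     "2009-08-01"))
  two <- elixhauser_index(codes, dates, as.Date("2009-01-01"),
                          as.Date("2010-01-01"), map)
  expect_equal(two$index, 2)  # chf (twice) + diabetes; V99 unmapped
  expect_setequal(two$categories, c("chf", "diabetes"))

  # nondecreasing in the as-of date
  early <- elixhauser_index(codes, dates, as.Date("2009-01-01"),
                            as.Date("2009-05-15"), map)
  expect_lte(early$index, two$index)

  # weighted variant
  wts <- c(chf = 7, diabetes = 0.5)
  wtd <- elixhauser_index(codes, dates, as.Date("2009-01-01"),
                          as.Date("2010-01-01"), map, weights = wts)
  expect_equal(wtd$index, 7.5)

  expect_error(elixhauser_index(codes, dates, dates[1], dates[2],
                                data.frame()), "config")
})

test_that("model table has two normalised rows per person in period
           order", {
  ehr <- gen_ehr(sim_config(45, n_persons = 25),
                 data.frame(ingredient = "drugx", delta = -10))
  windows <- build_windows(ehr, "drugx")
  exc <- apply_exclusions(ehr, windows, "approvedstatin", "drugx",
                          "LDL-C")
  med <- period_medians(ehr, windows, "LDL-C", exc$retained)
  tab <- assemble_model_table(ehr, windows, med,
                              default_elixhauser_map())
  expect_equal(nrow(tab), 2L * length(exc$retained))
  expect_equal(as.integer(table(tab$person_id)),
               rep(2L, length(exc$retained)))
  expect_equal(mean(tab$Age), 0, tolerance = 1e-9)
  expect_equal(sd(tab$Age), 1, tolerance = 1e-9)
  expect_equal(mean(tab$Comorbidity), 0, tolerance = 1e-9)
  # exposure flag matches the period
  expect_true(all(tab$drugExposure[tab$period == "baseline"] == 0))
  expect_true(all(tab$drugExposure[tab$period == "treatment"] == 1))
  # raw age advances from baseline to treatment for every person
  b <- tab[tab$period == "baseline", ]
  t <- tab[tab$period == "treatment", ]
  expect_true(all(t$age_raw[match(b$person_id, t$person_id)] >
                    b$age_raw))
  # comorbidity never decreases over the observation period
  expect_true(all(t$comorbidity_raw[match(b$person_id, t$person_id)] >=
                    b$comorbidity_raw))
})
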