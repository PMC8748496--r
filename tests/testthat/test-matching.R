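# signature fixture holding the given named scores verbatim
make_sig <- function(scores) {
  suppressWarnings(select_topk(
    deg_fix(names(scores), unname(scores), rep(0.01, length(scores))),
    k = length(scores), disease = "fix"))
}

test_that("pearson_match recovers exact reversal, mimicry and the
           direct-formula values", {
  s <- c(g1 = 2, g2 = 1, g3 = -1, g4 = -2)
  sig <- make_sig(s)
  expect_equal(pearson_match(sig, drug_signature("rev", -s))$r, -1)
  expect_equal(pearson_match(sig, drug_signature("mim", s))$r, 1)
  # |r| = 1 is flagged degenerate with a machine-epsilon p floor
  m <- pearson_match(sig, drug_signature("rev", -s))
  expect_equal(m$flag, "degenerate")
  expect_gt(m$p, 0)

  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(10); names(x) <- sprintf("g%02d", 1:10)
    y <- rnorm(10); names(y) <- names(x)
    m <- pearson_match(make_sig(x), drug_signature("d", y))
    ref <- pearson_brute(x, y)
    expect_equal(m$r, ref$r, tolerance = 1e-12)
    expect_equal(m$p, ref$p, tolerance = 1e-12)
    expect_equal(m$n_overlap, 10L)
    # weighted variant against the explicit weighted sums
    w <- runif(10, 0.1, 2); names(w) <- names(x)
    mw <- pearson_match(make_sig(x), drug_signature("d", y), weights = w)
    refw <- pearson_brute(x, y, w)
    expect_equal(mw$r, refw$r, tolerance = 1e-12)
  }
})

test_that("pearson_match flags insufficient overlap instead of failing", {
  sig <- make_sig(c(a = 1, b = -1, c = 2))
  m2 <- pearson_match(sig, drug_signature("d", c(a = 1, b = 2)))
  expect_equal(m2$flag, "insufficient-overlap")
  expect_false(is.na(m2$r))
  expect_true(is.na(m2$p))
  m1 <- pearson_match(sig, drug_signature("d", c(a = 1, zz = 2)))
  expect_equal(m1$flag, "undefined")
  expect_true(is.na(m1$r))
})

test_that("correlation is antisymmetric under negation and invariant to
           positive affine rescaling", {
  set.seed(9)
  x <- rnorm(30); names(x) <- sprintf("g%02d", 1:30)
  sig <- make_sig(x)
  y <- rnorm(30); names(y) <- names(x)
  m_pos <- pearson_match(sig, drug_signature("d", y))
  m_neg <- pearson_match(sig, drug_signature("d", -y))
  expect_equal(m_pos$r, -m_neg$r)
  m_scaled <- pearson_match(sig, drug_signature("d", 3.7 * y + 11))
  expect_equal(m_scaled$r, m_pos$r, tolerance = 1e-12)
})

test_that("screen retention is controlled at the null and monotone in
           alpha", {
  set.seed(31)
  x <- rnorm(100); names(x) <- sprintf("g%03d", 1:100)
  sig <- make_sig(x)
  lib <- lapply(sprintf("null%04d", 1:2000), function(d) {
    v <- rnorm(100); names(v) <- names(x)
    drug_signature(d, v)
  })
  names(lib) <- sprintf("null%04d", 1:2000)
  scr <- screen_library(sig, lib, alpha = 0.05)
  # two-sided p < alpha rate near alpha (3 binomial SE)
  frac_sig <- mean(scr$all$p < 0.05)
  expect_lt(abs(frac_sig - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # retained (negative side only) near alpha / 2
  frac_ret <- nrow(scr$retained) / 2000
  expect_lt(abs(frac_ret - 0.025), 3 * sqrt(0.025 * 0.975 / 2000))
  expect_true(all(scr$retained$r < 0))
  expect_equal(scr$retained$r, sort(scr$retained$r))
  # monotone non-increasing retention as alpha tightens
  n_prev <- Inf
  for (a in c(0.05, 0.01, 0.001)) {
    n_a <- nrow(screen_library(sig, lib, alpha = a)$retained)
    expect_lte(n_a, n_prev)
    n_prev <- n_a
  }
  expect_equal(nrow(screen_library(sig, lib, alpha = 1e-6)$retained), 0L)
})

test_that("candidate lists merge by union with best-r provenance", {
  row <- function(drug, r, method)
    data.frame(drug = drug, r = r, p = 0.01, n_overlap = 100,
               signature_method = method, flag = "ok",
               stringsAsFactors = FALSE)
  a <- rbind(row("A", -0.5, "topK"), row("B", -0.4, "topK"))
  b <- rbind(row("B", -0.6, "fdr"), row("C", -0.3, "fdr"))
  comb <- combine_candidates(a, b)
  expect_setequal(comb$drug, c("A", "B", "C"))
  expect_equal(comb$methods[comb$drug == "B"], "fdr+topK")
  expect_equal(comb$r[comb$drug == "B"], -0.6)  # best of -0.4 / -0.6
  expect_equal(comb$methods[comb$drug == "A"], "topK")

  # one empty list leaves the other unchanged
  empty <- a[0, ]
  solo <- combine_candidates(a, empty)
  expect_setequal(solo$drug, a$drug)

  # mismatched disease labels refuse to merge
  attr(a, "disease") <- "x"; attr(b, "disease") <- "y"
  expect_error(combine_candidates(a, b), "different diseases")
})

test_that("ingredient mapping collapses salts and drops OTC and
           unmapped drugs", {
  cands <- combine_candidates(
    data.frame(drug = c("drug-a hcl", "drug-a tartrate", "drug-b",
                        "mystery"),
               r = c(-0.5, -0.7, -0.4, -0.9), p = 0.001, n_overlap = 100,
               signature_method = "topK", flag = "ok",
               stringsAsFactors = FALSE),
    data.frame(drug = character(), r = numeric(), p = numeric(),
               n_overlap = integer(), signature_method = character(),
               flag = character(), stringsAsFactors = FALSE))
  imap <- data.frame(
    drug = c("drug-a hcl", "drug-a tartrate", "drug-b"),
    ingredient = c("druga", "druga", "drugb"),
    prescription = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  expect_message(out <- filter_candidates(cands, imap), "unmapped")
  expect_equal(out$ingredient, "druga")   # salts collapsed, OTC removed
  expect_equal(out$r, -0.7)               # best formulation kept
  expect_equal(attr(out, "unmapped"), "mystery")
  keep_otc <- filter_candidates(cands, imap, prescription_only = FALSE)
  expect_setequal(keep_otc$ingredient, c("druga", "drugb"))
  expect_error(filter_candidates(cands, imap[, 1:2]), "schema")
})
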