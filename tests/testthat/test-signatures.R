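test_that("DEG tables read, validate and collapse duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tzscore\tpvalue",
               "A\t2.1\t0.01", "B\t-1.5\t0.2", "C\t0.3\t0.9"), f)
  degs <- read_deg_table(f)
  expect_s3_class(degs, "deg_table")
  expect_equal(nrow(degs), 3L)
  expect_setequal(degs$gene, c("A", "B", "C"))

  # duplicate gene: most significant record wins
  writeLines(c("gene\tzscore\tpvalue",
               "G\t2.0\t0.5", "G\t1.0\t0.01", "H\t-1\t0.3"), f)
  expect_message(degs <- read_deg_table(f), "collapsed")
  expect_equal(nrow(degs), 2L)
  expect_equal(degs$pvalue[degs$gene == "G"], 0.01)

  # schema and parse errors
  writeLines(c("gene\tpvalue", "A\t0.1"), f)
  expect_error(read_deg_table(f), "schema")
  writeLines(c("gene\tzscore\tpvalue", "A\tx\t0.1"), f)
  expect_error(read_deg_table(f), "parse")

  # custom column names resolve through the map
  writeLines(c("sym,z,p", "A,1.2,0.2"), f)
  f2 <- sub("\\.tsv$", ".csv", f)
  file.rename(f, f2)
  degs <- read_deg_table(f2, c(gene = "sym", zscore = "z", pvalue = "p"))
  expect_equal(degs$zscore, 1.2)
})

test_that("top-K selection takes the K most extreme genes per side", {
  degs <- deg_fix(LETTERS[1:6], c(3.1, 2.0, 0.5, -0.4, -1.9, -3.3),
                  rep(0.01, 6))
  sig <- select_topk(degs, k = 2)
  up <- sig$entries$gene[sig$entries$direction == "up"]
  down <- sig$entries$gene[sig$entries$direction == "down"]
  expect_setequal(up, c("A", "B"))
  expect_setequal(down, c("F", "E"))
  # entries sorted by descending score
  expect_equal(sig$entries$score, sort(sig$entries$score,
                                       decreasing = TRUE))

  # K exceeding both tails takes only same-signed genes, one warning
  # per depleted side
  w <- capture_warnings(sig_all <- select_topk(degs, k = 10))
  expect_length(w, 2L)
  expect_match(w, "available", all = TRUE)
  expect_equal(sum(sig_all$entries$direction == "up"), 3L)
  expect_equal(sum(sig_all$entries$direction == "down"), 3L)

  # ties in Z resolved by ascending p then symbol
  degs_tie <- deg_fix(c("B2", "A1", "C3", "D", "E"),
                      c(2, 2, 2, -1, -2), c(0.05, 0.05, 0.01, 0.1, 0.1))
  sig_tie <- select_topk(degs_tie, k = 2)
  up <- sig_tie$entries$gene[sig_tie$entries$direction == "up"]
  expect_equal(sort(up), c("A1", "C3"))  # C3 by p, A1 by symbol

  expect_error(select_topk(deg_fix(character(), numeric(), numeric())),
               "empty")
})

test_that("top-K signature size follows min(K, tail count) per side", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    degs <- deg_fix(sprintf("g%03d", 1:n), rnorm(n), runif(n))
    k <- sample(1:60, 1)
    sig <- suppressWarnings(select_topk(degs, k = k))
    expected <- min(k, sum(degs$zscore > 0)) + min(k, sum(degs$zscore < 0))
    expect_equal(nrow(sig$entries), expected)
    expect_lte(nrow(sig$entries), 2 * k)
    # every signature gene exists in the table with matching sign
    idx <- match(sig$entries$gene, degs$gene)
    expect_false(anyNA(idx))
    expect_equal(sign(degs$zscore[idx]), sign(sig$entries$score))
  }
})

test_that("FDR selection applies Benjamini-Hochberg at the q cutoff", {
  degs <- deg_fix(c("a", "b", "c", "d"), c(1, 2, -3, 0.5),
                  c(0.001, 0.01, 0.02, 0.8))
  # hand-computed BH q-values: 0.004, 0.02, 0.0267, 0.8
  sig <- select_fdr(degs, q = 0.05)
  expect_setequal(sig$entries$gene, c("a", "b", "c"))
  expect_equal(sig$entries$direction[sig$entries$gene == "c"], "down")

  # nothing significant
  degs1 <- deg_fix(c("a", "b"), c(1, -1), c(1, 1))
  expect_equal(nrow(select_fdr(degs1, 0.05)$entries), 0L)

  # default threshold is 0.05
  expect_equal(formals(select_fdr)$q, 0.05)

  # directionless Z = 0 genes excluded with warning
  degs0 <- deg_fix(c("a", "b"), c(0, 2), c(0.001, 0.001))
  expect_warning(sig0 <- select_fdr(degs0, 0.05), "Z = 0")
  expect_equal(sig0$entries$gene, "b")
})

test_that("FDR selection is monotone in q", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    degs <- deg_fix(sprintf("g%03d", 1:n), rnorm(n),
                    pmin(runif(n)^2 + 1e-6, 1))
    qs <- sort(runif(3, 0.01, 0.5))
    sets <- lapply(qs, function(q) select_fdr(degs, q)$entries$gene)
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("signature files round-trip exactly", {
  degs <- gen_deg_table(sim_config(3))$degs
  sig <- select_topk(degs, k = 50, disease = "demo")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$entries, sig$entries)
  expect_equal(back$disease, sig$disease)
  expect_equal(back$method, sig$method)
  expect_equal(back$params$K, 50)

  # duplicate gene rejected
  writeLines(c("# disease: d", "# method: topK", "# params: K=2",
               "gene\tscore\tdirection", "A\t1\tup", "A\t2\tup"), f)
  expect_error(read_signature(f), "duplicate")

  # header-only file: empty signature with a warning
  writeLines(c("# disease: d", "# method: fdr", "# params: q=0.05",
               "gene\tscore\tdirection"), f)
  expect_warning(empty <- read_signature(f), "empty")
  expect_equal(nrow(empty$entries), 0L)
})
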