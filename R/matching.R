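# Reversal screening: score every drug perturbation signature in a
# library against a disease signature with a (weighted) Pearson
# correlation over the shared genes. A reverser has r < 0 at the
# configured alpha.

#' Construct a drug perturbation signature
#'
#' @param drug Drug identifier.
#' @param values Named numeric vector: gene symbol -> signed
#'   differential-expression value. Gene symbols are uppercased for
#'   matching; values must be finite.
#' @param source Library tag (e.g. `"drugmatrix-like"`, `"lincs-like"`).
#' @return An object of class `drug_signature`.
#' @export
drug_signature <- function(drug, values, source = "library") {
  stopifnot(is.character(drug), length(drug) == 1L,
            is.numeric(values), !is.null(names(values)))
  names(values) <- toupper(names(values))
  if (anyDuplicated(names(values)))
    stop("drug signature invariant: duplicate gene keys for ", drug,
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("drug signature invariant: non-finite values for ", drug,
         call. = FALSE)
  structure(list(drug = drug, values = values, source = source),
            class = "drug_signature")
}

#' Read a drug-perturbation library
#'
#' Accepts either a long table with columns `drug`, `gene`, `value`
#' (TSV) or a wide matrix (CSV/TSV; first column gene symbols, one
#' column per drug). The layout is auto-detected from the header.
#'
#' @param path File path.
#' @param source Library tag stored on each signature.
#' @return A named list of [drug_signature()] objects.
#' @export
read_drug_library <- function(path, source = "library") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("drug", "gene", "value") %in% names(tab))) {
    split_vals <- split(tab[, c("gene", "value")], tab$drug)
    lib <- lapply(names(split_vals), function(d) {
      v <- split_vals[[d]]
      drug_signature(d, stats::setNames(v$value, v$gene), source)
    })
    names(lib) <- names(split_vals)
  } else {
    genes <- as.character(tab[[1L]])
    lib <- lapply(names(tab)[-1L], function(d)
      drug_signature(d, stats::setNames(tab[[d]], genes), source))
    names(lib) <- names(tab)[-1L]
  }
  lib
}

#' Weighted Pearson correlation of disease and drug signatures
#'
#' Computes the (optionally weighted) Pearson correlation between the
#' disease signature scores and the drug perturbation values over the
#' intersection of their gene sets (exact symbol match after uppercase
#' normalisation). The two-tailed p-value comes from the t-transform
#' `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of freedom and
#' requires at least 3 overlapping genes. Degenerate |r| = 1 cases are
#' reported with `p = .Machine$double.eps` and `degenerate = TRUE` so
#' downstream -log10 displays stay finite.
#'
#' @param disease A [select_topk()]/[select_fdr()] signature.
#' @param drug A [drug_signature()].
#' @param weights Optional named non-negative gene weights (e.g. |Z|);
#'   unnamed genes default to weight 1. `NULL` gives plain Pearson.
#' @return A list of class `match_result` with fields `drug`, `r`, `p`,
#'   `n_overlap`, `signature_method`, `flag` (`"ok"`,
#'   `"insufficient-overlap"`, `"undefined"` or `"degenerate"`).
#' @export
pearson_match <- function(disease, drug, weights = NULL) {
  stopifnot(inherits(disease, "disease_signature"),
            inherits(drug, "drug_signature"))
  ds <- signature_scores(disease)
  names(ds) <- toupper(names(ds))
  shared <- intersect(names(ds), names(drug$values))
  n <- length(shared)
  res <- list(drug = drug$drug, r = NA_real_, p = NA_real_, n_overlap = n,
              signature_method = disease$method, flag = "ok")
  class(res) <- "match_result"
  if (n < 2L) { res$flag <- "undefined"; return(res) }
  x <- ds[shared]; y <- drug$values[shared]
  w <- rep(1, n)
  if (!is.null(weights)) {
    stopifnot(all(weights >= 0))
    hit <- shared %in% toupper(names(weights))
    w[hit] <- weights[match(shared[hit], toupper(names(weights)))]
  }
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) { res$flag <- "undefined"; return(res) }
  r <- cxy / sqrt(cxx * cyy)
  res$r <- max(-1, min(1, r))
  if (n < 3L) { res$flag <- "insufficient-overlap"; return(res) }
  if (abs(res$r) >= 1) {
    res$p <- .Machine$double.eps
    res$flag <- "degenerate"
  } else {
    tstat <- res$r * sqrt((n - 2) / (1 - res$r^2))
    res$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    if (res$p == 0) { res$p <- .Machine$double.eps; res$flag <- "degenerate" }
  }
  res
}

#' Screen a perturbation library for signature reversal
#'
#' Scores every drug in the library against the disease signature and
#' retains the reversers: drugs with `r < 0` and `p < alpha`. Retained
#' results are sorted by ascending r (strongest reversal first). Drugs
#' with insufficient gene overlap are reported separately, not silently
#' dropped.
#'
#' @param disease A `disease_signature`.
#' @param library List of `drug_signature` objects.
#' @param alpha Screening significance threshold (0.05 or 0.001 in the
#'   shipped disease configurations).
#' @param weights Optional gene weights passed to [pearson_match()].
#' @return List with elements `retained` (data frame: drug, r, p,
#'   n_overlap, signature_method), `all` (every scored drug) and
#'   `skipped` (drugs with undefined or overlap-limited results).
#' @export
screen_library <- function(disease, library, alpha = 0.05, weights = NULL) {
  stopifnot(length(library) > 0L, alpha > 0, alpha <= 1)
  results <- lapply(library, pearson_match, disease = disease,
                    weights = weights)
  to_row <- function(m)
    data.frame(drug = m$drug, r = m$r, p = m$p, n_overlap = m$n_overlap,
               signature_method = m$signature_method, flag = m$flag,
               stringsAsFactors = FALSE)
  all_df <- do.call(rbind, lapply(results, to_row))
  rownames(all_df) <- NULL
  scored <- all_df[!is.na(all_df$p), ]
  retained <- scored[scored$r < 0 & scored$p < alpha, ]
  retained <- retained[order(retained$r, retained$drug), ]
  rownames(retained) <- NULL
  skipped <- all_df[is.na(all_df$p), ]
  rownames(skipped) <- NULL
  attr(retained, "disease") <- disease$disease
  list(retained = retained, all = all_df, skipped = skipped)
}

#' Combine candidate lists from the two signature-selection rules
#'
#' Takes the retained reversers screened against the top-K signature and
#' against the FDR signature for the same disease and merges them by
#' drug id. The representative correlation is the best (most negative)
#' r across the two routes, and per-drug provenance records which
#' method(s) selected the drug.
#'
#' @param list_topk,list_fdr `retained` data frames from
#'   [screen_library()] (or the full screen result lists).
#' @param disease Disease label for the combined list; when both inputs
#'   carry the same label it may be omitted.
#' @return A `candidate_list`: data frame with columns `drug`, `r`, `p`,
#'   `n_overlap`, `methods`, sorted by ascending r, plus attribute
#'   `disease`.
#' @export
combine_candidates <- function(list_topk, list_fdr, disease = NULL) {
  get_df <- function(x) if (is.data.frame(x)) x else x$retained
  a <- get_df(list_topk); b <- get_df(list_fdr)
  lab_a <- attr(a, "disease"); lab_b <- attr(b, "disease")
  if (!is.null(lab_a) && !is.null(lab_b) && !identical(lab_a, lab_b))
    stop("candidate lists are for different diseases: ", lab_a, " vs ",
         lab_b, call. = FALSE)
  if (is.null(disease)) disease <- if (!is.null(lab_a)) lab_a else lab_b
  both <- rbind(a, b)
  if (nrow(both) == 0L) {
    out <- data.frame(drug = character(), r = numeric(), p = numeric(),
                      n_overlap = integer(), methods = character(),
                      stringsAsFactors = FALSE)
  } else {
    # representative record per drug: most negative r
    both <- both[order(both$drug, both$r, both$p), ]
    methods <- tapply(both$signature_method, both$drug,
                      function(m) paste(sort(unique(m)), collapse = "+"))
    out <- both[!duplicated(both$drug), ]
    out$methods <- as.character(methods[out$drug])
    out <- out[order(out$r, out$drug),
               c("drug", "r", "p", "n_overlap", "methods")]
    rownames(out) <- NULL
  }
  attr(out, "disease") <- disease
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Map candidates to ingredients and apply the prescription filter
#'
#' Maps library drug names to bioactive ingredients through a reference
#' table; drugs without a mapping are dropped (and reported), salts or
#' formulations mapping to the same ingredient are collapsed (keeping
#' the best r), and non-prescription ingredients are removed when
#' `prescription_only` is set.
#'
#' @param cands A `candidate_list`.
#' @param ingredient_map Data frame with columns `drug`, `ingredient`,
#'   `prescription` (logical or 0/1).
#' @param prescription_only Drop non-prescription ingredients (default
#'   `TRUE`).
#' @return A `candidate_list` with an `ingredient` column; attribute
#'   `unmapped` lists dropped drug names.
#' @export
filter_candidates <- function(cands, ingredient_map,
                              prescription_only = TRUE) {
  need <- c("drug", "ingredient", "prescription")
  if (!is.data.frame(ingredient_map) || !all(need %in% names(ingredient_map)))
    stop("ingredient map schema error: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  idx <- match(cands$drug, ingredient_map$drug)
  unmapped <- cands$drug[is.na(idx)]
  if (length(unmapped))
    message(length(unmapped), " unmapped candidate(s) dropped: ",
            paste(unmapped, collapse = ", "))
  out <- cands[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  out$ingredient <- ingredient_map$ingredient[idx]
  out$prescription <- as.logical(ingredient_map$prescription[idx])
  if (prescription_only) out <- out[out$prescription, , drop = FALSE]
  # collapse formulations of the same ingredient, keep strongest reversal
  out <- out[order(out$ingredient, out$r, out$p), ]
  out <- out[!duplicated(out$ingredient), ]
  out <- out[order(out$r, out$drug), ]
  rownames(out) <- NULL
  attr(out, "disease") <- attr(cands, "disease")
  attr(out, "unmapped") <- unmapped
  class(out) <- c("candidate_list", "data.frame")
  out
}
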