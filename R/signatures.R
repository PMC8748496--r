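# Disease gene-expression signatures from imputed DEG tables.
#
# A DEG table holds one row per gene with a genetically imputed
# association Z-score and two-tailed p-value (the schema produced by
# transcriptome-wide association imputation tools). Two selection rules
# turn a table into a disease signature: the top-K most up- and
# downregulated genes, or Benjamini-Hochberg FDR selection.

#' Read a differentially-expressed-gene (DEG) table
#'
#' Reads a delimited table of per-gene imputed differential-expression
#' records (gene symbol, association Z-score, two-tailed p-value).
#' Duplicate gene symbols are collapsed by keeping the record with the
#' smallest p-value; the number of collapsed records is reported via
#' `message()`.
#'
#' @param path Path to a TSV or CSV file with a header row. The
#'   delimiter is chosen by file extension (`.csv` is comma-separated,
#'   anything else tab-separated).
#' @param column_map Named character vector mapping the canonical names
#'   `gene`, `zscore`, `pvalue` to the column names used in the file.
#' @return A `data.frame` of class `deg_table` with columns `gene`
#'   (character), `zscore` (numeric, finite) and `pvalue` (numeric in
#'   (0, 1]); gene symbols are unique.
#' @export
read_deg_table <- function(path,
                           column_map = c(gene = "gene", zscore = "zscore",
                                          pvalue = "pvalue")) {
  stopifnot(length(path) == 1L, file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("gene", "zscore", "pvalue")
  map <- column_map[needed]
  if (anyNA(map) || !all(map %in% names(raw))) {
    missing <- map[is.na(map) | !(map %in% names(raw))]
    stop("DEG table schema error: cannot resolve column(s) ",
         paste(needed[is.na(map) | !(map %in% names(raw))], collapse = ", "),
         " in ", path, call. = FALSE)
  }
  degs <- data.frame(gene = as.character(raw[[map[["gene"]]]]),
                     zscore = raw[[map[["zscore"]]]],
                     pvalue = raw[[map[["pvalue"]]]],
                     stringsAsFactors = FALSE)
  for (col in c("zscore", "pvalue")) {
    if (!is.numeric(degs[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(degs[[col]]))))[1L]
      stop("DEG table parse error: non-numeric ", col, " at data row ",
           bad, call. = FALSE)
    }
  }
  as_deg_table(degs)
}

#' Construct a validated DEG table from a data frame
#'
#' @param degs Data frame with columns `gene`, `zscore`, `pvalue`.
#' @return A `deg_table`; duplicate genes collapsed keeping minimum p.
#' @export
as_deg_table <- function(degs) {
  stopifnot(is.data.frame(degs),
            all(c("gene", "zscore", "pvalue") %in% names(degs)))
  degs <- degs[, c("gene", "zscore", "pvalue")]
  degs$gene <- as.character(degs$gene)
  if (any(!nzchar(degs$gene)) || anyNA(degs$gene))
    stop("DEG table invariant: empty gene symbol", call. = FALSE)
  if (any(!is.finite(degs$zscore)))
    stop("DEG table invariant: non-finite Z-score", call. = FALSE)
  if (any(is.na(degs$pvalue) | degs$pvalue <= 0 | degs$pvalue > 1))
    stop("DEG table invariant: p-value outside (0, 1]", call. = FALSE)
  if (anyDuplicated(degs$gene)) {
    n0 <- nrow(degs)
    # keep the most significant record per gene
    degs <- degs[order(degs$gene, degs$pvalue), ]
    degs <- degs[!duplicated(degs$gene), ]
    message(n0 - nrow(degs), " duplicate gene record(s) collapsed ",
            "(kept minimum p-value)")
  }
  rownames(degs) <- NULL
  class(degs) <- c("deg_table", "data.frame")
  degs
}

new_signature <- function(disease, method, entries, params) {
  stopifnot(!anyDuplicated(entries$gene))
  entries <- entries[order(-entries$score, entries$gene), ]
  rownames(entries) <- NULL
  structure(list(disease = disease, method = method,
                 entries = entries, params = params),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("Disease signature:", x$disease, "\n")
  cat("  method:", x$method, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")\n")
  cat("  genes:", nrow(x$entries),
      sprintf("(%d up, %d down)\n", sum(x$entries$direction == "up"),
              sum(x$entries$direction == "down")))
  invisible(x)
}

#' Signature scores as a named vector
#'
#' @param sig A `disease_signature`.
#' @return Named numeric vector of signed scores, names are gene symbols.
#' @export
signature_scores <- function(sig) {
  stopifnot(inherits(sig, "disease_signature"))
  stats::setNames(sig$entries$score, sig$entries$gene)
}

#' Top-K up- and downregulated signature selection
#'
#' Selects the `k` genes with the largest positive Z-scores (direction
#' "up") and the `k` genes with the most negative Z-scores (direction
#' "down"), for a signature of up to `2k` genes. Only genes with
#' strictly positive (resp. negative) Z qualify for each side; if fewer
#' than `k` are available a warning is issued and all qualifying genes
#' are taken. Ties in Z are broken by ascending p-value, then gene
#' symbol, so output is deterministic.
#'
#' @param degs A `deg_table`.
#' @param k Genes to take on each side (default 50, i.e. a 100-gene
#'   signature when both tails are full).
#' @param disease Label stored with the signature.
#' @param restrict_to Optional character vector of gene symbols; the
#'   table is intersected with it before selection (used when the
#'   signature should be restricted to a curated causal-gene list).
#' @return A `disease_signature` with `method = "topK"`.
#' @export
select_topk <- function(degs, k = 50, disease = "disease",
                        restrict_to = NULL) {
  stopifnot(inherits(degs, "deg_table"), k >= 1)
  if (!is.null(restrict_to)) degs <- degs[degs$gene %in% restrict_to, ]
  if (nrow(degs) == 0L) stop("empty DEG table", call. = FALSE)
  zero <- degs$zscore == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with Z = 0 carry no direction; excluded")
    degs <- degs[!zero, ]
  }
  take <- function(side) {
    pool <- if (side == "up") degs[degs$zscore > 0, ]
            else degs[degs$zscore < 0, ]
    # most extreme first: descending |Z|, ties by ascending p then symbol
    ord <- order(-abs(pool$zscore), pool$pvalue, pool$gene)
    pool <- pool[ord, ]
    if (nrow(pool) < k)
      warning("only ", nrow(pool), " gene(s) with ",
              if (side == "up") "Z > 0" else "Z < 0",
              " available for k = ", k)
    utils::head(pool, k)
  }
  up <- take("up"); down <- take("down")
  entries <- data.frame(
    gene = c(up$gene, down$gene),
    score = c(up$zscore, down$zscore),
    direction = rep(c("up", "down"), c(nrow(up), nrow(down))),
    stringsAsFactors = FALSE)
  new_signature(disease, "topK", entries, list(K = k))
}

#' FDR-based signature selection
#'
#' Computes Benjamini-Hochberg adjusted q-values over every gene in the
#' table and retains genes with q-value strictly below `q`; direction is
#' the sign of the Z-score. Genes with Z = 0 are excluded with a warning
#' because they carry no direction.
#'
#' @param degs A `deg_table`.
#' @param q FDR threshold in (0, 1); default 0.05.
#' @param disease Label stored with the signature.
#' @param restrict_to Optional gene list applied before selection.
#' @return A `disease_signature` with `method = "fdr"`.
#' @export
select_fdr <- function(degs, q = 0.05, disease = "disease",
                       restrict_to = NULL) {
  stopifnot(inherits(degs, "deg_table"), q > 0, q < 1)
  if (!is.null(restrict_to)) degs <- degs[degs$gene %in% restrict_to, ]
  if (nrow(degs) == 0L) stop("empty DEG table", call. = FALSE)
  qval <- stats::p.adjust(degs$pvalue, method = "BH")
  keep <- qval < q
  if (any(keep & degs$zscore == 0)) {
    warning(sum(keep & degs$zscore == 0),
            " significant gene(s) with Z = 0 carry no direction; excluded")
  }
  keep <- keep & degs$zscore != 0
  entries <- data.frame(
    gene = degs$gene[keep],
    score = degs$zscore[keep],
    direction = ifelse(degs$zscore[keep] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  new_signature(disease, "fdr", entries, list(q = q))
}

#' Write a disease signature to a TSV file
#'
#' The file carries `#`-prefixed metadata lines (disease, method,
#' parameters) followed by a header and one row per gene with columns
#' `gene`, `score`, `direction`. [read_signature()] inverts it.
#'
#' @param sig A `disease_signature`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "disease_signature"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# disease: ", sig$disease),
               paste0("# method: ", sig$method),
               paste0("# params: ", paste(names(sig$params),
                                          unlist(sig$params),
                                          sep = "=", collapse = ";"))),
             con)
  utils::write.table(sig$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", hit[1L])
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L) stop("signature parse error: no header", call. = FALSE)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "character"))
  if (!identical(names(tab), c("gene", "score", "direction")))
    stop("signature parse error: expected columns gene, score, direction",
         call. = FALSE)
  if (anyDuplicated(tab$gene))
    stop("signature validation error: duplicate gene", call. = FALSE)
  if (nrow(tab) > 0 && !all((tab$score > 0) == (tab$direction == "up")))
    stop("signature validation error: direction inconsistent with score sign",
         call. = FALSE)
  if (nrow(tab) == 0L) warning("empty signature file: ", path)
  params <- strsplit(get("params"), ";")[[1]]
  pl <- list()
  for (kv in params) {
    parts <- strsplit(kv, "=")[[1]]
    val <- suppressWarnings(as.numeric(parts[2]))
    pl[[parts[1]]] <- if (is.na(val)) parts[2] else val
  }
  new_signature(get("disease"), get("method"), tab, pl)
}
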