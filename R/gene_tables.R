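#' Construct a GeneTable
#'
#' A `GeneTable` holds one dataset's differential-expression results: one row
#' per gene symbol with a log2 fold change and optional (adjusted) p-values.
#' Gene symbols must be unique and non-empty, and every logFC finite; use
#' [read_gene_table()] to load and deduplicate raw files.
#'
#' @param name Dataset label.
#' @param gene Character vector of gene symbols (unique, non-empty).
#' @param logFC Numeric vector of log2 fold changes (finite).
#' @param pval Optional numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param adj_pval Optional numeric vector of adjusted p-values in `[0, 1]`.
#' @return An object of class `GeneTable`: a list with elements `name` and
#'   `data` (a data.frame with columns `gene`, `logFC`, `pval`, `adj_pval`).
#' @export
gene_table <- function(name, gene, logFC, pval = NULL, adj_pval = NULL) {
  gene <- as.character(gene)
  logFC <- as.numeric(logFC)
  n <- length(gene)
  if (length(logFC) != n)
    stop("`gene` and `logFC` must have the same length", call. = FALSE)
  if (is.null(pval)) pval <- rep(NA_real_, n)
  if (is.null(adj_pval)) adj_pval <- rep(NA_real_, n)
  obj <- structure(
    list(name = as.character(name)[1],
         data = data.frame(gene = gene, logFC = logFC,
                           pval = as.numeric(pval),
                           adj_pval = as.numeric(adj_pval),
                           stringsAsFactors = FALSE)),
    class = "GeneTable")
  validate_gene_table(obj)
}

validate_gene_table <- function(x) {
  d <- x$data
  if (any(is.na(d$gene) | !nzchar(d$gene)))
    stop("gene symbols must be non-empty", call. = FALSE)
  if (anyDuplicated(d$gene))
    stop("gene symbols must be unique (deduplicate first)", call. = FALSE)
  if (any(!is.finite(d$logFC)))
    stop("every logFC must be finite", call. = FALSE)
  for (col in c("pval", "adj_pval")) {
    v <- d[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad))
      stop(sprintf("%s values must lie in [0, 1]", col), call. = FALSE)
  }
  x
}

#' @export
print.GeneTable <- function(x, ...) {
  cat(sprintf("GeneTable '%s': %d genes\n", x$name, nrow(x$data)))
  print(utils::head(x$data, 6))
  invisible(x)
}

#' Number of genes in a GeneTable
#' @param x A `GeneTable`.
#' @return Integer gene count.
#' @export
n_genes <- function(x) nrow(x$data)

#' Gene symbols of a GeneTable
#' @param x A `GeneTable`.
#' @return Character vector of symbols, in table order.
#' @export
genes <- function(x) x$data$gene

# Column-name aliases for the limma topTable dialect and common variants.
.pval_aliases <- c("P.Value", "pval", "pval.", "p.value", "PValue", "pvalue")
.adj_aliases  <- c("adj.P.Val", "adj.pval", "adj.pval.", "padj",
                   "adj.p.val", "FDR", "q.value")

.match_col <- function(cols, aliases) {
  hit <- cols[match(tolower(aliases), tolower(cols), nomatch = 0L)]
  if (length(hit)) hit[1] else NA_character_
}

# Pick the delimiter (comma, tab, semicolon) that appears most often in the
# header line; comma wins ties.
.detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", "\t", ";"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a differential-expression table from delimited text
#'
#' Reads a delimited file (comma, tab or semicolon; auto-detected) whose first
#' column holds gene symbols and whose remaining columns are numeric DE
#' statistics. P-value columns are recognised under the limma `topTable`
#' names (`P.Value`, `adj.P.Val`) and common aliases (`pval`, `padj`, `FDR`,
#' ...). Symbols are taken verbatim: no case folding is applied, since symbol
#' normalization is upstream's job and silent folding can merge distinct IDs.
#'
#' Rows with missing or non-finite score values are dropped (with a message
#' giving the count). Duplicate gene symbols are resolved by keeping the row
#' with the smallest p-value when a p-value column exists, otherwise the row
#' with the largest absolute score (first occurrence breaks exact ties).
#'
#' @param path Path to the file.
#' @param score_col Name of the numeric column used as the competing score
#'   (default `"logFC"`).
#' @param dataset_name Label for the dataset; defaults to the file name
#'   without extension.
#' @return A [gene_table()] object.
#' @export
read_gene_table <- function(path, score_col = "logFC", dataset_name = NULL) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (is.null(dataset_name))
    dataset_name <- sub("\\.[^.]*$", "", basename(path))
  delim <- .detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (ncol(df) < 2)
    stop("table must have a gene column plus at least one numeric column",
         call. = FALSE)
  if (!score_col %in% names(df)[-1])
    stop(sprintf("score column '%s' not found; available columns: %s",
                 score_col, paste(names(df)[-1], collapse = ", ")),
         call. = FALSE)
  gene <- as.character(df[[1]])
  score <- suppressWarnings(as.numeric(df[[score_col]]))

  pcol <- .match_col(names(df), .pval_aliases)
  acol <- .match_col(names(df), .adj_aliases)
  pval <- if (!is.na(pcol)) suppressWarnings(as.numeric(df[[pcol]])) else rep(NA_real_, nrow(df))
  adjp <- if (!is.na(acol)) suppressWarnings(as.numeric(df[[acol]])) else rep(NA_real_, nrow(df))

  keep <- is.finite(score) & !is.na(gene) & nzchar(gene)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("%s: dropped %d row(s) with missing/non-finite %s or empty symbol",
                    dataset_name, n_dropped, score_col))
  gene <- gene[keep]; score <- score[keep]; pval <- pval[keep]; adjp <- adjp[keep]
  if (length(gene) == 0)
    stop(sprintf("no parsable rows in %s", path), call. = FALSE)

  if (anyDuplicated(gene)) {
    has_p <- !is.na(pcol) && any(is.finite(pval))
    key <- if (has_p) {
      # smallest p-value wins; NA p-values lose to any finite one
      ifelse(is.na(pval), Inf, pval)
    } else {
      -abs(score)
    }
    ord <- order(key, seq_along(gene))  # stable: first occurrence breaks ties
    first <- ord[!duplicated(gene[ord])]
    first <- sort(first)                # keep original row order
    gene <- gene[first]; score <- score[first]
    pval <- pval[first]; adjp <- adjp[first]
  }
  gene_table(dataset_name, gene, score, pval, adjp)
}

#' Write rating results to delimited text
#'
#' Writes one table with the gene symbol in column 1 followed by
#' `<method>_score` and `<method>_rank` columns for each rating method. Rows
#' are sorted by the first method's rank (ascending), ties broken
#' lexicographically by symbol. Values round-trip at full double precision.
#'
#' @param results A list of `RatingResult` objects (see [rank_all()]), all
#'   sharing one candidate gene universe.
#' @param path Output file path; the delimiter is chosen from the extension
#'   (`.tsv`/`.txt` write tabs, anything else commas).
#' @return Invisibly, the data.frame written.
#' @export
write_ratings <- function(results, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  if (length(results) == 0) {
    warning("no rating results: writing header-only file", call. = FALSE)
    out <- data.frame(gene = character(0))
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  universe <- names(results[[1]]$scores)
  for (r in results) {
    if (!setequal(names(r$scores), universe))
      stop("all rating results must share one candidate gene universe",
           call. = FALSE)
  }
  out <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (r in results) {
    out[[paste0(r$method, "_score")]] <- unname(r$scores[universe])
    out[[paste0(r$method, "_rank")]]  <- unname(r$ranks[universe])
  }
  ord <- order(out[[paste0(results[[1]]$method, "_rank")]],
               rank_order_key(out$gene))
  out <- out[ord, , drop = FALSE]
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(out)
}

# Locale-independent (C-collation) sort key / sorted vector, so candidate
# ordering and tie-breaks do not depend on the session locale.
rank_order_key <- function(x) xtfrm(factor(x, levels = sort_c(unique(x))))

sort_c <- function(x) sort(x, method = "radix")
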