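#' Competition configuration
#'
#' Settings controlling how genes compete on log-fold change across datasets.
#'
#' @param regulation One of `"up"`, `"down"`, `"abs"`. Up-regulation: the gene
#'   with the higher logFC wins a pairwise game; down-regulation: the lower
#'   logFC wins; absolute: the larger `|logFC|` wins (two-sided mode).
#' @param strategy `"intersection"` (candidates are genes present in every
#'   dataset; the threshold is ignored) or `"union"` (candidates are genes
#'   passing the logFC filter in at least one dataset).
#' @param thres Non-negative logFC threshold used by the union filter:
#'   `logFC > thres` (up), `logFC < -thres` (down), `|logFC| > thres` (abs).
#'   Default 0.
#' @param score_col Name of the score column expected in input files.
#' @param candidate_cap Union candidate count above which a performance
#'   warning is emitted (default 10000).
#' @return An object of class `CompetitionConfig`.
#' @export
competition_config <- function(regulation = c("up", "down", "abs"),
                               strategy = c("intersection", "union"),
                               thres = 0, score_col = "logFC",
                               candidate_cap = 10000L) {
  regulation <- match.arg(regulation)
  strategy <- match.arg(strategy)
  if (!is.numeric(thres) || length(thres) != 1 || is.na(thres) || thres < 0)
    stop("`thres` must be a single non-negative number", call. = FALSE)
  structure(list(regulation = regulation, strategy = strategy,
                 thres = thres, score_col = score_col,
                 candidate_cap = as.integer(candidate_cap)),
            class = "CompetitionConfig")
}

# Score transform under which "larger wins" for every regulation mode.
.effective_score <- function(score, regulation) {
  switch(regulation, up = score, down = -score, abs = abs(score))
}

#' Pairwise win/loss matrices within one dataset
#'
#' Plays every ordered pair of genes on their scores. In up mode gene i beats
#' gene j iff `score_i >= score_j`; down mode iff `score_i <= score_j`;
#' absolute mode iff `|score_i| >= |score_j|`. An exact tie therefore credits
#' BOTH genes a win and neither a loss (the sign(sign(d)+1) construction);
#' losses are `1 - win` off the diagonal; diagonals are zero. Exact floating
#' equality defines a tie — no epsilon.
#'
#' @param scores Named numeric vector of finite scores (>= 2 genes).
#' @param regulation `"up"`, `"down"` or `"abs"`.
#' @return A list with 0/1 matrices `W` and `L` over `names(scores)`.
#' @export
compare_within_dataset <- function(scores, regulation = "up") {
  if (length(scores) < 2)
    stop("degenerate competition: need at least 2 genes", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  s <- .effective_score(as.numeric(scores), regulation)
  W <- (outer(s, s, ">=")) * 1L
  diag(W) <- 0L
  L <- 1L - W
  diag(L) <- 0L
  dimnames(W) <- dimnames(L) <- list(names(scores), names(scores))
  list(W = W, L = L)
}

#' Construct a CompetitionMatrices object directly
#'
#' Low-level constructor for hand-built competitions (oracle tests, degenerate
#' cases such as a no-games tournament). Most users should build competitions
#' from tables with [build_intersection()] or [build_union()].
#'
#' @param genes Ordered candidate gene symbols (length N).
#' @param W,L N x N win and loss count matrices (`w_ij` = matches i beat j).
#' @param n N x N symmetric games matrix; defaults to `W + L`.
#' @param per_dataset List, one entry per dataset, of named score vectors over
#'   the candidates present in that dataset (needed by [rank_elo()]).
#' @param regulation,strategy,k Competition metadata.
#' @return A validated `CompetitionMatrices` object.
#' @export
competition_matrices <- function(genes, W, L, n = W + L,
                                 per_dataset = list(),
                                 regulation = "up", strategy = "intersection",
                                 k = length(per_dataset)) {
  validate_competition(new_competition_matrices(
    genes, W, L, n, per_dataset, regulation, strategy, k))
}

new_competition_matrices <- function(genes, W, L, n, per_dataset,
                                     regulation, strategy, k) {
  dimnames(W) <- dimnames(L) <- dimnames(n) <- list(genes, genes)
  structure(list(genes = genes, W = W, L = L, n = n, Ni = rowSums(n),
                 per_dataset = per_dataset, regulation = regulation,
                 strategy = strategy, k = k),
            class = "CompetitionMatrices")
}

#' Validate a CompetitionMatrices object
#'
#' Asserts the structural invariants: zero diagonals, symmetric games matrix,
#' and `w_ij + l_ij = n_ij` with `w_ij <= n_ij` for every pair.
#'
#' @param cm A `CompetitionMatrices` object.
#' @return `cm`, invisibly, or an error.
#' @export
validate_competition <- function(cm) {
  stopifnot(inherits(cm, "CompetitionMatrices"))
  with(cm, {
    if (any(diag(W) != 0) || any(diag(L) != 0) || any(diag(n) != 0))
      stop("diagonals of W, L, n must be zero", call. = FALSE)
    if (!isTRUE(all.equal(n, t(n))))
      stop("games matrix n must be symmetric", call. = FALSE)
    if (any(W + L != n))
      stop("w_ij + l_ij must equal n_ij for every pair", call. = FALSE)
    if (any(W < 0) || any(L < 0) || any(W > n))
      stop("win/loss counts out of range", call. = FALSE)
  })
  invisible(cm)
}

#' @export
print.CompetitionMatrices <- function(x, ...) {
  cat(sprintf("CompetitionMatrices: %d candidates, %d dataset(s), %s/%s\n",
              length(x$genes), x$k, x$strategy, x$regulation))
  invisible(x)
}

#' Build competition matrices under the intersection strategy
#'
#' Candidates are the genes present in every input dataset (the conventional
#' integration). Every pair plays exactly one game per dataset, so
#' `n_ij = k` off the diagonal and `N_i = k (N - 1)`.
#'
#' @param tables List of [gene_table()] objects (>= 2; a single table is
#'   allowed with a warning, giving a k = 1 competition).
#' @param config A [competition_config()]; its `thres` is ignored here.
#' @return A `CompetitionMatrices` object.
#' @export
build_intersection <- function(tables, config = competition_config()) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1)
    warning("single input table: k = 1 competition", call. = FALSE)
  k <- length(tables)
  cand <- Reduce(intersect, lapply(tables, genes))
  if (length(cand) == 0)
    stop("empty competition: no gene is present in every dataset",
         call. = FALSE)
  cand <- sort_c(cand)
  N <- length(cand)
  W <- L <- matrix(0, N, N)
  per_dataset <- vector("list", k)
  names(per_dataset) <- vapply(tables, function(t) t$name, character(1))
  for (t in seq_len(k)) {
    s <- stats::setNames(tables[[t]]$data$logFC, tables[[t]]$data$gene)[cand]
    per_dataset[[t]] <- s
    if (N >= 2) {
      g <- compare_within_dataset(s, config$regulation)
      W <- W + g$W
      L <- L + g$L
    }
  }
  n <- matrix(k, N, N); diag(n) <- 0
  if (N < 2) warning("degenerate competition: fewer than 2 candidates",
                     call. = FALSE)
  validate_competition(new_competition_matrices(
    cand, W, L, n, per_dataset, config$regulation, "intersection", k))
}

#' Build competition matrices under the union strategy
#'
#' Candidates are the genes passing the logFC filter (`> thres` up,
#' `< -thres` down, `|logFC| > thres` abs; strict) in at least one dataset.
#' Within each dataset the competition then runs over the candidates present
#' in that dataset using that dataset's ORIGINAL scores — a candidate that
#' failed the filter locally but is present still competes with its
#' unfiltered logFC. Genes absent from a dataset contribute zero rows and
#' columns for it, so `n_ij` is the number of datasets containing both i
#' and j.
#'
#' @inheritParams build_intersection
#' @return A `CompetitionMatrices` object.
#' @export
build_union <- function(tables, config = competition_config(strategy = "union")) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1)
    warning("single input table: k = 1 competition", call. = FALSE)
  k <- length(tables)
  thres <- config$thres
  passes <- function(logFC) switch(config$regulation,
    up   = logFC > thres,
    down = logFC < -thres,
    abs  = abs(logFC) > thres)
  cand <- unique(unlist(lapply(tables, function(t)
    t$data$gene[passes(t$data$logFC)])))
  if (length(cand) == 0)
    stop("empty competition: no gene passes the logFC filter in any dataset",
         call. = FALSE)
  if (length(cand) > config$candidate_cap)
    warning(sprintf(paste("%d candidate genes exceed the recommended cap of %d;",
                          "consider raising `thres` for performance"),
                    length(cand), config$candidate_cap), call. = FALSE)
  cand <- sort_c(cand)
  N <- length(cand)
  W <- L <- n <- matrix(0, N, N)
  per_dataset <- vector("list", k)
  names(per_dataset) <- vapply(tables, function(t) t$name, character(1))
  for (t in seq_len(k)) {
    d <- tables[[t]]$data
    present <- cand[cand %in% d$gene]
    s <- stats::setNames(d$logFC, d$gene)[present]
    per_dataset[[t]] <- s
    if (length(present) >= 2) {
      g <- compare_within_dataset(s, config$regulation)
      idx <- match(present, cand)
      W[idx, idx] <- W[idx, idx] + g$W
      L[idx, idx] <- L[idx, idx] + g$L
      ones <- matrix(1, length(idx), length(idx)); diag(ones) <- 0
      n[idx, idx] <- n[idx, idx] + ones
    }
  }
  if (N < 2) warning("degenerate competition: fewer than 2 candidates",
                     call. = FALSE)
  validate_competition(new_competition_matrices(
    cand, W, L, n, per_dataset, config$regulation, "union", k))
}

#' Build competition matrices per the configured strategy
#'
#' @inheritParams build_intersection
#' @return A `CompetitionMatrices` object from [build_intersection()] or
#'   [build_union()].
#' @export
build_competition <- function(tables, config = competition_config()) {
  switch(config$strategy,
         intersection = build_intersection(tables, config),
         union = build_union(tables, config))
}
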