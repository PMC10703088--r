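# Independent oracles: deliberately naive transcriptions of the pseudocode
# and textbook definitions, kept free of any implementation-path code.

oracle_win <- function(si, sj, regulation) {
  e <- function(x) switch(regulation, up = x, down = -x, abs = abs(x))
  if (e(si) >= e(sj)) 1 else 0
}

# Literal quadruple-loop intersection tournament.
oracle_intersection <- function(tables, regulation) {
  cand <- sort(Reduce(intersect, lapply(tables, genes)), method = "radix")
  N <- length(cand)
  W <- L <- n <- matrix(0, N, N, dimnames = list(cand, cand))
  for (tab in tables) {
    s <- stats::setNames(tab$data$logFC, tab$data$gene)
    for (i in cand) for (j in cand) if (i != j) {
      w <- oracle_win(s[[i]], s[[j]], regulation)
      W[i, j] <- W[i, j] + w
      L[i, j] <- L[i, j] + (1 - w)
      n[i, j] <- n[i, j] + 1
    }
  }
  list(genes = cand, W = W, L = L, n = n)
}

# Literal union tournament: filter for candidacy, compete with original
# scores wherever both genes are present, zero-pad absentees.
oracle_union <- function(tables, regulation, thres) {
  passes <- function(x) switch(regulation,
    up = x > thres, down = x < -thres, abs = abs(x) > thres)
  cand <- sort(unique(unlist(lapply(tables, function(t)
    t$data$gene[passes(t$data$logFC)]))), method = "radix")
  N <- length(cand)
  W <- L <- n <- matrix(0, N, N, dimnames = list(cand, cand))
  for (tab in tables) {
    s <- stats::setNames(tab$data$logFC, tab$data$gene)
    for (i in cand) for (j in cand) if (i != j &&
        i %in% names(s) && j %in% names(s)) {
      w <- oracle_win(s[[i]], s[[j]], regulation)
      W[i, j] <- W[i, j] + w
      L[i, j] <- L[i, j] + (1 - w)
      n[i, j] <- n[i, j] + 1
    }
  }
  list(genes = cand, W = W, L = L, n = n)
}

# Left stationary vector of a row-stochastic matrix by dense eigen
# decomposition (eigenvalue 1 of t(P)).
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# PageRank by direct linear solve of the dense Google-matrix stationary
# equations (dangling rows uniform).
oracle_pagerank <- function(A, alpha) {
  N <- nrow(A)
  rs <- rowSums(A)
  Z <- A / ifelse(rs == 0, 1, rs)
  Z[rs == 0, ] <- 1 / N
  G <- alpha * Z + (1 - alpha) / N
  oracle_stationary(G)
}

# Trapezoidal integration of the empirical ROC curve over all distinct
# thresholds (tied scores collapse to one curve point).
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels); Nn <- sum(!labels)
  tpr <- c(0, vapply(thr, function(t) sum(labels & scores >= t) / P, 0))
  fpr <- c(0, vapply(thr, function(t) sum(!labels & scores >= t) / Nn, 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
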