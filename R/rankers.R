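#' Rating-algorithm parameters
#'
#' @param elo_f Elo scale constant applied to (actual - expected); default 10.
#' @param elo_init Initial Elo rating for every gene; default 1500.
#' @param elo_logistic_scale Divisor in the Elo logistic expectation
#'   `1 / (1 + 10^((r_j - r_i) / scale))`; default 400.
#' @param alpha Damping factor for PageRank and bi-directional PageRank,
#'   in (0, 1); default 0.85.
#' @param tol Convergence tolerance for iterative solvers; default 1e-10.
#' @param max_iter Iteration cap for iterative solvers; default 10000.
#' @return An object of class `RankerParams`.
#' @export
ranker_params <- function(elo_f = 10, elo_init = 1500,
                          elo_logistic_scale = 400,
                          alpha = 0.85, tol = 1e-10, max_iter = 10000L) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(elo_f = elo_f, elo_init = elo_init,
                 elo_logistic_scale = elo_logistic_scale,
                 alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "RankerParams")
}

# A RatingResult packages one method's scores with average-tie ranks
# (rank 1 = highest score).
new_rating_result <- function(method, scores) {
  ranks <- rank(-scores, ties.method = "average")
  structure(list(method = method,
                 scores = scores,
                 ranks = stats::setNames(ranks, names(scores))),
            class = "RatingResult")
}

#' @export
print.RatingResult <- function(x, ...) {
  cat(sprintf("RatingResult [%s]: %d genes; top:\n", x$method, length(x$scores)))
  top <- sort_c(names(x$ranks)[order(x$ranks)][seq_len(min(5, length(x$ranks)))])
  print(x$scores[top])
  invisible(x)
}

#' Win-loss rating
#'
#' The ratio of wins to games, summed over opponents actually played:
#' `r(i) = sum_j w_ij / n_ij` over pairs with `n_ij > 0`. Under the
#' intersection strategy (all `n_ij = k`) this ordering coincides with
#' ordering by total wins.
#'
#' @param cm A `CompetitionMatrices` object.
#' @return A `RatingResult` (also carries total wins as attribute
#'   `total_wins`).
#' @export
rank_winloss <- function(cm) {
  frac <- cm$W / cm$n
  frac[cm$n == 0] <- 0
  scores <- stats::setNames(rowSums(frac), cm$genes)
  res <- new_rating_result("winloss", scores)
  attr(res, "total_wins") <- stats::setNames(rowSums(cm$W), cm$genes)
  res
}

# Massey matrix: diag N_i, off-diagonal -n_ij. Shared with Colley.
.massey_matrix <- function(cm) {
  M <- -cm$n
  diag(M) <- cm$Ni
  M
}

#' Massey least-squares rating
#'
#' Solves `M r = p` where `M_ii = N_i`, `M_ij = -n_ij`, and
#' `p_i = W_i - L_i` (total wins minus losses; for binary outcomes this is
#' exactly the aggregate of the game-level point differentials). M is
#' singular, so the last row is replaced by ones and the last entry of p by
#' zero, which pins the ratings to sum to zero. If the replaced system is
#' still singular (disconnected competition graph) the minimum-norm
#' least-squares solution is returned with a warning.
#'
#' @param cm A `CompetitionMatrices` object (>= 2 genes).
#' @param params A [ranker_params()] (unused; kept for a uniform signature).
#' @return A `RatingResult`; scores sum to 0.
#' @export
rank_massey <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("Massey rating needs at least 2 genes", call. = FALSE)
  M <- .massey_matrix(cm)
  p <- rowSums(cm$W) - rowSums(cm$L)
  M[N, ] <- 1
  p[N] <- 0
  r <- tryCatch(solve(M, p), error = function(e) {
    warning("replaced Massey system is singular; returning minimum-norm ",
            "least-squares solution", call. = FALSE)
    .pinv_solve(M, p)
  })
  new_rating_result("massey", stats::setNames(as.numeric(r), cm$genes))
}

# Minimum-norm least-squares via SVD pseudoinverse.
.pinv_solve <- function(A, b, rtol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * (t(sv$u) %*% b)))
}

#' Colley least-squares rating
#'
#' Solves `C r = b` with the Colley matrix `C = M + 2I` (Laplace's rule of
#' succession regularizing Massey) and `b_i = 1 + (W_i - L_i) / 2`. C is
#' symmetric positive definite, so the system always has a unique solution;
#' with no games every rating is exactly 0.5 and in general the ratings sum
#' to N/2.
#'
#' @inheritParams rank_massey
#' @return A `RatingResult`.
#' @export
rank_colley <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("Colley rating needs at least 2 genes", call. = FALSE)
  C <- .massey_matrix(cm) + 2 * diag(N)
  b <- 1 + (rowSums(cm$W) - rowSums(cm$L)) / 2
  r <- solve(C, b)
  new_rating_result("colley", stats::setNames(as.numeric(r), cm$genes))
}

#' Keener's skewing function
#'
#' `h(x) = 0.5 + 0.5 sgn(x - 0.5) sqrt(|2x - 1|)` stretches win proportions
#' away from 0.5, separating densely packed near-even players. Fixed points
#' at 0, 0.5 and 1; antisymmetric about 0.5 (`h(x) + h(1 - x) = 1`).
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @return Skewed proportion(s) in `[0, 1]`.
#' @export
keener_skew <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("keener_skew is defined on [0, 1]", call. = FALSE)
  0.5 + 0.5 * sign(x - 0.5) * sqrt(abs(2 * x - 1))
}

#' Keener's Perron-eigenvector rating
#'
#' Win proportions are Laplace-smoothed, `a_ij = (w_ij + 1) /
#' (w_ij + w_ji + 2)` (never-played pairs get 0.5, keeping the matrix
#' entrywise positive off the diagonal, hence irreducible), skewed by
#' [keener_skew()] into `K`, and the rating is the Perron eigenvector of K.
#' The eigenpair is computed by power iteration on `K + I` (same eigenvector;
#' the shift rules out period-2 oscillation); the vector is normalized to
#' sum 1.
#'
#' @inheritParams rank_massey
#' @param params A [ranker_params()]; uses `tol` and `max_iter`.
#' @return A `RatingResult`; attribute `lambda` carries the dominant
#'   eigenvalue of K.
#' @export
rank_keener <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("Keener rating needs at least 2 genes", call. = FALSE)
  a <- (cm$W + 1) / (cm$W + t(cm$W) + 2)
  K <- keener_skew(a)
  diag(K) <- 0
  v <- rep(1 / N, N)
  B <- K + diag(N)
  for (it in seq_len(params$max_iter)) {
    v_new <- as.numeric(B %*% v)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < params$tol) {
      v <- v_new
      lam <- as.numeric((t(v) %*% K %*% v) / sum(v^2))
      res <- new_rating_result("keener", stats::setNames(v, cm$genes))
      attr(res, "lambda") <- lam
      attr(res, "iterations") <- it
      return(res)
    }
    v <- v_new
  }
  stop(sprintf("Keener power iteration did not converge in %d iterations (residual %.3g)",
               params$max_iter, max(abs(as.numeric(B %*% v) / sum(B %*% v) - v))),
       call. = FALSE)
}

#' Elo sequential rating
#'
#' All genes start at `elo_init`. Datasets are processed in input order;
#' within a dataset the unordered pairs of genes present in it are processed
#' in lexicographic order. For each game the actual outcome kappa is 1/0/0.5
#' for win/loss/tie on that dataset's scores under the competition's
#' regulation mode, the expected outcome is the logistic
#' `mu_ij = 1 / (1 + 10^((r_j - r_i)/400))`, and both ratings update
#' simultaneously by `r += f (kappa - mu)`. Note the result depends on the
#' dataset order (the matrices do not).
#'
#' @inheritParams rank_massey
#' @param params A [ranker_params()]; uses `elo_f`, `elo_init`,
#'   `elo_logistic_scale`.
#' @return A `RatingResult`.
#' @export
rank_elo <- function(cm, params = ranker_params()) {
  if (is.null(cm$per_dataset))
    stop("Elo needs the per-dataset outcome record", call. = FALSE)
  r <- stats::setNames(rep(params$elo_init, length(cm$genes)), cm$genes)
  f <- params$elo_f
  scl <- params$elo_logistic_scale
  for (s in cm$per_dataset) {
    present <- sort_c(names(s))
    m <- length(present)
    if (m < 2) next
    eff <- .effective_score(as.numeric(s[present]), cm$regulation)
    for (i in seq_len(m - 1)) {
      gi <- present[i]
      for (j in seq((i + 1), m)) {
        gj <- present[j]
        kap <- if (eff[i] > eff[j]) 1 else if (eff[i] < eff[j]) 0 else 0.5
        mu_ij <- 1 / (1 + 10^((r[[gj]] - r[[gi]]) / scl))
        mu_ji <- 1 - mu_ij
        ri_new <- r[[gi]] + f * (kap - mu_ij)
        r[[gj]] <- r[[gj]] + f * ((1 - kap) - mu_ji)
        r[[gi]] <- ri_new
      }
    }
  }
  new_rating_result("elo", r)
}

# Row-normalize a non-negative matrix into a transition matrix; rows with
# zero sum (dangling nodes) become uniform 1/N.
.row_stochastic <- function(A) {
  N <- nrow(A)
  rs <- rowSums(A)
  P <- A / ifelse(rs == 0, 1, rs)
  P[rs == 0, ] <- 1 / N
  P
}

# Left stationary vector of a row-stochastic P by power iteration from
# uniform. Returns NULL on non-convergence.
.stationary <- function(P, tol, max_iter) {
  N <- nrow(P)
  v <- rep(1 / N, N)
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(crossprod(P, v))
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) return(list(pi = v_new, iterations = it))
    v <- v_new
  }
  NULL
}

#' Markov-chain rating
#'
#' The weaker alternative votes for the stronger: the binary voting matrix
#' has `V_ij = 1` iff gene i lost at least once to gene j. V is
#' row-normalized into a transition matrix P (undefeated genes become
#' dangling nodes, replaced by uniform rows) and the rating is the chain's
#' stationary distribution, found by power iteration. The naive fixed point
#' `r = P r` of a row-stochastic matrix is degenerate (any constant vector
#' solves it); the stationary distribution is the standard Markov rating.
#' A reducible or periodic chain that fails to converge is mixed with the
#' uniform chain at weight 0.15 and retried, with a warning.
#'
#' @inheritParams rank_keener
#' @return A `RatingResult`; scores are non-negative and sum to 1.
#' @export
rank_markov <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("Markov rating needs at least 2 genes", call. = FALSE)
  V <- (cm$L > 0) * 1
  diag(V) <- 0
  P <- .row_stochastic(V)
  st <- .stationary(P, params$tol, params$max_iter)
  if (is.null(st)) {
    warning("Markov chain did not converge; mixing with uniform at weight 0.15",
            call. = FALSE)
    P <- 0.85 * P + 0.15 / N
    st <- .stationary(P, params$tol, params$max_iter)
    if (is.null(st))
      stop("Markov rating failed to converge even after uniform mixing",
           call. = FALSE)
  }
  res <- new_rating_result("markov", stats::setNames(st$pi, cm$genes))
  attr(res, "iterations") <- st$iterations
  res
}

# Damped PageRank on a weighted adjacency matrix A (row = source node).
# Iterates r <- alpha * r Z + teleport without forming the dense Google
# matrix; dangling rows spread uniformly.
.pagerank <- function(A, alpha, tol, max_iter) {
  N <- nrow(A)
  rs <- rowSums(A)
  dangling <- rs == 0
  Z <- A / ifelse(rs == 0, 1, rs)
  r <- rep(1 / N, N)
  for (it in seq_len(max_iter)) {
    r_new <- alpha * (as.numeric(crossprod(Z, r)) +
                        sum(r[dangling]) / N) + (1 - alpha) / N
    if (max(abs(r_new - r)) < tol)
      return(list(r = r_new / sum(r_new), iterations = it))
    r <- r_new
  }
  stop(sprintf("PageRank did not converge in %d iterations", max_iter),
       call. = FALSE)
}

#' PageRank rating
#'
#' Builds the loser-to-winner graph with multiplicity weights
#' (`A_uv = l_uv`, the number of matches u lost to v), row-normalizes it with
#' dangling (undefeated) rows spread uniformly, and iterates the damped
#' Google-matrix update `r <- alpha r Z + (1 - alpha)/N` from the uniform
#' vector until the max-abs change falls below `tol`.
#'
#' @inheritParams rank_keener
#' @param params A [ranker_params()]; uses `alpha`, `tol`, `max_iter`.
#' @return A `RatingResult`; scores are positive and sum to 1.
#' @export
rank_pagerank <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("PageRank rating needs at least 2 genes", call. = FALSE)
  pr <- .pagerank(cm$L, params$alpha, params$tol, params$max_iter)
  res <- new_rating_result("pagerank", stats::setNames(pr$r, cm$genes))
  attr(res, "iterations") <- pr$iterations
  res
}

#' Bi-directional PageRank rating
#'
#' Combines the forward PageRank `r_p` (loser-to-winner graph) with a
#' backward score `r_q` that propagates along losses: `r_q` is PageRank on
#' the edge-reversed, winner-to-loser graph (`A_uv = w_uv`), computed with
#' the same damping, tolerance and dangling rule. The rating is
#' `r_s = r_p - r_q`: positive for genes that mostly win, negative for genes
#' that mostly lose; the scores sum to 0.
#'
#' @inheritParams rank_pagerank
#' @return A `RatingResult`.
#' @export
rank_bipagerank <- function(cm, params = ranker_params()) {
  N <- length(cm$genes)
  if (N < 2) stop("BiPageRank rating needs at least 2 genes", call. = FALSE)
  rp <- .pagerank(cm$L, params$alpha, params$tol, params$max_iter)$r
  rq <- .pagerank(cm$W, params$alpha, params$tol, params$max_iter)$r
  new_rating_result("bipagerank", stats::setNames(rp - rq, cm$genes))
}

#' The eight rating-method identifiers
#' @return Character vector of valid method names.
#' @export
ranking_methods <- function() {
  c("winloss", "massey", "colley", "keener", "elo", "markov",
    "pagerank", "bipagerank")
}

#' Run several rating methods on one competition
#'
#' Dispatches each requested method on the same `CompetitionMatrices`, so all
#' results share the candidate gene universe. Per-method wall time (seconds)
#' is recorded in the result's `runtime` attribute for cost benchmarking.
#'
#' @param cm A `CompetitionMatrices` object.
#' @param methods Character vector of method identifiers (see
#'   [ranking_methods()]); duplicates are dropped with a warning.
#' @param params A [ranker_params()].
#' @return Named list of `RatingResult` objects, one per method.
#' @export
rank_all <- function(cm, methods = ranking_methods(),
                     params = ranker_params()) {
  if (anyDuplicated(methods)) {
    warning("duplicate method names dropped", call. = FALSE)
    methods <- unique(methods)
  }
  bad <- setdiff(methods, ranking_methods())
  if (length(bad))
    stop(sprintf("unknown ranking method(s): %s; valid names are: %s",
                 paste(bad, collapse = ", "),
                 paste(ranking_methods(), collapse = ", ")), call. = FALSE)
  out <- vector("list", length(methods))
  names(out) <- methods
  for (m in methods) {
    fn <- switch(m,
                 winloss = function(cm, params) rank_winloss(cm),
                 massey = rank_massey, colley = rank_colley,
                 keener = rank_keener, elo = rank_elo, markov = rank_markov,
                 pagerank = rank_pagerank, bipagerank = rank_bipagerank)
    t0 <- proc.time()[["elapsed"]]
    res <- fn(cm, params)
    attr(res, "runtime") <- proc.time()[["elapsed"]] - t0
    out[[m]] <- res
  }
  out
}
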