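# Two-gene competition in which A beat B exactly once.
cm_ab <- function() {
  suppressWarnings(build_intersection(list(tbl("d1", c(A = 2, B = 1))),
                                      competition_config("up")))
}

test_that("win-loss ratio sums over opponents played", {
  d1 <- tbl("d1", c(A = 2, B = 1, C = -0.5))
  d2 <- tbl("d2", c(B = 3, C = 1))
  cm <- build_union(list(d1, d2), competition_config("up", "union"))
  r <- rank_winloss(cm)
  expect_equal(unname(r$scores[c("A", "B", "C")]), c(2, 1, 0))
  expect_equal(unname(r$ranks[c("A", "B", "C")]), c(1, 2, 3))

  expect_equal(unname(rank_winloss(cm_ab())$scores), c(1, 0))

  tie <- suppressWarnings(build_intersection(list(tbl("t", c(A = 1, B = 1)))))
  expect_equal(unname(rank_winloss(tie)$scores), c(1, 1))
  expect_equal(unname(rank_winloss(tie)$ranks), c(1.5, 1.5))
})

test_that("Massey: worked two-gene system, zero-sum, and no-games case", {
  r <- rank_massey(cm_ab())
  expect_equal(unname(r$scores), c(0.5, -0.5), tolerance = 1e-12)

  for (seed in 1:5) {
    cm <- rand_cm(seed, n_genes = 15, k = 3)
    expect_lt(abs(sum(rank_massey(cm)$scores)), 1e-8)
  }

  Z <- matrix(0, 4, 4)
  cm0 <- competition_matrices(letters[1:4], Z, Z)
  expect_warning(r0 <- rank_massey(cm0), "singular")
  expect_equal(unname(r0$scores), rep(0, 4), tolerance = 1e-10)
})

test_that("Massey handles a disconnected competition graph", {
  # two 2-gene islands that never meet
  W <- matrix(0, 4, 4); W[1, 2] <- 1; W[3, 4] <- 1
  L <- t(W)
  cm <- competition_matrices(letters[1:4], W, L)
  expect_warning(r <- rank_massey(cm), "singular")
  expect_true(all(is.finite(r$scores)))
  expect_gt(r$scores[["a"]], r$scores[["b"]])
})

test_that("Colley: worked system, 0.5 baseline, N/2 sum", {
  expect_equal(unname(rank_colley(cm_ab())$scores), c(0.625, 0.375),
               tolerance = 1e-12)

  Z <- matrix(0, 5, 5)
  cm0 <- competition_matrices(letters[1:5], Z, Z)
  expect_equal(unname(rank_colley(cm0)$scores), rep(0.5, 5))

  for (seed in 1:5) {
    cm <- rand_cm(seed + 20, n_genes = 15, k = 3)
    expect_equal(sum(rank_colley(cm)$scores), length(cm$genes) / 2,
                 tolerance = 1e-8)
  }
})

test_that("keener_skew: fixed points, antisymmetry, domain", {
  expect_equal(keener_skew(0.5), 0.5)
  expect_equal(keener_skew(0), 0)
  expect_equal(keener_skew(1), 1)
  expect_equal(keener_skew(2 / 3), 0.5 + 0.5 * sqrt(1 / 3))
  x <- seq(0, 1, by = 0.05)
  expect_equal(keener_skew(x) + keener_skew(1 - x), rep(1, length(x)))
  expect_error(keener_skew(1.2), "\\[0, 1\\]")
})

test_that("Keener matches the dense eigen oracle and handles no games", {
  cm <- cm_ab()
  r <- rank_keener(cm)
  a <- 0.5 + 0.5 * sqrt(1 / 3)
  closed <- sqrt(a) / (sqrt(a) + sqrt(1 - a))
  expect_equal(unname(r$scores), c(closed, 1 - closed), tolerance = 1e-8)
  expect_equal(attr(r, "lambda"), sqrt(a * (1 - a)), tolerance = 1e-6)

  Z <- matrix(0, 4, 4)
  cm0 <- competition_matrices(letters[1:4], Z, Z)
  expect_equal(unname(rank_keener(cm0)$scores), rep(0.25, 4),
               tolerance = 1e-8)

  for (seed in 1:4) {
    cmr <- rand_cm(seed + 40, n_genes = 8, k = 3)
    N <- length(cmr$genes)
    a_m <- (cmr$W + 1) / (cmr$W + t(cmr$W) + 2)
    K <- keener_skew(a_m); diag(K) <- 0
    expect_equal(K + t(K), matrix(1, N, N) - diag(N),
                 ignore_attr = TRUE, tolerance = 1e-12)
    e <- eigen(K)
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    expect_equal(unname(rank_keener(cmr)$scores), v / sum(v),
                 tolerance = 1e-7)
  }
})

test_that("Elo: worked updates, tie no-op, zero-sum conservation", {
  r <- rank_elo(cm_ab())
  expect_equal(unname(r$scores[c("A", "B")]), c(1505, 1495))

  tie <- suppressWarnings(build_intersection(list(tbl("t", c(A = 1, B = 1)))))
  expect_equal(unname(rank_elo(tie)$scores), c(1500, 1500))

  for (seed in 1:5) {
    cm <- rand_cm(seed + 60, n_genes = 12, k = 3)
    expect_equal(sum(rank_elo(cm)$scores), 1500 * length(cm$genes),
                 tolerance = 1e-9)
  }

  cm_bad <- cm_ab(); cm_bad$per_dataset <- NULL
  expect_error(rank_elo(cm_bad), "per-dataset")
})

test_that("Elo respects parameters and dataset order", {
  cm <- cm_ab()
  r <- rank_elo(cm, ranker_params(elo_f = 32, elo_init = 1000))
  expect_equal(unname(r$scores[c("A", "B")]), c(1016, 984))

  tabs <- rand_tables(99, n_genes = 8, k = 3)
  cfg <- competition_config("up")
  a <- rank_elo(build_intersection(tabs, cfg))
  b <- rank_elo(build_intersection(tabs[c(2, 3, 1)], cfg))
  expect_equal(sum(a$scores), sum(b$scores))  # conservation regardless
})

test_that("Markov matches the stationary-distribution oracle", {
  r <- rank_markov(cm_ab())
  expect_equal(unname(r$scores[c("A", "B")]), c(2 / 3, 1 / 3),
               tolerance = 1e-8)

  Z <- matrix(0, 4, 4)
  cm0 <- competition_matrices(letters[1:4], Z, Z)
  expect_equal(unname(rank_markov(cm0)$scores), rep(0.25, 4),
               tolerance = 1e-8)

  for (seed in 1:5) {
    cm <- rand_cm(seed + 80, n_genes = 6, k = 3)
    N <- length(cm$genes)
    V <- (cm$L > 0) * 1
    rs <- rowSums(V)
    P <- V / ifelse(rs == 0, 1, rs); P[rs == 0, ] <- 1 / N
    pi_hat <- suppressWarnings(rank_markov(cm)$scores)
    expect_gte(min(pi_hat), 0)
    expect_equal(sum(pi_hat), 1, tolerance = 1e-10)
    expect_equal(unname(pi_hat), oracle_stationary(P), tolerance = 1e-7)
  }
})

test_that("Markov mixes with uniform on a periodic chain", {
  # a and b trade one loss each; c lost once to a. The voting chain
  # a->b, b->a, c->a is periodic and oscillates from the uniform start.
  L <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  L["a", "b"] <- 1; L["b", "a"] <- 1; L["c", "a"] <- 1
  cm <- competition_matrices(letters[1:3], t(L), L, n = L + t(L))
  expect_warning(r <- rank_markov(cm), "mixing")
  P <- rbind(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(unname(r$scores), oracle_stationary(0.85 * P + 0.15 / 3),
               tolerance = 1e-7)
})

test_that("PageRank matches the dense-solve oracle and igraph", {
  r <- rank_pagerank(cm_ab())
  expect_equal(unname(r$scores[c("A", "B")]),
               c(0.925 / 1.425, 0.5 / 1.425), tolerance = 1e-8)

  Z <- matrix(0, 3, 3)
  cm0 <- competition_matrices(letters[1:3], Z, Z)
  expect_equal(unname(rank_pagerank(cm0)$scores), rep(1 / 3, 3),
               tolerance = 1e-10)

  for (seed in 1:5) {
    cm <- rand_cm(seed + 100, n_genes = 6, k = 3)
    mine <- rank_pagerank(cm)$scores
    expect_equal(unname(mine), oracle_pagerank(cm$L, 0.85), tolerance = 1e-8)
    expect_equal(sum(mine), 1, tolerance = 1e-10)
    expect_true(all(mine > 0))
  }

  skip_if_not_installed("igraph")
  cm <- rand_cm(7, n_genes = 8, k = 3, presence = 1)
  g <- igraph::graph_from_adjacency_matrix(cm$L, mode = "directed",
                                           weighted = TRUE)
  ig <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(unname(rank_pagerank(cm)$scores), unname(ig),
               tolerance = 1e-6)
})

test_that("BiPageRank is the forward-minus-reversed PageRank", {
  r <- rank_bipagerank(cm_ab())
  expect_equal(unname(r$scores[c("A", "B")]),
               c(0.425 / 1.425, -0.425 / 1.425), tolerance = 1e-8)

  # head-to-head 1-1: forward and reversed graphs coincide
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  cm <- competition_matrices(c("a", "b"), W, t(W), n = W + t(W))
  expect_equal(unname(rank_bipagerank(cm)$scores), c(0, 0),
               tolerance = 1e-10)

  for (seed in 1:5) {
    cm <- rand_cm(seed + 120, n_genes = 9, k = 3)
    s <- rank_bipagerank(cm)$scores
    expect_equal(sum(s), 0, tolerance = 1e-9)
    expect_equal(unname(s),
                 oracle_pagerank(cm$L, 0.85) - oracle_pagerank(cm$W, 0.85),
                 tolerance = 1e-8)
  }
})

test_that("rank_all dispatches, dedupes, and shares the universe", {
  cm <- rand_cm(5, n_genes = 20, k = 3)
  res <- rank_all(cm)
  expect_length(res, 8)
  for (r in res) {
    expect_identical(names(r$scores), cm$genes)
    expect_true(is.numeric(attr(r, "runtime")))
  }
  expect_error(rank_all(cm, "sorcery"), "unknown ranking method")
  expect_warning(one <- rank_all(cm, c("winloss", "winloss")), "duplicate")
  expect_length(one, 1)
})

test_that("ratings are permutation-equivariant and outcome-only", {
  cm <- rand_cm(31, n_genes = 7, k = 3)
  set.seed(1)
  perm <- sample(seq_along(cm$genes))
  cmp <- competition_matrices(cm$genes[perm], cm$W[perm, perm],
                              cm$L[perm, perm], cm$n[perm, perm],
                              per_dataset = lapply(cm$per_dataset, identity),
                              regulation = cm$regulation,
                              strategy = cm$strategy, k = cm$k)
  for (m in setdiff(ranking_methods(), "elo")) {
    a <- rank_all(cm, m)[[1]]$scores
    b <- rank_all(cmp, m)[[1]]$scores
    expect_equal(b[cm$genes], a[cm$genes], tolerance = 1e-9)
  }
  # outcome-only dependence: rescaling logFC without changing pairwise
  # order leaves every method untouched (Elo included)
  tabs <- rand_tables(32, n_genes = 8, k = 3)
  tabs2 <- lapply(tabs, function(t) { t$data$logFC <- t$data$logFC * 7; t })
  cfg <- competition_config("up", "union")
  for (m in ranking_methods()) {
    a <- rank_all(build_union(tabs, cfg), m)[[1]]$scores
    b <- rank_all(build_union(tabs2, cfg), m)[[1]]$scores
    expect_equal(a, b, tolerance = 1e-10)
  }
})
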