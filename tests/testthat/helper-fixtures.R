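# Small builders used across test files.

# GeneTable from a named logFC vector.
tbl <- function(name, scores, pval = NULL, adj = NULL) {
  gene_table(name, names(scores), unname(scores), pval = pval, adj_pval = adj)
}

# Random tie-free tables over a shared alphabet with per-dataset presence.
rand_tables <- function(seed, n_genes = 10, k = 3, presence = 0.8) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  lapply(seq_len(k), function(t) {
    keep <- runif(n_genes) < presence
    if (sum(keep) < 2) keep[sample.int(n_genes, 2)] <- TRUE
    s <- rnorm(sum(keep))
    if (all(s <= 0)) s[1] <- abs(s[1]) + 0.1  # keep the up-filter non-empty
    tbl(paste0("d", t), stats::setNames(s, ids[keep]))
  })
}

# Random competition (suppresses the k = 1 warning when k == 1).
rand_cm <- function(seed, n_genes = 10, k = 3, strategy = "union",
                    regulation = "up", presence = 0.8) {
  tabs <- rand_tables(seed, n_genes, k, presence)
  cfg <- competition_config(regulation, strategy)
  suppressWarnings(build_competition(tabs, cfg))
}
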