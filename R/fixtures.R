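#' Specification for synthetic multi-dataset DE tables
#'
#' Describes a synthetic world of `k_datasets` differential-expression tables
#' over a shared gene universe with heterogeneous per-dataset coverage:
#' each gene enters each dataset independently with `presence_prob`
#' (planted genes are forced into at least 2 datasets so they are rankable
#' under the union strategy). Null genes draw logFC from
#' `Normal(0, noise_sd)`; planted up/down genes from
#' `Normal(+/- effect_mu, noise_sd)`. P-values are a deterministic monotone
#' transform of `|logFC|` (a two-sided normal tail at scale `noise_sd`) times
#' a small seeded jitter, then BH-adjusted, so planted genes clear the usual
#' DEG rule (|logFC| > 1, adjusted p < 0.05) with high probability.
#'
#' @param n_genes Gene universe size (default 200).
#' @param k_datasets Number of tables (default 4).
#' @param presence_prob Per-gene per-dataset inclusion probability in (0, 1]
#'   (default 0.8).
#' @param n_planted_up,n_planted_down Counts of planted strong genes
#'   (defaults 10 and 10).
#' @param effect_mu Mean `|logFC|` of planted genes (default 2.5).
#' @param noise_sd logFC standard deviation of null genes (default 0.5).
#' @param seed Random seed (integer).
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_genes = 200, k_datasets = 4, presence_prob = 0.8,
                         n_planted_up = 10, n_planted_down = 10,
                         effect_mu = 2.5, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_genes >= 2, k_datasets >= 1,
            presence_prob > 0, presence_prob <= 1,
            n_planted_up >= 0, n_planted_down >= 0,
            n_planted_up + n_planted_down <= n_genes,
            effect_mu >= 0, noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes),
                 k_datasets = as.integer(k_datasets),
                 presence_prob = presence_prob,
                 n_planted_up = as.integer(n_planted_up),
                 n_planted_down = as.integer(n_planted_down),
                 effect_mu = effect_mu, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate synthetic DE tables with planted differential genes
#'
#' Fully reproducible from `spec$seed`. Returns the tables together with the
#' planted/null truth labels so recovery experiments can score themselves.
#'
#' @param spec A [fixture_spec()].
#' @return List with `tables` (list of [gene_table()] objects named
#'   `sim1..simK`) and `truth` (data.frame with columns `gene` and `label`
#'   in `{"up", "down", "null"}`).
#' @export
generate_tables <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))
  label <- rep("null", ng)
  if (spec$n_planted_up > 0) label[seq_len(spec$n_planted_up)] <- "up"
  if (spec$n_planted_down > 0)
    label[spec$n_planted_up + seq_len(spec$n_planted_down)] <- "down"

  k <- spec$k_datasets
  present <- matrix(stats::runif(ng * k) < spec$presence_prob, ng, k)
  # planted genes must be rankable under union: force presence in >= 2
  # datasets (or all, when k < 2)
  need <- min(2L, k)
  for (g in which(label != "null")) {
    while (sum(present[g, ]) < need) {
      present[g, sample.int(k, 1)] <- TRUE
    }
  }

  mu <- ifelse(label == "up", spec$effect_mu,
               ifelse(label == "down", -spec$effect_mu, 0))
  tables <- vector("list", k)
  for (t in seq_len(k)) {
    idx <- which(present[, t])
    lfc <- stats::rnorm(length(idx), mean = mu[idx], sd = spec$noise_sd)
    pval <- pmin(1, 2 * stats::pnorm(-abs(lfc) / spec$noise_sd) *
                   exp(stats::rnorm(length(idx), 0, 0.05)))
    adj <- stats::p.adjust(pval, method = "BH")
    tables[[t]] <- gene_table(sprintf("sim%d", t), gene_ids[idx], lfc,
                              pval = pval, adj_pval = adj)
  }
  list(tables = tables,
       truth = data.frame(gene = gene_ids, label = label,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic fixture set to disk
#'
#' Writes one CSV per dataset (`sim<k>.csv`, limma-dialect columns
#' `gene,logFC,P.Value,adj.P.Val`) plus `truth.csv` with the planted labels.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the character vector of paths written.
#' @export
write_fixture_set <- function(spec, outdir) {
  sim <- generate_tables(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in sim$tables) {
    d <- tab$data
    out <- data.frame(gene = d$gene, logFC = d$logFC,
                      P.Value = d$pval, adj.P.Val = d$adj_pval,
                      stringsAsFactors = FALSE)
    p <- file.path(outdir, paste0(tab$name, ".csv"))
    utils::write.csv(format(out, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  tp <- file.path(outdir, "truth.csv")
  utils::write.csv(sim$truth, tp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, tp))
}
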