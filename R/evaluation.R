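#' Positive-set rule for held-out DEG calls
#'
#' A gene in the held-out dataset counts as a true positive when it clears
#' both cutoffs (strict inequalities): up mode `logFC > logfc_cut`, down mode
#' `logFC < -logfc_cut`, absolute mode either side; always
#' `adj_pval < adj_cut`.
#'
#' @param regulation `"up"`, `"down"` or `"abs"`.
#' @param logfc_cut Positive logFC cutoff (default 1).
#' @param adj_cut Adjusted-p cutoff in (0, 1) (default 0.05).
#' @return An object of class `PositiveSetRule`.
#' @export
positive_set_rule <- function(regulation = c("up", "down", "abs"),
                              logfc_cut = 1, adj_cut = 0.05) {
  regulation <- match.arg(regulation)
  stopifnot(logfc_cut > 0, adj_cut > 0, adj_cut < 1)
  structure(list(regulation = regulation, logfc_cut = logfc_cut,
                 adj_cut = adj_cut), class = "PositiveSetRule")
}

#' Positive genes of a held-out table under a rule
#'
#' @param test_table A [gene_table()] with adjusted p-values.
#' @param rule A [positive_set_rule()].
#' @return Character vector of positive gene symbols.
#' @export
define_positives <- function(test_table, rule = positive_set_rule()) {
  d <- test_table$data
  if (all(is.na(d$adj_pval)))
    stop(sprintf("dataset '%s' has no adjusted p-values; cannot define positives",
                 test_table$name), call. = FALSE)
  fc_ok <- switch(rule$regulation,
                  up   = d$logFC > rule$logfc_cut,
                  down = d$logFC < -rule$logfc_cut,
                  abs  = abs(d$logFC) > rule$logfc_cut)
  pos <- fc_ok & !is.na(d$adj_pval) & d$adj_pval < rule$adj_cut
  d$gene[pos]
}

#' ROC and precision-recall areas for a ranking
#'
#' AUC uses the rank-statistic (Mann-Whitney) formulation with midrank tie
#' correction. AUPR integrates the precision-recall curve stepwise with tied
#' score blocks grouped (precision at each block's boundary times the recall
#' increment), and AUPRN divides AUPR by the positive prevalence so a random
#' scorer sits near 1 regardless of class imbalance.
#'
#' @param scores Named numeric scores (higher = stronger candidate), defined
#'   on all of `universe`.
#' @param positives Character vector of positive genes (subset of universe).
#' @param universe Character vector of evaluated genes.
#' @return List with `auc`, `aupr`, `auprn`, `n_pos`, `n_neg`.
#' @export
score_curve_areas <- function(scores, positives, universe) {
  universe <- unique(universe)
  positives <- intersect(positives, universe)
  if (!all(universe %in% names(scores)))
    stop("scores must be defined on the whole universe", call. = FALSE)
  s <- as.numeric(scores[universe])
  y <- universe %in% positives
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop(sprintf("undefined metric: %d positives and %d negatives in universe",
                 n_pos, n_neg), call. = FALSE)
  # midrank Mann-Whitney AUC
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # stepwise PR with tied blocks grouped, descending score
  ord <- order(-s)
  sy <- y[ord]; ss <- s[ord]
  block_end <- which(ss != c(ss[-1], NA) | seq_along(ss) == length(ss))
  tp <- cumsum(sy)[block_end]
  fp <- block_end - tp
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, aupr = aupr, auprn = aupr / (n_pos / length(universe)),
       n_pos = n_pos, n_neg = n_neg)
}

#' Baseline prioritization scores
#'
#' Three conventional references against which the tournament ratings are
#' compared: `classical` — 1 iff the gene meets the DEG rule in every
#' training dataset where it is present (the intersection-of-DEG-lists
#' convention), else 0; `count` — number of training datasets in which the
#' gene meets the rule; `avg_logfc` — mean logFC over the training datasets
#' containing the gene, sign-flipped in down mode and `|logFC|`-averaged in
#' absolute mode so larger always means stronger. Genes absent from every
#' training dataset score 0 (with a warning).
#'
#' @param train_tables List of [gene_table()] objects with adjusted p-values.
#' @param rule A [positive_set_rule()].
#' @param universe Character vector of genes to score.
#' @return Named list of three named numeric score vectors over `universe`:
#'   `classical`, `count`, `avg_logfc`.
#' @export
baseline_scores <- function(train_tables, rule, universe) {
  stopifnot(length(universe) > 0)
  for (tt in train_tables)
    if (all(is.na(tt$data$adj_pval)))
      stop(sprintf("training dataset '%s' has no adjusted p-values", tt$name),
           call. = FALSE)
  n_u <- length(universe)
  meets <- present <- matrix(FALSE, n_u, length(train_tables))
  fc <- matrix(NA_real_, n_u, length(train_tables))
  for (t in seq_along(train_tables)) {
    d <- train_tables[[t]]$data
    idx <- match(universe, d$gene)
    here <- !is.na(idx)
    present[here, t] <- TRUE
    fc[here, t] <- d$logFC[idx[here]]
    pos <- define_positives(train_tables[[t]], rule)
    meets[, t] <- universe %in% pos
  }
  n_present <- rowSums(present)
  if (any(n_present == 0))
    warning(sprintf("%d universe gene(s) absent from every training dataset score 0",
                    sum(n_present == 0)), call. = FALSE)
  classical <- as.numeric(n_present > 0 & rowSums(meets) == n_present &
                            rowSums(meets) > 0)
  count <- rowSums(meets)
  eff <- switch(rule$regulation, up = fc, down = -fc, abs = abs(fc))
  avg <- rowMeans(eff, na.rm = TRUE)
  avg[n_present == 0] <- 0
  list(classical = stats::setNames(classical, universe),
       count = stats::setNames(count, universe),
       avg_logfc = stats::setNames(avg, universe))
}

#' Leave-one-out cross-validation of ranking methods
#'
#' Each dataset in turn is held out as the truth-defining test set; the
#' competition is built from the remaining (training) datasets, scored by
#' every requested rating method plus the three baselines, and evaluated
#' against the held-out DEG calls. By default the evaluation universe is the
#' ranked candidates that are also present in the held-out table (a held-out
#' label is unknowable for absent genes); set `absent_as_negative = TRUE` to
#' keep all ranked candidates and treat the absent ones as negatives.
#'
#' @param tables List of >= 3 [gene_table()] objects with adjusted p-values.
#' @param config A [competition_config()].
#' @param methods Rating methods to evaluate (see [ranking_methods()]).
#' @param params A [ranker_params()].
#' @param rule A [positive_set_rule()]; defaults to the configured regulation
#'   with logFC cutoff 1 and adjusted-p cutoff 0.05.
#' @param absent_as_negative Logical; see above.
#' @return List with `reports` (data.frame: one row per fold x scorer with
#'   auc/aupr/auprn/n_pos/universe) and `means` (data.frame of per-scorer
#'   means over defined folds). Folds with no positives (or no negatives) in
#'   the universe are reported as `NA` and excluded from the means, with a
#'   warning.
#' @export
loocv <- function(tables, config = competition_config(),
                  methods = ranking_methods(), params = ranker_params(),
                  rule = NULL, absent_as_negative = FALSE) {
  if (length(tables) < 3)
    stop("LOOCV needs at least 3 datasets (2 training per fold)", call. = FALSE)
  if (is.null(rule)) rule <- positive_set_rule(config$regulation)
  rows <- list()
  for (f in seq_along(tables)) {
    test <- tables[[f]]
    train <- tables[-f]
    cm <- build_competition(train, config)
    ratings <- rank_all(cm, methods, params)
    scorer_scores <- lapply(ratings, `[[`, "scores")
    base <- baseline_scores(train, rule, cm$genes)
    scorer_scores <- c(scorer_scores, base)
    universe <- if (absent_as_negative) cm$genes else
      intersect(cm$genes, genes(test))
    positives <- intersect(define_positives(test, rule), universe)
    for (m in names(scorer_scores)) {
      areas <- tryCatch(
        score_curve_areas(scorer_scores[[m]], positives, universe),
        error = function(e) NULL)
      if (is.null(areas)) {
        warning(sprintf("fold '%s', scorer '%s': undefined metric (%d positives in universe of %d); excluded from means",
                        test$name, m, length(positives), length(universe)),
                call. = FALSE)
        areas <- list(auc = NA_real_, aupr = NA_real_, auprn = NA_real_,
                      n_pos = length(positives),
                      n_neg = length(universe) - length(positives))
      }
      rows[[length(rows) + 1]] <- data.frame(
        held_out = test$name, method = m, auc = areas$auc,
        aupr = areas$aupr, auprn = areas$auprn, n_pos = areas$n_pos,
        universe = length(universe), stringsAsFactors = FALSE)
    }
  }
  reports <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(reports, reports$method), function(d)
    data.frame(method = d$method[1],
               mean_auc = mean(d$auc, na.rm = TRUE),
               mean_aupr = mean(d$aupr, na.rm = TRUE),
               mean_auprn = mean(d$auprn, na.rm = TRUE),
               n_folds = sum(!is.na(d$auc)), stringsAsFactors = FALSE)))
  rownames(means) <- NULL
  list(reports = reports, means = means)
}
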