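---
title: "Tournament-based gene prioritization across DE datasets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tournament-based gene prioritization across DE datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankDEG)
```

## The model

Given $k$ differential-expression tables over partially overlapping gene
universes $S_1, \dots, S_k$, each gene pair $(i, j)$ plays one game per
dataset in which both compete. Within a dataset the game is decided by the
competing score (logFC by default): in up-regulation mode $i$ beats $j$ iff
$\mathrm{logFC}_i \ge \mathrm{logFC}_j$, in down mode iff
$\mathrm{logFC}_i \le \mathrm{logFC}_j$, and in the two-sided (absolute)
mode iff $|\mathrm{logFC}_i| \ge |\mathrm{logFC}_j|$. Because only the
within-dataset *ordering* of scores enters, the integration is invariant to
any strictly increasing per-dataset transform of the scores — this is what
makes results from different platforms commensurable, and it is asserted as
a property test.

Note the tie convention: the $\ge$ comparisons mean an *exact* floating-point
tie credits both genes a win and neither a loss. This follows the
sign-composition construction of the integration pseudocode literally, even
though it breaks the usual $l_{ij} = w_{ji}$ symmetry under ties (the
invariant that survives, and that `validate_competition()` asserts, is
$w_{ij} + l_{ij} = n_{ij}$). Ties have measure zero for continuous scores but
occur in real tables (rounded logFC); a deliberate choice of the literal rule
keeps the matrices reproducible against the reference construction. No
epsilon is applied — equality means equality.

Aggregation strategies:

* **Intersection.** Candidates are $\bigcap_t S_t$; every pair plays $k$
  games, $N_i = k(N-1)$. Simple, but discards genes missing from any single
  study.
* **Union.** Candidates are genes passing the logFC filter (strict:
  $> thres$, $< -thres$, or $|\cdot| > thres$; default $thres = 0$) in at
  least one dataset. Within each dataset the competition runs over the
  candidates *present* in that dataset with their original, unfiltered
  scores: a gene that failed the filter locally still plays, it just tends to
  lose. Genes absent from a dataset contribute zero rows/columns there, so
  $n_{ij}$ counts the datasets containing both $i$ and $j$.

## Rating algorithms

All eight methods consume only $(W, L, n)$ plus, for Elo, the per-dataset
outcome sequence. None uses randomness; given a competition, every rating is
deterministic.

* **Win-loss** $r(i) = \sum_{j:\,n_{ij}>0} w_{ij}/n_{ij}$. Under
  intersection this orders identically to total wins.
* **Massey** solves $Mr = p$ with $M_{ii} = N_i$, $M_{ij} = -n_{ij}$,
  $p_i = W_i - L_i$. For binary outcomes, $p$ is exactly the aggregate of
  game-level point differentials, so the game-by-outcome design matrix is
  never materialized. $M$ is singular (rows sum to zero); the last row is
  replaced by ones and the last entry of $p$ by zero, pinning
  $\sum_i r_i = 0$. If the replaced system is still singular — a disconnected
  competition graph, possible under union — the minimum-norm least-squares
  solution is returned with a warning.
* **Colley** solves $(M + 2I)\,r = b$, $b_i = 1 + (W_i - L_i)/2$. The +2I
  regularization is Laplace's rule of succession; with no games at all every
  rating is exactly 0.5, and in general $\mathbf{1}^\top C r =
  \mathbf{1}^\top b$ forces $\sum_i r_i = N/2$. $C$ is symmetric strictly
  diagonally dominant, hence always uniquely solvable.
* **Keener** skews Laplace-smoothed win proportions
  $a_{ij} = (w_{ij}+1)/(w_{ij}+w_{ji}+2)$ through
  $h(x) = 1/2 + \operatorname{sgn}(x - 1/2)\sqrt{|2x-1|}/2$ and takes the
  Perron eigenvector. Smoothing gives never-played pairs $a_{ij} = 1/2$,
  keeping $K$ entrywise positive off the diagonal and therefore irreducible
  even under union — without it the Perron vector could concentrate on one
  connected component.
* **Elo** processes games sequentially: start 1500, update both players
  simultaneously by $r \mathrel{+}= f(\kappa - \mu)$ with $f = 10$,
  $\mu_{ij} = 1/(1 + 10^{(r_j - r_i)/400})$, $\kappa \in \{1, 0, 1/2\}$.
  Ties here score $\kappa = 1/2$ for both (the tournament's double-win rule
  applies to the matrices, not to Elo's game outcomes, whose own tie code is
  explicit). Because $\mu_{ij} + \mu_{ji} = 1$, tie-free play conserves
  $\sum_i r_i = 1500N$ exactly.
* **Markov** lets the weaker vote for the stronger: $V_{ij} = 1$ iff $i$
  lost at least once to $j$; $P$ row-normalizes $V$ with undefeated
  (dangling) genes given uniform rows. The printed fixed point $r = Pr$ is
  degenerate for a row-stochastic matrix — any constant vector solves it —
  so the implemented rating is the standard one: the stationary distribution
  of the chain (left eigenvector of $P$ at eigenvalue 1), by power iteration.
  A reducible/periodic chain that fails to converge is mixed with the
  uniform chain at weight 0.15 and retried, with a warning.
* **PageRank** walks the loser→winner graph with multiplicity weights
  ($A_{uv} = l_{uv}$), dangling rows uniform, damping $\alpha = 0.85$,
  iterating $r \leftarrow \alpha rZ + (1-\alpha)/N$ from uniform. The
  multiplicity weighting keeps PageRank distinct from Markov's binary votes.
* **BiPageRank** subtracts from the forward score a backward score $r_q$
  computed as PageRank on the edge-reversed, winner→loser graph
  ($A_{uv} = w_{uv}$) with identical damping and dangling rules; the
  "in-neighbor" backward propagation is read in this reversed-graph sense,
  matching the sports-ranking construction it derives from. $r_s = r_p - r_q$
  sums to 0 and is negative for predominantly losing genes.

### Numerical choices

Iterative solvers (Keener, Markov, PageRank) use tolerance `1e-10` on the
max-abs change, cap `max_iter = 10000`, and deterministic uniform
initialization. Keener's power iteration runs on $K + I$ — the shift
preserves the Perron vector but rules out period-2 oscillation for
antisymmetric-like $K$. Candidate ordering is lexicographic (C collation,
locale-independent) everywhere, and reported ranks use the average-rank
convention on ties; Elo's within-dataset match order is lexicographic pairs
in dataset input order. These orderings are arbitrary but fixed: Elo is the
one method whose *values* (not its conservation law) depend on match order,
which is why order-invariance tests exclude it.

## Validation

Leave-one-out cross-validation holds out one dataset per fold as the label
source: positives are its genes with $\mathrm{logFC} > 1$ and adjusted
$p < 0.05$ (strict; mirrored for down, two-sided for absolute). The ranking
is computed from the remaining datasets only. By default the evaluation
universe is the ranked candidates *also present in the held-out table* —
the held-out label of an absent gene is unknowable; pass
`absent_as_negative = TRUE` to score all candidates instead, counting absent
ones as negatives. AUC uses the midrank Mann–Whitney statistic (equal to
trapezoidal ROC integration, asserted against that oracle at 1e-12); AUPR
integrates stepwise with tied-score blocks grouped, and AUPRN divides AUPR
by prevalence so chance sits near 1 under any class imbalance.

The `classical` baseline is binary (DEG in every training dataset where
present); how a binary indicator should yield a full ROC curve is genuinely
ambiguous, and we use the indicator itself as the score — its AUC is then
driven by the single threshold it defines. `count` and `avg_logfc` are the
graded conventional alternatives.

## The synthetic world

`fixture_spec()` defaults state the benchmark world: 200 genes, 4 datasets,
10 planted up-regulated genes at mean |logFC| 2.5 against null noise SD 0.5,
per-gene per-dataset presence probability 0.8. Effect size, noise and counts
follow the recovery experiment's stated design; presence 0.8 is our choice
for a realistic cross-platform overlap (each gene missing from roughly one
dataset in five), fixed once and not tuned. Planted genes are forced into at
least two datasets so they are rankable under union. P-values are a
deterministic monotone transform of |logFC| (two-sided normal tail at the
noise scale) with ~5% lognormal jitter, BH-adjusted per dataset: plausible
joint structure, *not* calibrated hypothesis tests.

What the generator does not emulate: count-level RNA-seq noise,
gene–gene correlation, batch effects, platform-specific dynamic range, or
symbol mismatches. A green recovery test therefore establishes that the
pipeline ranks strong, consistently-signed signals above independent noise
across heterogeneous universes — not that it is robust to correlated
confounding in real cohorts.

## Known limitations

* Elo's rating depends on dataset and pair order; the deterministic order is
  a convention, not a canonical choice.
* The union strategy's candidate list grows with the number of datasets;
  above ~10,000 candidates the dense matrices get slow (a warning points to
  raising `thres`).
* Dataset weighting (by sample size or quality) and margin-of-victory
  scoring are out of scope: outcomes are binary by construction.
* Gene symbols are matched verbatim; upstream identifier harmonization is
  assumed.
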