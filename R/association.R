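#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sorted ascending, `adj_i = min_{j>=i} p_j * m / j`
#' capped at 1, returned in the original order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param m Family size (defaults to `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH", n = m)
}

#' Spearman correlation with t-approximation p-value
#'
#' Ranked Pearson correlation with midrank ties;
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df.  Returns `NA` for
#' constant input.
#'
#' @param x,y Numeric vectors.
#' @return List with `rho`, `p`, `n`.
#' @keywords internal
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    # perfect monotone association: the smallest achievable two-sided
    # permutation p for this n (2 of the n! orderings)
    p_min <- min(1, 2 * exp(-lgamma(n + 1)))
    return(list(rho = rho, p = p_min, n = n))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Pairwise Spearman correlations with BH adjustment
#'
#' All column pairs of `a` against `b` on shared samples; BH adjustment is
#' applied within the declared family (by default the whole block of pairs,
#' matching one correlation-heatmap panel).
#'
#' @param a,b Numeric matrices or data frames with samples as rows (shared
#'   row order).
#' @param family `"block"` (one family for all pairs, default) or `"per_a"`
#'   (one family per column of `a`).
#' @return Data frame: `var_a`, `var_b`, `rho`, `p`, `p_adj`, `family`.
#' @export
spearman_bh <- function(a, b, family = c("block", "per_a")) {
  family <- match.arg(family)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("a and b must share samples")
  grid <- expand.grid(ia = seq_len(ncol(a)), ib = seq_len(ncol(b)))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    st <- spearman_test(a[, grid$ia[k]], b[, grid$ib[k]])
    data.frame(var_a = colnames(a)[grid$ia[k]], var_b = colnames(b)[grid$ib[k]],
               rho = st$rho, p = st$p, stringsAsFactors = FALSE)
  }))
  res$family <- if (family == "block") "block" else res$var_a
  res$p_adj <- NA_real_
  for (f in unique(res$family)) {
    i <- res$family == f & !is.na(res$p)
    res$p_adj[i] <- bh_adjust(res$p[i])
  }
  res
}

#' Correlation network edges above a cutoff
#'
#' Edges with `|rho| >= cutoff`; the sign is retained.  Raising the cutoff
#' always yields a nested subset.
#'
#' @param associations Data frame from [spearman_bh()].
#' @param cutoff Absolute correlation threshold (default 0.6).
#' @return Data frame: `source`, `target`, `rho`, `sign`.
#' @export
correlation_network <- function(associations, cutoff = 0.6) {
  keep <- !is.na(associations$rho) & abs(associations$rho) >= cutoff
  e <- associations[keep, , drop = FALSE]
  data.frame(source = e$var_a, target = e$var_b, rho = e$rho,
             sign = ifelse(e$rho >= 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-timepoint group comparison of index values
#'
#' For each timepoint and index, the exact rank-sum test between Lower and
#' Higher groups.  When both baseline and final values are present, the
#' within-group baseline-to-final change is summarised (median paired change
#' and a paired signed-rank p, flagged exploratory given the group sizes).
#'
#' @param index_values Long data frame from [evaluate_indices()].
#' @param indices Index columns to test (default: all of microbial,
#'   metabolome, combined that are present).
#' @return List with `between` (per timepoint x index test table) and
#'   `within` (per group x index change summary, `NULL` with a single
#'   timepoint).
#' @export
longitudinal_index_comparison <- function(index_values,
                                          indices = intersect(c("microbial",
                                                                "metabolome",
                                                                "combined"),
                                                              names(index_values))) {
  tps <- intersect(TIMEPOINTS, unique(index_values$timepoint))
  between <- do.call(rbind, lapply(tps, function(tp) {
    d <- index_values[index_values$timepoint == tp, ]
    do.call(rbind, lapply(indices, function(ix) {
      rs <- exact_rank_sum(d[[ix]][d$group == "Lower"],
                           d[[ix]][d$group == "Higher"])
      data.frame(timepoint = tp, index = ix, U = rs$U, p = rs$p,
                 method = rs$method, stringsAsFactors = FALSE)
    }))
  }))
  within <- NULL
  if (all(c("bsl", "final") %in% tps)) {
    within <- do.call(rbind, lapply(unique(index_values$group), function(g) {
      do.call(rbind, lapply(indices, function(ix) {
        b <- index_values[index_values$timepoint == "bsl" &
                            index_values$group == g, ]
        f <- index_values[index_values$timepoint == "final" &
                            index_values$group == g, ]
        delta <- f[[ix]][match(b$participant, f$participant)] - b[[ix]]
        pw <- tryCatch(
          suppressWarnings(stats::wilcox.test(delta, exact = FALSE)$p.value),
          error = function(e) NA_real_)
        data.frame(group = g, index = ix, median_change = stats::median(delta),
                   p_paired = pw, note = "exploratory (small n)",
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(between = between, within = within)
}

#' Correlation of final index values with the NPZ-6 change
#'
#' Spearman correlation between each index at the final timepoint and the
#' final-minus-baseline NPZ-6 score, matched by participant.  A constant
#' delta vector yields `NA` (missing), not an error.
#'
#' @param index_values_final Index values at the final timepoint (one row
#'   per participant).
#' @param npz6_delta Named numeric vector of NPZ-6 deltas, names =
#'   participant ids.
#' @param indices Index columns to correlate.
#' @return Data frame: index, rho, p, n.
#' @export
delta_correlation <- function(index_values_final, npz6_delta,
                              indices = intersect(c("microbial", "metabolome",
                                                    "combined"),
                                                  names(index_values_final))) {
  d <- npz6_delta[index_values_final$participant]
  do.call(rbind, lapply(indices, function(ix) {
    st <- spearman_test(index_values_final[[ix]], d)
    data.frame(index = ix, rho = st$rho, p = st$p, n = st$n,
               stringsAsFactors = FALSE)
  }))
}

#' Bray-Curtis PERMANOVA between groups
#'
#' Permutational multivariate ANOVA on the Bray-Curtis dissimilarity matrix
#' (free permutation of sample labels, two-group case), with
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.  Computed with
#' `vegan::vegdist` and `vegan::adonis2`; a degenerate distance matrix with
#' zero total sum of squares returns pseudo-F 0 and p 1.
#'
#' @param species [feature_table] of non-negative abundances.
#' @param classes Two-level factor aligned with rows.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return List with `pseudo_F`, `R2`, `p`, `n_perm`.
#' @export
bray_curtis_permanova <- function(species, classes, n_perm = 999, seed = 1) {
  stopifnot(is_feature_table(species))
  cl <- factor(classes)
  if (nlevels(cl) != 2) stop("two groups required")
  d <- vegan::vegdist(ft_values(species), method = "bray")
  if (sum(d^2) < 1e-12)
    return(list(pseudo_F = 0, R2 = 0, p = 1, n_perm = n_perm))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ cl, permutations = n_perm)
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       n_perm = n_perm)
}

#' Over-representation analysis of a metabolite set
#'
#' Hypergeometric upper-tail enrichment (`P(X >= overlap)`) of a query
#' metabolite set against pathway membership sets, with population size the
#' enrichment universe, followed by BH adjustment across the tested
#' pathways.  Pathways disjoint from the universe are skipped with a
#' warning.
#'
#' @param query Character vector of metabolite ids (must lie in `universe`).
#' @param library Named list of pathway member vectors (see [read_gmt()]).
#' @param universe Character vector of measured, named metabolites.
#' @return Data frame: pathway, set_size (within universe), overlap, p,
#'   p_adj.
#' @export
ora_enrich <- function(query, library, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query metabolites outside the universe: ",
         paste(utils::head(setdiff(query, universe)), collapse = ", "))
  sizes <- vapply(library, function(s) length(intersect(s, universe)), integer(1))
  if (any(sizes == 0)) {
    warning("skipping ", sum(sizes == 0), " pathway(s) disjoint from the universe")
    library <- library[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  if (length(library) == 0)
    return(data.frame(pathway = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), p_adj = numeric(0)))
  N <- length(universe); n <- length(query)
  res <- do.call(rbind, lapply(names(library), function(pw) {
    K <- sizes[[pw]]
    k <- length(intersect(intersect(library[[pw]], universe), query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
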