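# Independent brute-force oracles used to validate the analytical routines.

# Exact two-sided rank-sum p by explicit enumeration of every group
# assignment (independent of the package's distribution-based branch).
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sums <- combn(length(pooled), n1, function(i) sum(r[i]))
  lo <- mean(sums <= obs)
  hi <- mean(sums >= obs)
  min(1, 2 * min(lo, hi))
}

# Step-up BH computed literally from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(p[o][i:m] * m / seq_len(m)[i:m]))
  adj
}

# Hypergeometric upper tail P(X >= k) from binomial coefficients.
brute_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Naive O(n^3) Ward clustering: at each step merge the pair of clusters
# whose union minimises the increase in within-cluster sum of squares.
# Returns the merge sets (as sorted member index vectors) per step.
naive_ward_merges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  ess <- function(members) {
    xs <- X[members, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs), "-")^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets produced by each hclust merge step.
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}

# Small helper: baseline classes of a cohort.
cohort_classes <- function(cohort) {
  md <- cohort$metadata[cohort$metadata$timepoint == "bsl", ]
  factor(md$npz6_group, levels = c("Lower", "Higher"))
}

# Small positive matrix with named dims for feature_table construction.
toy_table <- function(values, kind = "metabolite") {
  m <- as.matrix(values)
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  feature_table(m, kind = kind)
}
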