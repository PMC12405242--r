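test_that("BH adjustment matches hand-stepped cases and a brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("Spearman correlations behave on identities and monotone transforms", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  res <- spearman_bh(cbind(a = x), cbind(b = x))
  expect_equal(res$rho, 1)
  res2 <- spearman_bh(cbind(a = x), cbind(b = -x))
  expect_equal(res2$rho, -1)
  expect_equal(res2$p, 2 / factorial(8), tolerance = 1e-12)

  set.seed(2)
  y <- rnorm(8)
  r1 <- spearman_bh(cbind(a = x), cbind(b = y))
  r2 <- spearman_bh(cbind(a = exp(x)), cbind(b = y^3 + 5 * y))  # monotone maps
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  # constant input gives NA, not an error
  r3 <- spearman_bh(cbind(a = rep(1, 8)), cbind(b = y))
  expect_true(is.na(r3$rho))
})

test_that("null correlation families rarely survive BH adjustment", {
  # n = 30 keeps the t-approximation of the Spearman p accurate in the tail
  set.seed(3)
  fp <- vapply(1:200, function(i) {
    a <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("a", 1:4)))
    b <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("b", 1:5)))
    any(spearman_bh(a, b)$p_adj <= 0.05)
  }, logical(1))
  expect_gte(mean(!fp), 0.95)
})

test_that("correlation networks threshold strictly and nest with the cutoff", {
  assoc <- data.frame(var_a = c("t1", "t2", "t3", "t4"),
                      var_b = c("m1", "m2", "m3", "m4"),
                      rho = c(0.59, -0.65, 0.72, NA),
                      p = c(0.1, 0.02, 0.01, NA),
                      family = "block", p_adj = c(0.2, 0.05, 0.03, NA))
  net6 <- correlation_network(assoc, 0.6)
  expect_setequal(net6$source, c("t2", "t3"))
  expect_equal(net6$sign[net6$source == "t2"], "negative")
  net7 <- correlation_network(assoc, 0.7)
  expect_true(all(net7$source %in% net6$source))
  expect_equal(net7$source, "t3")
})

test_that("per-timepoint index comparisons use the exact test and handle one timepoint", {
  vals <- data.frame(
    sample_id = sprintf("S%02d", 1:18), participant = sprintf("P%02d", 1:18),
    timepoint = "bsl", group = rep(c("Lower", "Higher"), c(3, 15)),
    microbial = c(16:18, 1:15))   # complete separation
  res <- longitudinal_index_comparison(vals, indices = "microbial")
  expect_equal(res$between$p, 2 / 816, tolerance = 1e-12)
  expect_null(res$within)

  # identical group distributions at a null timepoint: p-values calibrated
  # (the exact two-sided p at (3, 15) has P(p > 0.5) = 0.5025, so the
  # median sits at 0.5 up to Monte-Carlo noise and small p's are rare)
  set.seed(5)
  pvals <- vapply(1:200, function(i) {
    vals$microbial <- rnorm(18)
    longitudinal_index_comparison(vals, indices = "microbial")$between$p
  }, numeric(1))
  expect_gt(median(pvals), 0.45)
  expect_lt(abs(mean(pvals <= 0.05) - 40 / 816), 0.03)
})

test_that("within-group change summaries appear when both endpoints exist", {
  co <- simulate_cohort(cohort_config(seed = 23, n_species = 60,
                                      n_metabolites = 4,
                                      n_discriminant_metabolites = 2,
                                      unnamed_fraction = 0))
  cl <- cohort_classes(co)
  fit <- fit_balance_indices(co$tables$bsl$species, NULL, cl)
  tabs <- lapply(co$tables, function(x) list(species = x$species))
  vals <- evaluate_indices(fit, tabs, co$metadata)
  res <- longitudinal_index_comparison(vals)
  expect_equal(nrow(res$between), 3)
  expect_equal(nrow(res$within), 2)
  lower_change <- res$within$median_change[res$within$group == "Lower"]
  expect_lt(lower_change, 0)   # Lower-group index falls as the effect fades
})

test_that("delta-NPZ-6 correlations carry the planted positive coupling", {
  rhos <- vapply(1:30, function(s) {
    co <- simulate_cohort(cohort_config(seed = 900 + s, n_species = 60,
                                        n_metabolites = 4,
                                        n_discriminant_metabolites = 2,
                                        unnamed_fraction = 0))
    cl <- cohort_classes(co)
    fit <- fit_balance_indices(co$tables$bsl$species, NULL, cl)
    tabs <- lapply(co$tables, function(x) list(species = x$species))
    vals <- evaluate_indices(fit, tabs, co$metadata)
    npz <- npz6_results(co$metadata)
    dc <- delta_correlation(vals[vals$timepoint == "final", ],
                            setNames(npz$delta_npz6, npz$participant))
    dc$rho[dc$index == "microbial"]
  }, numeric(1))
  expect_gt(median(rhos), 0)

  # degenerate delta vector: missing, not an error
  vals1 <- data.frame(participant = paste0("P", 1:6), microbial = rnorm(6))
  dc <- delta_correlation(vals1, setNames(rep(0.3, 6), paste0("P", 1:6)),
                          indices = "microbial")
  expect_true(is.na(dc$rho))
})

test_that("PERMANOVA handles degenerate input and detects planted structure", {
  m <- matrix(rep(c(0.2, 0.3, 0.5), each = 8), 8)
  rownames(m) <- paste0("S", 1:8); colnames(m) <- paste0("t", 1:3)
  cl <- factor(rep(c("A", "B"), 4))
  res <- bray_curtis_permanova(feature_table(m, "taxon", normalized = TRUE), cl)
  expect_equal(res$pseudo_F, 0)
  expect_equal(res$p, 1)

  # strong composition shift: a third of the community is 8-fold enriched
  cl2 <- factor(rep(c("Lower", "Higher"), c(3, 15)), c("Lower", "Higher"))
  hits <- vapply(1:10, function(s) {
    set.seed(40 + s)
    m <- matrix(rlnorm(18 * 100, 0, 0.3), 18, 100)
    m[cl2 == "Lower", 1:30] <- m[cl2 == "Lower", 1:30] * 8
    m <- m / rowSums(m)
    rownames(m) <- sprintf("S%02d", 1:18); colnames(m) <- paste0("t", 1:100)
    bray_curtis_permanova(feature_table(m, "taxon", normalized = TRUE), cl2,
                          n_perm = 199, seed = s)$p
  }, numeric(1))
  # the permutation floor up to redraws of the observed partition: with
  # n1 = 3 only 816 distinct partitions exist, so 199 random permutations
  # duplicate the observed one with probability ~0.22 and p lands on
  # 2/200 or 3/200 instead of exactly 1/200
  expect_gte(sum(hits <= 3 / 200), 9)
  expect_gte(sum(hits == 1 / 200), 5)
})

test_that("Bray-Curtis distances are a valid bounded dissimilarity", {
  co <- simulate_cohort(cohort_config(seed = 3, n_species = 50,
                                      n_metabolites = 4,
                                      n_discriminant_metabolites = 2,
                                      unnamed_fraction = 0))
  d <- as.matrix(vegan::vegdist(unclass(co$tables$bsl$species), "bray"))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  lib <- list(pw = paste0("m", 1:5))
  universe <- paste0("m", 1:20)
  res <- ora_enrich(paste0("m", c(1:5, 10:14)), lib, universe)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, choose(15, 5) / choose(20, 10), tolerance = 1e-12)

  res0 <- ora_enrich(paste0("m", 15:18), list(pw = paste0("m", 1:3)), universe)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  expect_warning(
    resd <- ora_enrich("m1", list(good = c("m1", "m2"), far = c("x1", "x2")),
                       universe),
    "disjoint")
  expect_equal(resd$pathway, "good")

  expect_error(ora_enrich("zz", lib, universe), "outside the universe")

  # exhaustive grid against the binomial-coefficient oracle
  for (N in c(8, 15, 25)) {
    uni <- paste0("u", seq_len(N))
    for (K in c(2, 4, min(7, N - 1))) for (n in c(3, 6, min(10, N - 1))) {
      set.seed(N * 100 + K * 10 + n)
      q <- sample(uni, n)
      lib <- list(s = sample(uni, K))
      res <- ora_enrich(q, lib, uni)
      expect_equal(res$p,
                   brute_hyper_tail(res$overlap, K, N, n), tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d", N, K, n))
    }
  }
})
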