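two_class <- function(n1 = 3, n2 = 15)
  factor(rep(c("Lower", "Higher"), c(n1, n2)), levels = c("Lower", "Higher"))

test_that("lefse returns nothing without signal and gates on the KW alpha", {
  set.seed(1)
  base <- matrix(rep(c(0.3, 0.5, 0.2), each = 18), 18)
  rownames(base) <- sprintf("S%02d", 1:18); colnames(base) <- paste0("t", 1:3)
  noisy <- base * matrix(runif(54, 0.95, 1.05), 18)
  ft <- close_rows(feature_table(noisy, "taxon"))
  res <- suppressWarnings(lefse(ft, two_class(), seed = 1))
  expect_equal(nrow(res), 0)

  # a feature whose KW p sits just above alpha is excluded whatever its fold change
  x <- c(100, 90, 6.2,                                   # Lower: huge fold change
         1, 1.5, 2, 2.5, 3, 3.5, 4, 5.5, 6, 6.5, 7, 7.5, 8, 8.5, 9)
  cl <- two_class()
  p_kw <- kruskal_wallis(split(x, cl))$p
  expect_gt(p_kw, 0.05)
  expect_lt(p_kw, 0.10)
  tab <- cbind(t1 = x / 200, t2 = 1 - x / 200)
  rownames(tab) <- sprintf("S%02d", 1:18)
  res2 <- suppressWarnings(lefse(feature_table(tab, "taxon", normalized = TRUE),
                                 cl, seed = 1))
  expect_false("t1" %in% res2$feature)
})

test_that("lefse recovers a planted 1% vs 4% abundance shift with correct direction", {
  cl <- two_class()
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    m <- matrix(rexp(18 * 30, rate = 30), 18, 30)
    m[, 1] <- rlnorm(18, log(ifelse(cl == "Lower", 0.04, 0.01)), 0.4)
    rownames(m) <- sprintf("S%02d", 1:18); colnames(m) <- paste0("t", 1:30)
    ft <- close_rows(feature_table(m, "taxon"))
    res <- suppressWarnings(lefse(ft, cl, seed = s))
    "t1" %in% res$feature && res$direction[res$feature == "t1"] == "Lower"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("lefse direction matches the sign of the class-median difference", {
  co <- simulate_cohort(cohort_config(seed = 9, n_species = 80,
                                      n_metabolites = 4,
                                      n_discriminant_metabolites = 2,
                                      unnamed_fraction = 0))
  cl <- cohort_classes(co)
  res <- suppressWarnings(lefse(co$tables$bsl$species, cl, seed = 9))
  expect_gt(nrow(res), 0)
  v <- unclass(co$tables$bsl$species)
  for (i in seq_len(nrow(res))) {
    f <- res$feature[i]
    dmed <- median(v[cl == "Lower", f]) - median(v[cl == "Higher", f])
    if (dmed != 0)
      expect_equal(res$direction[i], if (dmed > 0) "Lower" else "Higher")
  }
})

test_that("pathway screening applies the global-mean gate and recovers planted shifts", {
  cl <- two_class()
  set.seed(2)
  m <- cbind(rare = rep(0.005, 18), a = runif(18, 0.3, 0.4),
             b = runif(18, 0.55, 0.65))
  m <- m / rowSums(m)
  rownames(m) <- sprintf("S%02d", 1:18)
  res <- pathway_screen(feature_table(m, "pathway", normalized = TRUE), cl)
  expect_false("rare" %in% res$feature)   # below 1% global mean: never tested

  hits <- vapply(1:100, function(s) {
    set.seed(200 + s)
    pd <- rlnorm(18, log(ifelse(cl == "Lower", 0.08, 0.02)), 0.4)
    m <- cbind(pd = pd, other = 1 - pd)
    rownames(m) <- sprintf("S%02d", 1:18)
    res <- pathway_screen(feature_table(m, "pathway", normalized = TRUE), cl)
    "pd" %in% res$feature && res$direction[res$feature == "pd"] == "Lower"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("pathway screening holds its nominal level under the null", {
  cl <- two_class()
  rate <- mean(vapply(1:200, function(s) {
    set.seed(400 + s)
    m <- matrix(rlnorm(18 * 10, log(0.1), 0.5), 18, 10)
    m <- m / rowSums(m)
    rownames(m) <- sprintf("S%02d", 1:18); colnames(m) <- paste0("p", 1:10)
    nrow(pathway_screen(feature_table(m, "pathway", normalized = TRUE), cl)) / 10
  }, numeric(1)))
  expect_lt(abs(rate - 40 / 816), 0.02)
})

test_that("sPLS-DA with keepX = p matches dense PLS-DA from mixOmics on component 1", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  cl <- two_class(9, 9)
  X <- matrix(rnorm(18 * 40), 18)
  X[, 1:5] <- X[, 1:5] + ifelse(cl == "Lower", 1.5, 0)
  colnames(X) <- paste0("m", 1:40); rownames(X) <- sprintf("S%02d", 1:18)
  Z <- scale(X)
  fit <- fit_splsda(Z, cl, n_components = 2, keepX = 40, prescaled = TRUE)
  ref <- mixOmics::plsda(Z, cl, ncomp = 2, scale = FALSE)
  a1 <- fit$W[, 1]; b1 <- ref$loadings$X[, 1]
  expect_gt(abs(sum(a1 * b1)) / sqrt(sum(a1^2) * sum(b1^2)), 1 - 1e-8)
})

test_that("sPLS-DA keeps exactly keepX unit-norm loadings and finds planted features", {
  set.seed(3)
  cl <- two_class(20, 20)
  X <- matrix(rnorm(40 * 500), 40)
  X[, 1:10] <- X[, 1:10] + ifelse(cl == "Lower", 2, 0)
  colnames(X) <- paste0("m", 1:500); rownames(X) <- paste0("S", 1:40)
  ft <- feature_table(exp(X / 3), "metabolite")
  fit <- fit_splsda(ft, cl, n_components = 2, keepX = 10)
  expect_equal(colSums(fit$W != 0), c(comp1 = 10, comp2 = 10))
  expect_equal(colSums(fit$W^2), c(comp1 = 1, comp2 = 1), tolerance = 1e-12)

  found <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 500), 40)
    X[, 1:10] <- X[, 1:10] + ifelse(cl == "Lower", 2, 0)
    colnames(X) <- paste0("m", 1:500); rownames(X) <- paste0("S", 1:40)
    fit <- fit_splsda(scale(X), cl, n_components = 1, keepX = 10,
                      prescaled = TRUE)
    sum(paste0("m", 1:10) %in% fit$kept[[1]])
  }, numeric(1))
  expect_gte(median(found), 9)
})

test_that("kept sets are invariant to feature order and within-class sample order", {
  co <- simulate_cohort(cohort_config(seed = 13, n_species = 20,
                                      n_metabolites = 120,
                                      n_discriminant_metabolites = 16,
                                      unnamed_fraction = 0))
  cl <- cohort_classes(co)
  met <- co$tables$bsl$metabolites
  fit <- fit_splsda(met, cl, keepX = 20)

  perm_f <- sample(ncol(met))
  fit_pf <- fit_splsda(met[, perm_f], cl, keepX = 20)
  expect_setequal(fit$kept[[1]], fit_pf$kept[[1]])

  perm_s <- c(sample(1:3), sample(4:18))   # permute within classes
  fit_ps <- fit_splsda(met[perm_s, ], cl[perm_s], keepX = 20)
  expect_setequal(fit$kept[[1]], fit_ps$kept[[1]])
})

test_that("permuted class labels reduce CV accuracy to the majority rate", {
  set.seed(5)
  cl <- two_class(9, 9)
  X <- matrix(rnorm(18 * 40), 18)
  colnames(X) <- paste0("m", 1:40); rownames(X) <- paste0("S", 1:18)
  acc <- vapply(1:60, function(i) {
    splsda_cv_accuracy(X, sample(cl), n_components = 1, keepX = 10)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.05)
})

test_that("the rank-sum filter excludes kept-but-insignificant variables", {
  co <- simulate_cohort(cohort_config(seed = 17, n_species = 20,
                                      n_metabolites = 200,
                                      n_discriminant_metabolites = 10,
                                      unnamed_fraction = 0))
  cl <- cohort_classes(co)
  met <- co$tables$bsl$metabolites
  model <- fit_splsda(met, cl, keepX = 60)
  res <- splsda_wilcoxon_filter(model, met, cl)
  expect_true(all(res$p < 0.05))
  v <- unclass(met)
  dropped <- setdiff(unique(unlist(model$kept)), res$feature)
  expect_gt(length(dropped), 0)
  for (f in dropped[1:min(5, length(dropped))])
    expect_gte(exact_rank_sum(v[cl == "Lower", f], v[cl == "Higher", f])$p, 0.05)
})

test_that("PC1 shortlisting is threshold-exact, sign-invariant and planted-enriched", {
  co <- simulate_cohort(cohort_config(seed = 19, n_species = 20,
                                      n_metabolites = 150,
                                      n_discriminant_metabolites = 40,
                                      unnamed_fraction = 0))
  cl <- cohort_classes(co)
  planted <- co$tables$bsl$metabolites[, c(co$truth$discriminant_metabolites_up,
                                           co$truth$discriminant_metabolites_down)]
  sel <- suppressWarnings(pca_pc1_select(planted, cl))
  expect_true(all(sel$loadings[sel$positive] > sel$upper))
  expect_true(all(sel$loadings[sel$negative] < sel$lower))
  expect_length(intersect(sel$positive, sel$negative), 0)

  flipped <- suppressWarnings(
    pca_pc1_select(feature_table(1 / unclass(planted), kind = "metabolite"), cl))
  # inverting intensities flips every association; orientation flips with it
  expect_setequal(flipped$negative,
                  names(sel$loadings)[-sel$loadings < flipped$lower])

  counts <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_config(seed = 5000 + s, n_species = 20,
                                        n_metabolites = 150,
                                        n_discriminant_metabolites = 40,
                                        unnamed_fraction = 0))
    cl <- cohort_classes(co)
    keep <- c(co$truth$discriminant_metabolites_up,
              co$truth$discriminant_metabolites_down,
              setdiff(colnames(co$tables$bsl$metabolites),
                      c(co$truth$discriminant_metabolites_up,
                        co$truth$discriminant_metabolites_down))[1:20])
    sel <- suppressWarnings(pca_pc1_select(co$tables$bsl$metabolites[, keep], cl))
    c(pos_up = sum(sel$positive %in% co$truth$discriminant_metabolites_up),
      pos = length(sel$positive),
      neg_dn = sum(sel$negative %in% co$truth$discriminant_metabolites_down),
      neg = length(sel$negative))
  }, numeric(4))
  tot <- rowSums(counts)
  # the positive set is enriched for planted-up metabolites and the negative
  # set for planted-down, relative to their share of the PCA input (20 up,
  # 20 down, 20 null per cohort)
  n_in <- 60 * 40
  p_pos <- fisher.test(matrix(c(tot[["pos_up"]], tot[["pos"]] - tot[["pos_up"]],
                                40 * 20 - tot[["pos_up"]],
                                n_in - 40 * 20 - tot[["pos"]] + tot[["pos_up"]]),
                              2), alternative = "greater")$p.value
  p_neg <- fisher.test(matrix(c(tot[["neg_dn"]], tot[["neg"]] - tot[["neg_dn"]],
                                40 * 20 - tot[["neg_dn"]],
                                n_in - 40 * 20 - tot[["neg"]] + tot[["neg_dn"]]),
                              2), alternative = "greater")$p.value
  expect_lt(p_pos, 0.01)
  expect_lt(p_neg, 0.01)
  expect_gt(tot[["pos_up"]] / tot[["pos"]], 0.6)
  expect_gt(tot[["neg_dn"]] / tot[["neg"]], 0.6)
})

test_that("Ward clustering matches the naive O(n^3) oracle and separates planted groups", {
  set.seed(6)
  m <- matrix(rnorm(5 * 4), 5)
  rownames(m) <- paste0("S", 1:5); colnames(m) <- paste0("f", 1:4)
  hc <- hca(m, scale = FALSE)
  expect_identical(hclust_merge_sets(hc$hclust), naive_ward_merges(m))

  for (trial in 1:100) {
    set.seed(trial)
    m <- matrix(rnorm(6 * 3), 6)
    rownames(m) <- paste0("S", 1:6); colnames(m) <- paste0("f", 1:3)
    hc <- hca(m, scale = FALSE)
    expect_identical(hclust_merge_sets(hc$hclust), naive_ward_merges(m),
                     label = paste("trial", trial))
  }

  # identical samples merge first at height zero
  dup <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9), d = c(8, 9, 10))
  colnames(dup) <- paste0("f", 1:3)
  hc2 <- hca(dup, scale = FALSE)
  expect_equal(hc2$hclust$height[1], 0)
  expect_identical(sort(hclust_merge_sets(hc2$hclust)[[1]]), c(1L, 2L))

  # well-separated planted clusters are recovered by a 2-cut
  set.seed(7)
  m3 <- rbind(matrix(rnorm(12, 0, 0.2), 4), matrix(rnorm(12, 5, 0.2), 4))
  rownames(m3) <- paste0("S", 1:8); colnames(m3) <- paste0("f", 1:3)
  hc3 <- hca(m3, scale = FALSE)
  expect_equal(unname(cutree(hc3$hclust, 2)), rep(c(1, 2), each = 4))
  expect_true(all(diff(hc3$hclust$height) >= -1e-12))
})
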