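#' LEfSe-style discriminant taxon analysis
#'
#' Two-class linear discriminant analysis effect size: features are first
#' screened by a Kruskal-Wallis test at `alpha`; candidates then receive an
#' effect score from repeated balanced subsampling (fraction 2/3 of each
#' class) with a one-dimensional LDA fitted on the candidate set.  Per
#' bootstrap the feature score is the average of the raw class-mean
#' difference and the feature's share of the discriminant-axis class-mean
#' separation, on a parts-per-million abundance scale; the reported LDA
#' score is `log10(max(mean_boot_score, 1))` and features are retained when
#' it exceeds `lda_threshold`.  Direction is the class with the higher
#' median abundance.
#'
#' @param table A compositional [feature_table] (taxa).
#' @param classes Two-level factor/character vector aligned with the rows.
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @param lda_threshold Retention threshold on the log10 effect score
#'   (default 2).
#' @param n_boot Number of subsampling rounds (default 30).
#' @param seed RNG seed for the subsampling.
#' @return A `discriminant_set` data frame: feature, direction, `p`,
#'   `score`, stage.
#' @export
lefse <- function(table, classes, alpha = 0.05, lda_threshold = 2,
                  n_boot = 30, seed = 1) {
  stopifnot(is_feature_table(table))
  cl <- factor(classes)
  if (nlevels(cl) != 2) stop("lefse requires exactly two classes")
  v <- ft_values(table) * 1e6          # original tool's per-million scale
  keep_var <- apply(v, 2, function(col) stats::var(col) > 0)
  if (any(!keep_var)) {
    warning("skipping ", sum(!keep_var), " zero-variance feature(s)")
    v <- v[, keep_var, drop = FALSE]
  }
  if (ncol(v) == 0) return(empty_discriminant_set("lefse"))
  kw_p <- apply(v, 2, function(col)
    kruskal_wallis(split(col, cl))$p)
  cand <- which(kw_p < alpha)
  if (length(cand) == 0) return(empty_discriminant_set("lefse"))
  x <- v[, cand, drop = FALSE]

  set.seed(seed)
  idx <- split(seq_along(cl), cl)
  take <- vapply(idx, function(i) max(2L, as.integer(ceiling(2 / 3 * length(i)))),
                 integer(1))
  scores <- matrix(NA_real_, n_boot, ncol(x))
  for (b in seq_len(n_boot)) {
    sub <- unlist(mapply(function(i, k) sample(i, k), idx, take,
                         SIMPLIFY = FALSE), use.names = FALSE)
    xb <- x[sub, , drop = FALSE]
    cb <- cl[sub]
    # jitter for numerical stability of the within-class scatter
    jit_sd <- pmax(apply(xb, 2, stats::sd), 1e-8) * 0.05
    xb <- xb + sweep(matrix(stats::rnorm(length(xb)), nrow(xb)), 2, jit_sd, "*")
    fit <- tryCatch(suppressWarnings(MASS::lda(xb, grouping = cb)),
                    error = function(e) NULL)
    m1 <- colMeans(xb[cb == levels(cl)[1], , drop = FALSE])
    m2 <- colMeans(xb[cb == levels(cl)[2], , drop = FALSE])
    gm <- abs(m1 - m2)
    if (is.null(fit)) {
      scores[b, ] <- gm
      next
    }
    w <- fit$scaling[, 1]
    w_unit <- w / sqrt(sum(w^2))
    proj <- xb %*% w
    eff <- abs(mean(proj[cb == levels(cl)[1]]) - mean(proj[cb == levels(cl)[2]]))
    coeff <- abs(w_unit * eff)
    scores[b, ] <- (gm + coeff) / 2
  }
  lda_score <- log10(pmax(colMeans(scores, na.rm = TRUE), 1))
  med1 <- apply(x[cl == levels(cl)[1], , drop = FALSE], 2, stats::median)
  med2 <- apply(x[cl == levels(cl)[2], , drop = FALSE], 2, stats::median)
  dir_first <- ifelse(med1 == med2,
                      colMeans(x[cl == levels(cl)[1], , drop = FALSE]) >
                        colMeans(x[cl == levels(cl)[2], , drop = FALSE]),
                      med1 > med2)
  res <- data.frame(feature = colnames(x),
                    direction = ifelse(dir_first, levels(cl)[1], levels(cl)[2]),
                    p = kw_p[cand], score = lda_score, stage = "lefse",
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[res$score > lda_threshold, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("discriminant_set", "data.frame")
  res
}

empty_discriminant_set <- function(stage) {
  res <- data.frame(feature = character(0), direction = character(0),
                    p = numeric(0), score = numeric(0),
                    stage = character(0), stringsAsFactors = FALSE)
  class(res) <- c("discriminant_set", "data.frame")
  res
}

#' Screen abundant microbial pathways for group differences
#'
#' Community-level comparison restricted to pathways whose global mean
#' relative abundance exceeds `mean_threshold` (default 1%); those are
#' tested with the exact rank-sum test and retained at `p < alpha` with the
#' direction of the higher-median class.
#'
#' @param pathways Pathway-level [feature_table].
#' @param classes Two-level factor aligned with rows.
#' @param mean_threshold Global-mean abundance gate (default 0.01).
#' @param alpha Retention level (default 0.05).
#' @return A `discriminant_set` data frame.
#' @export
pathway_screen <- function(pathways, classes, mean_threshold = 0.01,
                           alpha = 0.05) {
  stopifnot(is_feature_table(pathways))
  cl <- factor(classes)
  if (nlevels(cl) != 2) stop("pathway_screen requires exactly two classes")
  v <- ft_values(pathways)
  tested <- which(colMeans(v) > mean_threshold)
  if (length(tested) == 0) return(empty_discriminant_set("pathway_screen"))
  rows <- lapply(tested, function(j) {
    a <- v[cl == levels(cl)[1], j]; b <- v[cl == levels(cl)[2], j]
    rs <- exact_rank_sum(a, b)
    data.frame(feature = colnames(v)[j],
               direction = if (stats::median(a) >= stats::median(b))
                 levels(cl)[1] else levels(cl)[2],
               p = rs$p, score = NA_real_, stage = "pathway_screen",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$p < alpha, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("discriminant_set", "data.frame")
  res
}

#' Sparse PLS-DA with exact-cardinality variable selection
#'
#' Two-class sparse partial least squares discriminant analysis.  Features
#' are autoscaled ([autoscale()]) and the class is coded as a centred +/-1
#' response.  Per component the loading-weight vector is soft-thresholded so
#' that exactly `keepX` entries are non-zero (cardinality convention), then
#' normalised to unit norm; the predictor matrix (and response) are deflated
#' between components.
#'
#' @param metabolites [feature_table] of intensities, or a pre-scaled
#'   numeric matrix (samples x features).
#' @param classes Two-level factor aligned with rows.
#' @param n_components Number of components (default 2).
#' @param keepX Non-zero loadings per component (default 100); values above
#'   the feature count fall back to dense PLS-DA with a message.
#' @param prescaled Set `TRUE` when `metabolites` is already autoscaled.
#' @return An object of class `splsda_model`: unit-norm loading weights
#'   (`W`), x-loadings (`P`), scores (`T`), kept-variable lists, class
#'   centroids on the scores, and the scaling used.
#' @export
fit_splsda <- function(metabolites, classes, n_components = 2, keepX = 100,
                       prescaled = FALSE) {
  cl <- factor(classes)
  if (nlevels(cl) != 2) stop("fit_splsda requires exactly two classes")
  X0 <- if (prescaled && is.matrix(metabolites)) metabolites else autoscale(metabolites)
  p <- ncol(X0)
  if (keepX > p) {
    message("keepX > number of features; fitting dense PLS-DA")
    keepX <- p
  }
  y <- ifelse(cl == levels(cl)[1], 1, -1)
  y <- y - mean(y)
  X <- X0
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(X0), paste0("comp", seq_len(n_components))))
  Tm <- matrix(0, nrow(X0), n_components,
               dimnames = list(rownames(X0), colnames(W)))
  kept <- vector("list", n_components)
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(X, y))
    aw <- abs(w)
    if (keepX < p) {
      lambda <- sort(aw, decreasing = TRUE)[keepX + 1]
      w <- sign(w) * pmax(aw - lambda, 0)
    }
    nz <- which(w != 0)
    if (length(nz) == 0) stop("component ", h, " has no signal left")
    w <- w / sqrt(sum(w^2))
    t_h <- drop(X %*% w)
    p_h <- drop(crossprod(X, t_h)) / sum(t_h^2)
    X <- X - tcrossprod(t_h, p_h)
    y <- y - t_h * sum(t_h * y) / sum(t_h^2)
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h
    kept[[h]] <- colnames(X0)[nz][order(-abs(w[nz]))]   # ranked by |loading|
  }
  centroids <- apply(Tm, 2, function(t) tapply(t, cl, mean))
  structure(list(W = W, P = P, scores = Tm, kept = kept, classes = cl,
                 levels = levels(cl), centroids = centroids,
                 n_components = n_components, keepX = keepX),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("sPLS-DA model: %d components, keepX = %d, classes %s vs %s\n",
              x$n_components, x$keepX, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Predict classes from an sPLS-DA model
#'
#' Nearest class centroid in the component-score space.
#'
#' @param object A `splsda_model`.
#' @param newdata Autoscaled matrix with the training features (defaults to
#'   the training scores).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.splsda_model <- function(object, newdata = NULL, ...) {
  scores <- if (is.null(newdata)) object$scores else {
    # regression coefficients mapping X to scores: W (P'W)^{-1}
    R <- object$W %*% solve(crossprod(object$P, object$W))
    newdata %*% R
  }
  d <- vapply(seq_len(nrow(object$centroids)), function(g)
    rowSums(sweep(scores, 2, object$centroids[g, ], "-")^2), numeric(nrow(scores)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  factor(rownames(object$centroids)[max.col(-d)], levels = object$levels)
}

#' Leave-one-out cross-validated sPLS-DA accuracy
#'
#' @param metabolites [feature_table] or matrix of intensities.
#' @param classes Two-level factor.
#' @param n_components,keepX Passed to [fit_splsda()].
#' @return Fraction of held-out samples classified correctly.
#' @export
splsda_cv_accuracy <- function(metabolites, classes, n_components = 2,
                               keepX = 100) {
  cl <- factor(classes)
  X <- if (is.matrix(metabolites)) metabolites else ft_values(metabolites)
  hits <- vapply(seq_len(nrow(X)), function(i) {
    Xi <- X[-i, , drop = FALSE]
    mu <- colMeans(Xi); s <- apply(Xi, 2, stats::sd); s[s == 0] <- 1
    Zi <- sweep(sweep(Xi, 2, mu, "-"), 2, s, "/")
    fit <- fit_splsda(Zi, cl[-i], n_components, keepX, prescaled = TRUE)
    z_new <- (X[i, ] - mu) / s
    as.character(predict(fit, matrix(z_new, 1))) == as.character(cl[i])
  }, logical(1))
  mean(hits)
}

#' Rank-sum filter of sPLS-DA-selected metabolites
#'
#' The union of variables kept on the model's components is tested with the
#' exact rank-sum test on the (unscaled) intensities; variables with
#' `p < alpha` are retained, with direction given by the higher-median
#' class.  No multiplicity adjustment is applied at this stage.
#'
#' @param model A fitted `splsda_model`.
#' @param metabolites The [feature_table] the model was fitted on.
#' @param classes Two-level factor aligned with rows.
#' @param alpha Retention level (default 0.05).
#' @return A `discriminant_set` data frame with the loading weight of each
#'   retained metabolite in `score`.
#' @export
splsda_wilcoxon_filter <- function(model, metabolites, classes, alpha = 0.05) {
  stopifnot(inherits(model, "splsda_model"))
  cl <- factor(classes)
  v <- ft_values(metabolites)
  cand <- unique(unlist(model$kept))
  rows <- lapply(cand, function(f) {
    a <- v[cl == levels(cl)[1], f]; b <- v[cl == levels(cl)[2], f]
    rs <- exact_rank_sum(a, b)
    w <- model$W[f, ]
    data.frame(feature = f,
               direction = if (stats::median(a) >= stats::median(b))
                 levels(cl)[1] else levels(cl)[2],
               p = rs$p, score = w[which.max(abs(w))],
               stage = "splsda_wilcoxon", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$p < alpha, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("discriminant_set", "data.frame")
  res
}

#' Shortlist metabolites by signed PC1 loading
#'
#' PCA on the autoscaled discriminant metabolites; the PC1 axis is oriented
#' so that the Lower-group mean score is positive, making the signed
#' thresholds reproducible.  Loadings are reported in the factor-analytic
#' standardized convention — the signed correlation between each metabolite
#' and the PC1 score, as drawn by mixOmics-style variable plots — rather
#' than as unit-norm rotation coordinates, whose magnitude is bounded near
#' `1/sqrt(k)` for k co-selected features and cannot reach fixed thresholds
#' like 0.15 once a few dozen discriminant features are involved.
#' Metabolites with loading above `upper` form the positive (Lower-elevated)
#' set, those below `lower` the negative set.  A warning is issued when PC1
#' explains less than 20% of the variance.
#'
#' @param metabolites [feature_table] restricted to discriminant
#'   metabolites (>= 2 features).
#' @param classes Two-level factor with levels `Lower`, `Higher` (first
#'   level used for orientation).
#' @param upper,lower Signed loading thresholds (defaults 0.15 and -0.10).
#' @return List of class `pc1_selection`: `loadings`, `positive`,
#'   `negative`, `var_share`.
#' @export
pca_pc1_select <- function(metabolites, classes, upper = 0.15, lower = -0.10) {
  cl <- factor(classes)
  Z <- autoscale(metabolites)
  if (ncol(Z) < 2) stop("need at least two features for PCA")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  score1 <- pc$x[, 1]
  if (mean(score1[cl == levels(cl)[1]]) < 0)   # orient: first level positive
    score1 <- -score1
  load1 <- drop(stats::cor(Z, score1))          # standardized loadings
  names(load1) <- colnames(Z)
  var_share <- pc$sdev[1]^2 / sum(pc$sdev^2)
  if (var_share < 0.20)
    warning(sprintf("PC1 explains only %.1f%% of the variance", 100 * var_share))
  structure(list(loadings = load1,
                 positive = names(load1)[load1 > upper],
                 negative = names(load1)[load1 < lower],
                 var_share = var_share,
                 upper = upper, lower = lower),
            class = "pc1_selection")
}

#' @export
print.pc1_selection <- function(x, ...) {
  cat(sprintf("PC1 selection: %d positive (> %.2f), %d negative (< %.2f); PC1 var share %.1f%%\n",
              length(x$positive), x$upper, length(x$negative), x$lower,
              100 * x$var_share))
  invisible(x)
}

#' Hierarchical clustering with Euclidean distance and Ward linkage
#'
#' Agglomerative clustering of samples (or features) on autoscaled values,
#' Euclidean distance, Ward's minimum-variance criterion (`ward.D2`, i.e.
#' the classical Ward algorithm on untransformed Euclidean distances).
#'
#' @param metabolites [feature_table] (>= 2 samples) or numeric matrix.
#' @param margin Cluster `"samples"` (default) or `"features"`.
#' @param scale Autoscale before clustering (default `TRUE`).
#' @return List of class `hca_result`: the `hclust` object and the leaf
#'   order (labels).
#' @export
hca <- function(metabolites, margin = c("samples", "features"), scale = TRUE) {
  margin <- match.arg(margin)
  v <- if (is_feature_table(metabolites)) {
    if (scale) autoscale(metabolites) else ft_values(metabolites)
  } else as.matrix(metabolites)
  if (margin == "features") v <- t(v)
  if (nrow(v) < 2) stop("need at least two observations to cluster")
  hc <- stats::hclust(stats::dist(v), method = "ward.D2")
  structure(list(hclust = hc, order = hc$labels[hc$order], margin = margin),
            class = "hca_result")
}
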