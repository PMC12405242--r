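#' Log-ratio balance index definition
#'
#' A balance index is the natural log of the ratio of geometric means of two
#' disjoint, non-empty feature sets: features enriched in the Lower NPZ-6
#' group (numerator) over features enriched in the Higher group
#' (denominator).  Definitions are frozen once built at baseline and applied
#' unchanged at later timepoints.
#'
#' @param name One of `"microbial"`, `"metabolome"`, `"combined"`.
#' @param numerator,denominator Disjoint, non-empty character vectors of
#'   feature ids.
#' @return An object of class `index_definition`.
#' @export
index_definition <- function(name = c("microbial", "metabolome", "combined"),
                             numerator, denominator) {
  name <- match.arg(name)
  numerator <- unique(as.character(numerator))
  denominator <- unique(as.character(denominator))
  if (length(numerator) == 0)
    stop(name, " index undefined: empty numerator (no Lower-enriched features)")
  if (length(denominator) == 0)
    stop(name, " index undefined: empty denominator (no Higher-enriched features)")
  overlap <- intersect(numerator, denominator)
  if (length(overlap) > 0)
    stop(name, " index: features in both numerator and denominator: ",
         paste(overlap, collapse = ", "))
  structure(list(name = name, numerator = numerator, denominator = denominator),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat(sprintf("%s index: ln(gm of %d Lower-enriched / gm of %d Higher-enriched)\n",
              x$name, length(x$numerator), length(x$denominator)))
  invisible(x)
}

#' Build the microbial index from the baseline species table
#'
#' Species are compared between the Lower and Higher groups with the exact
#' rank-sum test; species with `p < alpha` and higher median abundance in
#' the Lower group form the numerator, those with higher median in the
#' Higher group the denominator.  An empty side makes the index undefined,
#' which is an error.
#'
#' @param species_bsl Baseline species [feature_table].
#' @param classes Factor with levels `Lower`, `Higher` aligned with rows.
#' @param alpha Selection level (default 0.05).
#' @return An `index_definition` named `"microbial"`.
#' @export
build_microbial_index <- function(species_bsl, classes, alpha = 0.05) {
  stopifnot(is_feature_table(species_bsl))
  cl <- factor(classes, levels = c("Lower", "Higher"))
  if (any(is.na(cl))) stop("classes must be 'Lower' or 'Higher'")
  v <- ft_values(species_bsl)
  num <- character(0); den <- character(0)
  for (j in seq_len(ncol(v))) {
    a <- v[cl == "Lower", j]; b <- v[cl == "Higher", j]
    if (stats::var(c(a, b)) == 0) next
    if (exact_rank_sum(a, b)$p < alpha) {
      if (stats::median(a) > stats::median(b)) num <- c(num, colnames(v)[j])
      else den <- c(den, colnames(v)[j])
    }
  }
  index_definition("microbial", num, den)
}

#' Build the metabolome index from a PC1 selection
#'
#' The PC1 set aligned with Lower-group elevation (positive loadings under
#' the Lower-positive orientation) becomes the numerator, the negative set
#' the denominator.
#'
#' @param pc1_selection A [pca_pc1_select()] result.
#' @return An `index_definition` named `"metabolome"`.
#' @export
build_metabolome_index <- function(pc1_selection) {
  stopifnot(inherits(pc1_selection, "pc1_selection"))
  index_definition("metabolome", pc1_selection$positive, pc1_selection$negative)
}

#' Build the combined index
#'
#' Merges numerators and denominators of the microbial and metabolome
#' indices; a feature appearing on both sides after the merge is an error.
#'
#' @param microbial,metabolome `index_definition`s.
#' @return An `index_definition` named `"combined"`.
#' @export
build_combined_index <- function(microbial, metabolome) {
  stopifnot(inherits(microbial, "index_definition"),
            inherits(metabolome, "index_definition"))
  index_definition("combined",
                   union(microbial$numerator, metabolome$numerator),
                   union(microbial$denominator, metabolome$denominator))
}

#' Compute a balance index for each sample
#'
#' `ln( gm(numerator abundances) / gm(denominator abundances) )` per sample,
#' with geometric means over the definition's feature sets.  Zeros are
#' replaced by half the smallest non-zero value of the corresponding table
#' (per table, not per feature).  For the combined index, pass all source
#' tables; each feature is looked up in the table that contains it.  The
#' value is invariant to any per-sample rescaling of a table.
#'
#' @param tables A [feature_table] or list of feature_tables sharing sample
#'   ids.
#' @param definition An `index_definition`.
#' @return Named numeric vector of index values per sample.
#' @export
compute_index <- function(tables, definition) {
  stopifnot(inherits(definition, "index_definition"))
  if (is_feature_table(tables)) tables <- list(tables)
  samples <- rownames(tables[[1]])
  for (tb in tables)
    if (!identical(rownames(tb), samples))
      stop("all tables must share the same samples in the same order")
  feats <- c(definition$numerator, definition$denominator)
  logv <- matrix(NA_real_, length(samples), length(feats),
                 dimnames = list(samples, feats))
  for (tb in tables) {
    v <- ft_values(tb)
    pos <- v[v > 0]
    pseudo <- if (length(pos)) min(pos) / 2 else
      stop("all-zero table in compute_index")
    hit <- intersect(colnames(v), feats)
    if (length(hit)) {
      vv <- v[, hit, drop = FALSE]
      vv[vv == 0] <- pseudo
      logv[, hit] <- log(vv)
    }
  }
  missing <- feats[apply(logv, 2, function(x) any(is.na(x)))]
  if (length(missing) > 0)
    stop("features missing from the supplied tables: ",
         paste(missing, collapse = ", "))
  rowMeans(logv[, definition$numerator, drop = FALSE]) -
    rowMeans(logv[, definition$denominator, drop = FALSE])
}

#' Fit baseline balance indices for neurocognitive status
#'
#' The package's central estimator.  At baseline it (i) selects discriminant
#' species with the exact rank-sum test and freezes the microbial index,
#' (ii) runs sparse PLS-DA (`keepX` per component) followed by the rank-sum
#' filter on metabolites, shortlists them by signed PC1 loading and freezes
#' the metabolome index, and (iii) merges both into the combined index.  The
#' fitted object predicts per-sample index values at any timepoint from the
#' frozen definitions.
#'
#' @param species_bsl Baseline species [feature_table].
#' @param metabolites_bsl Baseline metabolite [feature_table] (or `NULL` to
#'   fit the microbial index only).
#' @param classes Factor with levels `Lower`, `Higher` aligned with rows.
#' @param alpha Rank-sum selection level for both omics (default 0.05).
#' @param n_components,keepX sPLS-DA settings (defaults 2 and 100).
#' @param pc1_upper,pc1_lower Signed PC1 loading thresholds (defaults 0.15,
#'   -0.10).
#' @param named_only Restrict the metabolite cascade to named metabolites,
#'   excluding `X-`-prefixed unnamed biochemicals (default `TRUE`).
#' @return An object of class `balance_fit` with components `indices` (list
#'   of `index_definition`s), `discriminant` (per-stage selections),
#'   `baseline` (per-sample baseline index values) and the call settings.
#' @export
fit_balance_indices <- function(species_bsl, metabolites_bsl, classes,
                                alpha = 0.05, n_components = 2, keepX = 100,
                                pc1_upper = 0.15, pc1_lower = -0.10,
                                named_only = TRUE) {
  cl <- factor(classes, levels = c("Lower", "Higher"))
  microbial <- build_microbial_index(species_bsl, cl, alpha = alpha)
  indices <- list(microbial = microbial)
  disc <- list()
  if (!is.null(metabolites_bsl)) {
    met <- metabolites_bsl
    if (named_only) {
      named <- !startsWith(colnames(met), "X-")
      met <- met[, named]
    }
    model <- fit_splsda(met, cl, n_components = n_components, keepX = keepX)
    filtered <- splsda_wilcoxon_filter(model, met, cl, alpha = alpha)
    if (nrow(filtered) < 2)
      stop("fewer than two discriminant metabolites; metabolome index undefined")
    sel <- pca_pc1_select(met[, filtered$feature], cl,
                          upper = pc1_upper, lower = pc1_lower)
    metabolome <- build_metabolome_index(sel)
    indices$metabolome <- metabolome
    indices$combined <- build_combined_index(microbial, metabolome)
    disc <- list(splsda = model, metabolites = filtered, pc1 = sel)
  }
  tables_bsl <- c(list(species_bsl),
                  if (!is.null(metabolites_bsl)) list(metabolites_bsl))
  baseline <- data.frame(sample_id = rownames(species_bsl),
                         group = as.character(cl),
                         stringsAsFactors = FALSE)
  for (nm in names(indices))
    baseline[[nm]] <- compute_index(tables_bsl, indices[[nm]])
  structure(list(indices = indices, discriminant = disc, baseline = baseline,
                 alpha = alpha, keepX = keepX, n_components = n_components,
                 pc1_upper = pc1_upper, pc1_lower = pc1_lower),
            class = "balance_fit")
}

#' @export
print.balance_fit <- function(x, ...) {
  cat("Baseline-frozen balance indices\n")
  for (d in x$indices) print(d)
  invisible(x)
}

#' @export
summary.balance_fit <- function(object, ...) {
  cat("Baseline-frozen balance indices (ln gm-ratio, Lower-enriched over",
      "Higher-enriched)\n\n")
  for (d in object$indices) {
    cat(sprintf("%s index\n  numerator  (%d): %s\n  denominator(%d): %s\n",
                d$name, length(d$numerator),
                paste(utils::head(d$numerator, 5), collapse = ", "),
                length(d$denominator),
                paste(utils::head(d$denominator, 5), collapse = ", ")))
  }
  agg <- stats::aggregate(object$baseline[names(object$indices)],
                          by = list(group = object$baseline$group), stats::median)
  cat("\nBaseline median index by group:\n")
  print(agg, row.names = FALSE)
  invisible(object)
}

#' @export
coef.balance_fit <- function(object, ...) {
  lapply(object$indices, function(d)
    list(numerator = d$numerator, denominator = d$denominator))
}

#' Evaluate frozen indices on new samples
#'
#' @param object A `balance_fit`.
#' @param species Species [feature_table] for the target samples.
#' @param metabolites Metabolite [feature_table] (required when the fit has
#'   metabolome/combined indices).
#' @param ... Unused.
#' @return Data frame with one row per sample and one column per index.
#' @export
predict.balance_fit <- function(object, species, metabolites = NULL, ...) {
  tables <- c(list(species), if (!is.null(metabolites)) list(metabolites))
  out <- data.frame(sample_id = rownames(species), stringsAsFactors = FALSE)
  for (nm in names(object$indices)) {
    if (nm != "microbial" && is.null(metabolites))
      stop("metabolite table required to evaluate the ", nm, " index")
    out[[nm]] <- compute_index(tables, object$indices[[nm]])
  }
  out
}

#' Boxplot of index values by group and timepoint
#'
#' @param x A data frame of index values as returned by
#'   [evaluate_indices()].
#' @param index Which index column to plot.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_index_values <- function(x, index = "microbial", ...) {
  if (!index %in% names(x)) stop("no such index column: ", index)
  x$timepoint <- factor(x$timepoint, levels = TIMEPOINTS)
  graphics::boxplot(x[[index]] ~ x$group + x$timepoint,
                    xlab = "group.timepoint", ylab = paste(index, "index"), ...)
  invisible(x)
}

#' Evaluate indices across all timepoints of a cohort
#'
#' @param fit A `balance_fit`.
#' @param tables Per-timepoint list of `list(species=, metabolites=)` as in
#'   a `synthetic_cohort`.
#' @param metadata Cohort metadata (sample_id, participant, timepoint,
#'   npz6_group).
#' @return Long data frame: sample, participant, timepoint, group, one
#'   column per index.
#' @export
evaluate_indices <- function(fit, tables, metadata) {
  stopifnot(inherits(fit, "balance_fit"))
  rows <- lapply(names(tables), function(tp) {
    tb <- tables[[tp]]
    pr <- predict(fit, tb$species, tb$metabolites)
    pr$timepoint <- tp
    pr
  })
  out <- do.call(rbind, rows)
  m <- match(out$sample_id, metadata$sample_id)
  if (anyNA(m)) stop("samples missing from metadata")
  out$participant <- metadata$participant[m]
  out$group <- metadata$npz6_group[m]
  out
}
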