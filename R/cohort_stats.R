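#' NPZ-6 composite score
#'
#' Arithmetic mean of six standardized cognitive-domain z-scores
#' (attention/working memory, processing speed, memory/learning, executive
#' function, verbal fluency, motor function).
#'
#' @param domains Numeric vector of exactly six finite z-scores.
#' @return The composite score.
#' @export
npz6_score <- function(domains) {
  domains <- as.numeric(domains)
  if (length(domains) != 6) stop("NPZ-6 requires exactly six domain z-scores")
  if (any(!is.finite(domains))) stop("domain z-scores must be finite")
  mean(domains)
}

#' Classify NPZ-6 performance group
#'
#' `Lower` iff the score is at or below the threshold (boundary closed on
#' the impaired side), else `Higher`.
#'
#' @param score NPZ-6 composite score(s).
#' @param threshold Classification threshold (default -0.5).
#' @return Character vector of `"Lower"` / `"Higher"`.
#' @export
classify_group <- function(score, threshold = -0.5) {
  if (any(!is.finite(score))) stop("score must be finite")
  ifelse(score <= threshold, "Lower", "Higher")
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(k-1), with
#' upper-tail p from the chi-square distribution.  All-zero columns are
#' dropped with a warning; an all-zero table is an error.
#'
#' @param tab Matrix of non-negative counts (groups as rows).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (all(tab == 0)) stop("all-zero contingency table")
  if (any(rowSums(tab) == 0)) stop("every group must have a positive total")
  zero_col <- colSums(tab) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " all-zero column(s)")
    tab <- tab[, !zero_col, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("need at least two non-empty categories")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Exact two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' For small samples (n1 + n2 <= `exact_max`) without ties, the p-value is
#' computed from the exact null distribution of U over all
#' `choose(n1 + n2, n1)` group assignments; two-sided p is twice the smaller
#' tail probability, capped at 1.  Otherwise a normal approximation with
#' midrank tie correction (and, by default, continuity correction) is used.
#' Degenerate all-tied input returns p = 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Largest total sample size for the exact branch
#'   (default 20).
#' @param correct Continuity correction in the approximate branch
#'   (default `TRUE`).
#' @return List with `U` (Mann-Whitney U of `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
exact_rank_sum <- function(x, y, exact_max = 20, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= exact_max) {
    # exact Mann-Whitney null distribution == full enumeration of assignments
    lo <- stats::pwilcox(U, n1, n2)
    hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  N <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  d <- U - mu
  if (correct) d <- sign(d) * max(abs(d) - 0.5, 0)
  z <- d / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on g - 1 degrees of
#' freedom.  With two groups the p-value agrees with the uncorrected
#' normal-approximation rank-sum test on the same data.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need at least two non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  res <- stats::kruskal.test(values, g)
  list(H = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Group descriptive comparisons
#'
#' Table-1-style comparison of metadata variables between the two NPZ-6
#' groups: categorical variables by Pearson chi-square (no continuity
#' correction), continuous variables by the exact rank-sum test with median
#' and IQR (linear-interpolation quartiles) per group.  Constant variables
#' are flagged.
#'
#' @param metadata Data frame with an `npz6_group` column.
#' @param variables Named character vector mapping variable names to
#'   `"categorical"` or `"continuous"`.  Default: all non-structural columns,
#'   typed by class.
#' @return Data frame with one row per variable: type, statistic, p, and
#'   per-group summaries.
#' @export
group_descriptives <- function(metadata, variables = NULL) {
  if (!"npz6_group" %in% names(metadata)) stop("metadata needs an npz6_group column")
  grp <- factor(metadata$npz6_group, levels = c("Lower", "Higher"))
  if (is.null(variables)) {
    skip <- c("sample_id", "participant", "timepoint", "npz6_group")
    vars <- setdiff(names(metadata), skip)
    variables <- stats::setNames(
      ifelse(vapply(metadata[vars], is.numeric, logical(1)),
             "continuous", "categorical"), vars)
  }
  rows <- lapply(names(variables), function(v) {
    vals <- metadata[[v]]
    if (is.null(vals)) stop("no such variable: ", v)
    type <- match.arg(variables[[v]], c("categorical", "continuous"))
    if (length(unique(vals)) == 1) {
      return(data.frame(variable = v, type = type, statistic = NA_real_,
                        p = NA_real_, lower_summary = as.character(vals[1]),
                        higher_summary = as.character(vals[1]),
                        note = "constant", stringsAsFactors = FALSE))
    }
    if (type == "categorical") {
      tab <- table(grp, vals)
      ct <- chi_square_test(tab)
      fmt <- function(g) paste(sprintf("%s:%d (%.0f%%)", colnames(tab), tab[g, ],
                                       100 * tab[g, ] / sum(tab[g, ])),
                               collapse = "; ")
      data.frame(variable = v, type = type, statistic = ct$statistic, p = ct$p,
                 lower_summary = fmt("Lower"), higher_summary = fmt("Higher"),
                 note = "", stringsAsFactors = FALSE)
    } else {
      rs <- exact_rank_sum(vals[grp == "Lower"], vals[grp == "Higher"])
      smry <- function(x) sprintf("%.3g (%.3g - %.3g)", stats::median(x),
                                  stats::quantile(x, 0.25, type = 7),
                                  stats::quantile(x, 0.75, type = 7))
      data.frame(variable = v, type = type, statistic = rs$U, p = rs$p,
                 lower_summary = smry(vals[grp == "Lower"]),
                 higher_summary = smry(vals[grp == "Higher"]),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Per-participant NPZ-6 results
#'
#' Computes the NPZ-6 composite from the six domain columns at each
#' timepoint, the group label at baseline, and the final-minus-baseline
#' delta.
#'
#' @param metadata Cohort metadata with domain columns and timepoints.
#' @param threshold Classification threshold (default -0.5).
#' @return Data frame, one row per participant: baseline NPZ-6, group,
#'   final NPZ-6, `delta_npz6`.
#' @export
npz6_results <- function(metadata, threshold = -0.5) {
  need <- DOMAINS
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stop("metadata missing domain columns: ",
                             paste(miss, collapse = ", "))
  score <- apply(metadata[, DOMAINS], 1, npz6_score)
  bsl <- metadata$timepoint == "bsl"
  fin <- metadata$timepoint == "final"
  out <- data.frame(participant = metadata$participant[bsl],
                    npz6_bsl = score[bsl],
                    group = classify_group(score[bsl], threshold),
                    stringsAsFactors = FALSE)
  if (any(fin)) {
    fi <- match(out$participant, metadata$participant[fin])
    out$npz6_final <- score[fin][fi]
    out$delta_npz6 <- out$npz6_final - out$npz6_bsl
  }
  out
}
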