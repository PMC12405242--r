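#' Sample-by-feature abundance table
#'
#' Lightweight container used throughout the package: a numeric matrix with
#' samples as rows and features as columns, tagged with the kind of feature
#' it holds and whether rows are compositional (sum to one).
#'
#' @param values Numeric matrix, samples x features, non-negative.  Row names
#'   are sample ids, column names are feature ids; both must be unique.
#' @param kind One of `"taxon"`, `"pathway"`, `"metabolite"`.
#' @param normalized Logical; `TRUE` when every row sums to 1 (checked to a
#'   tolerance of `1e-6`).  If `NA` (default) the flag is inferred from the
#'   data.
#'
#' @return An object of class `feature_table`: the matrix with attributes
#'   `kind` and `normalized`.
#' @export
feature_table <- function(values, kind = c("taxon", "pathway", "metabolite"),
                          normalized = NA) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature_table needs sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (anyNA(values)) stop("feature_table values must be finite")
  rs <- rowSums(values)
  if (is.na(normalized)) normalized <- all(abs(rs - 1) <= 1e-6)
  if (isTRUE(normalized) && any(abs(rs - 1) > 1e-6))
    stop("normalized = TRUE but some rows do not sum to 1")
  structure(values, kind = kind, normalized = normalized,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d samples x %d features%s\n",
              attr(x, "kind"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) ", compositional" else ""))
  invisible(x)
}

#' @rdname feature_table
#' @param x Object to test.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

# Subset while keeping class/attributes; drop = FALSE enforced.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  v <- NextMethod(drop = FALSE)
  structure(v, kind = attr(x, "kind"), normalized = FALSE,
            class = class(x))
}

ft_values <- function(x) {
  v <- unclass(x)
  attr(v, "kind") <- NULL
  attr(v, "normalized") <- NULL
  v
}

#' Close a table to relative abundances
#'
#' Divides each row by its sum so rows sum to one.  Rows with zero total are
#' an error.
#'
#' @param x A `feature_table`.
#' @return A normalized `feature_table`.
#' @export
close_rows <- function(x) {
  stopifnot(is_feature_table(x))
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("cannot normalize: a sample has zero total abundance")
  feature_table(ft_values(x) / rs, kind = attr(x, "kind"), normalized = TRUE)
}

#' Autoscale metabolite intensities
#'
#' Standard preprocessing ahead of sPLS-DA, PCA and hierarchical clustering:
#' per-feature median scaling, natural-log transform, then per-feature
#' centring and unit-variance scaling.  Zeros are replaced by half the
#' smallest positive value of the table before the log.
#'
#' @param x A `feature_table` of positive intensities.
#' @param scale Logical; divide by the per-feature standard deviation
#'   (default `TRUE`).  Constant features scale to zero, not `NaN`.
#' @return A plain numeric matrix, samples x features.
#' @export
autoscale <- function(x, scale = TRUE) {
  stopifnot(is_feature_table(x) || is.matrix(x))
  v <- if (is_feature_table(x)) ft_values(x) else x
  med <- apply(v, 2, stats::median)
  med[med <= 0] <- 1
  v <- sweep(v, 2, med, "/")
  pos <- v[v > 0]
  if (length(pos) == 0) stop("all-zero table cannot be autoscaled")
  v[v <= 0] <- min(pos) / 2
  v <- log(v)
  v <- sweep(v, 2, colMeans(v), "-")
  if (scale) {
    s <- apply(v, 2, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    v <- sweep(v, 2, s, "/")
  }
  v
}
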