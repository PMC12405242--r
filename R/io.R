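#' Read a feature table from TSV
#'
#' Reads MetaPhlAn/HUMAnN-style tables: features as rows, samples as columns,
#' first header field `feature_id` (any first header token is accepted when
#' `orientation` is given explicitly).  Tables whose per-sample totals are
#' ~100 are interpreted as percentages and divided by 100 (MetaPhlAn
#' convention, tolerance 1e-3 relative); totals ~1 mark the table as
#' compositional.  MetaPhlAn pipe-delimited clade strings are accepted; with
#' `species_only = TRUE` only rows whose last clade component starts with
#' `s__` are kept and ids are shortened to that component.
#'
#' @param path Path to a TSV file.
#' @param kind Feature kind: `"taxon"`, `"pathway"` or `"metabolite"`.
#' @param orientation `"features"` (rows are features; default, auto-detected
#'   from the `feature_id` header token) or `"samples"`.
#' @param species_only Keep only species-level (`s__`) clades (taxa only).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, kind = c("taxon", "pathway", "metabolite"),
                               orientation = NULL, species_only = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs at least one id and one value column")
  header1 <- names(df)[1]
  if (is.null(orientation)) {
    orientation <- if (identical(header1, "feature_id")) "features"
    else if (identical(header1, "sample_id")) "samples"
    else stop("cannot auto-detect orientation: first header field is '", header1,
              "' (expected 'feature_id' or 'sample_id'); pass orientation=")
  }
  orientation <- match.arg(orientation, c("features", "samples"))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)   # in memory: samples x features
  if (species_only && kind == "taxon") {
    last <- vapply(strsplit(colnames(m), "|", fixed = TRUE),
                   function(p) p[length(p)], character(1))
    keep <- startsWith(last, "s__")
    m <- m[, keep, drop = FALSE]
    colnames(m) <- last[keep]
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at feature '%s', sample '%s' in %s",
                 colnames(m)[neg[1, 2]], rownames(m)[neg[1, 1]], path))
  rs <- rowSums(m)
  normalized <- NA
  if (kind %in% c("taxon", "pathway") && all(rs > 0)) {
    if (all(abs(rs / 100 - 1) <= 1e-3)) {      # percent convention
      m <- m / rs
      normalized <- TRUE
    } else if (all(abs(rs - 1) <= 1e-3)) {
      m <- m / rs
      normalized <- TRUE
    }
  }
  feature_table(m, kind = kind, normalized = normalized)
}

#' Write a feature table to TSV
#'
#' Features as rows, samples as columns, header `feature_id` then sample ids;
#' full double precision.
#'
#' @param x A [feature_table].
#' @param path Output path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(is_feature_table(x))
  v <- t(ft_values(x))                          # features as rows on disk
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' One row per sample with participant id, timepoint (`bsl`, `post`,
#' `final`), NPZ-6 group (`Lower`, `Higher`), sex, intervention arm, the six
#' cognitive-domain z-scores and the functional outcome scales.
#'
#' @param path Path to a metadata TSV.
#' @return A `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant", "timepoint", "npz6_group")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(md$timepoint), c("bsl", "post", "final"))
  if (length(bad) > 0) stop("unknown timepoint labels: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(md$npz6_group), c("Lower", "Higher"))
  if (length(bad) > 0) stop("unknown group labels: ", paste(bad, collapse = ", "))
  md
}

#' Read a GMT pathway library
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.  Blank lines are skipped with a warning; duplicate members
#' within a set are collapsed with a warning; a named line with no members
#' is an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of member ids, with the
#'   descriptions in attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning("skipping ", sum(blank), " blank line(s) in ", path)
    lines <- lines[!blank]
  }
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character(0)
  for (p in parts) {
    if (length(p) < 3 || !any(nzchar(p[-(1:2)])))
      stop("GMT set '", p[1], "' has no members")
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members collapsed in set '", p[1], "'")
      members <- unique(members)
    }
    sets[[p[1]]] <- members
    desc[p[1]] <- p[2]
  }
  attr(sets, "description") <- desc
  sets
}
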