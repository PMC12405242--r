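#' Default pipeline thresholds
#'
#' Every numeric threshold used by the pipeline stages, overridable from the
#' run configuration and echoed to the run log.
#' @return Named list of defaults.
#' @export
default_thresholds <- function() {
  list(npz6_threshold = -0.5, alpha = 0.05, lda_threshold = 2, n_boot = 30,
       mean_threshold = 0.01, n_components = 2, keepX = 100,
       pc1_upper = 0.15, pc1_lower = -0.10, cor_cutoff = 0.6, n_perm = 999)
}

#' Run the full analysis pipeline
#'
#' End-to-end run over on-disk tables: group descriptives, Bray-Curtis
#' PERMANOVA, LEfSe-style species analysis, optional pathway screening,
#' the metabolite selection cascade, baseline-frozen balance indices,
#' longitudinal comparisons, index-outcome associations, the
#' microbiome-metabolome correlation network and (given a GMT library)
#' metabolite set enrichment.  Deterministic given `seed`; every threshold
#' is echoed to `log.txt` in the output directory.  When no metabolite
#' tables are configured the metabolome and combined indices are marked
#' absent and the remaining stages still run.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `species` (named per-timepoint TSV paths, `bsl` required),
#'   `metabolites` (optional, same shape), `pathways` (optional baseline
#'   pathway TSV), `metadata` (TSV path), `gmt` (optional), `out_dir`,
#'   `seed` (default 1) and any of [default_thresholds()].
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$species), !is.null(config$metadata),
            !is.null(config$out_dir))
  th <- utils::modifyList(default_thresholds(),
                          config[intersect(names(config),
                                           names(default_thresholds()))])
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  cat("gutbalance pipeline run\n", file = logf)
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  logmsg("seed = %d", seed)
  for (nm in names(th)) logmsg("threshold %s = %g", nm, th[[nm]])

  stage <- "read inputs"
  res <- tryCatch({
    metadata <- read_metadata(config$metadata)
    species <- lapply(config$species, read_feature_table, kind = "taxon")
    metabolites <- if (!is.null(config$metabolites))
      lapply(config$metabolites, read_feature_table, kind = "metabolite")
    pathways <- if (!is.null(config$pathways))
      read_feature_table(config$pathways, kind = "pathway")
    md_bsl <- metadata[metadata$timepoint == "bsl", ]
    sp_bsl <- species$bsl
    m <- match(rownames(sp_bsl), md_bsl$sample_id)
    if (anyNA(m)) stop("baseline species samples missing from metadata")
    cl <- factor(md_bsl$npz6_group[m], levels = c("Lower", "Higher"))

    stage <- "descriptives"
    desc <- group_descriptives(md_bsl)
    utils::write.table(desc, file.path(out, "descriptives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "permanova"
    pmv <- bray_curtis_permanova(sp_bsl, cl, n_perm = th$n_perm, seed = seed)
    jsonlite::write_json(pmv, file.path(out, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "discriminant"
    taxa <- lefse(sp_bsl, cl, alpha = th$alpha,
                  lda_threshold = th$lda_threshold, n_boot = th$n_boot,
                  seed = seed)
    utils::write.table(taxa, file.path(out, "lefse.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pw <- NULL
    if (!is.null(pathways)) {
      pw <- pathway_screen(pathways, cl, mean_threshold = th$mean_threshold,
                           alpha = th$alpha)
      utils::write.table(pw, file.path(out, "pathway_screen.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "indices"
    met_bsl <- if (!is.null(metabolites)) metabolites$bsl
    fit <- fit_balance_indices(sp_bsl, met_bsl, cl, alpha = th$alpha,
                               n_components = th$n_components,
                               keepX = th$keepX, pc1_upper = th$pc1_upper,
                               pc1_lower = th$pc1_lower)
    defs <- lapply(fit$indices, function(d)
      list(numerator = d$numerator, denominator = d$denominator))
    absent <- setdiff(c("microbial", "metabolome", "combined"), names(defs))
    jsonlite::write_json(list(defined = defs, absent = absent,
                              log_base = "natural"),
                         file.path(out, "index_definitions.json"),
                         auto_unbox = FALSE, digits = NA)
    if (length(absent) > 0)
      logmsg("indices absent (no metabolite input): %s",
             paste(absent, collapse = ", "))
    tables <- lapply(names(species), function(tp)
      list(species = species[[tp]],
           metabolites = if (!is.null(metabolites)) metabolites[[tp]]))
    names(tables) <- names(species)
    values <- evaluate_indices(fit, tables, metadata)
    utils::write.table(values, file.path(out, "index_values.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "longitudinal"
    longit <- longitudinal_index_comparison(values)
    utils::write.table(longit$between, file.path(out, "index_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(longit$within))
      utils::write.table(longit$within, file.path(out, "index_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "associate"
    outcome_cols <- intersect(c("npz6", names(OUTCOME_SIGNS)), names(metadata))
    assoc <- do.call(rbind, lapply(unique(values$timepoint), function(tp) {
      vt <- values[values$timepoint == tp, ]
      mt <- metadata[match(vt$sample_id, metadata$sample_id), outcome_cols]
      a <- spearman_bh(vt[intersect(names(fit$indices), names(vt))], mt)
      a$timepoint <- tp
      a
    }))
    utils::write.table(assoc, file.path(out, "index_outcome_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    npz <- npz6_results(metadata, threshold = th$npz6_threshold)
    dc <- NULL
    if ("delta_npz6" %in% names(npz) && "final" %in% values$timepoint) {
      dc <- delta_correlation(values[values$timepoint == "final", ],
                              stats::setNames(npz$delta_npz6, npz$participant))
      utils::write.table(dc, file.path(out, "delta_npz6_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    net <- NULL
    if (!is.null(met_bsl) && nrow(taxa) > 0 &&
        nrow(fit$discriminant$metabolites) > 0) {
      micro <- ft_values(sp_bsl)[, taxa$feature, drop = FALSE]
      metab <- ft_values(met_bsl)[, fit$discriminant$metabolites$feature,
                                  drop = FALSE]
      net <- correlation_network(spearman_bh(micro, metab),
                                 cutoff = th$cor_cutoff)
      utils::write.table(net, file.path(out, "correlation_network.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "enrich"
    enr <- NULL
    if (!is.null(config$gmt) && !is.null(met_bsl)) {
      lib <- read_gmt(config$gmt)
      universe <- colnames(met_bsl)[!startsWith(colnames(met_bsl), "X-")]
      disc_met <- fit$discriminant$metabolites
      enr <- lapply(c(Lower = "Lower", Higher = "Higher"), function(g) {
        q <- intersect(disc_met$feature[disc_met$direction == g], universe)
        if (length(q) == 0) return(NULL)
        ora_enrich(q, lib, universe)
      })
      for (g in names(enr)) if (!is.null(enr[[g]]))
        utils::write.table(enr[[g]],
                           file.path(out, sprintf("enrichment_%s.tsv", tolower(g))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logmsg("pipeline complete")
    list(descriptives = desc, permanova = pmv, lefse = taxa,
         pathway_screen = pw, fit = fit, index_values = values,
         longitudinal = longit, associations = assoc,
         delta_correlations = dc, network = net, enrichment = enr)
  }, error = function(e) {
    logmsg("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
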