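#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a small,
#' unbalanced neurocognition cohort (3 impaired / 15 unimpaired by default)
#' profiled at three timepoints (`bsl`, `post`, `final`) with ~200
#' compositional species profiles, a 1300-feature plasma metabolome with a
#' planted discriminant subset, six cognitive-domain z-scores and six
#' functional outcome scales driven by a latent cognition factor.
#'
#' @param n_lower,n_higher Participants in the Lower / Higher NPZ-6 groups
#'   (defaults 3 and 15).
#' @param n_species Number of microbial species (default 200).
#' @param n_metabolites Number of plasma metabolites (default 1300).
#' @param n_discriminant_species Planted discriminant species, split evenly
#'   between Lower- and Higher-enriched (default 6).
#' @param n_discriminant_metabolites Planted discriminant metabolites, split
#'   evenly between up- and down-shifted in the Lower group (default 64).
#' @param effect_size Planted log-scale group shift in units of the total
#'   per-feature SD.  The default 3.5 emulates the order-of-magnitude
#'   (~30-fold) abundance differences of strongly discriminant species, which
#'   is what near-complete group separation at n = 3 vs 15 requires.
#' @param attenuation Per-timepoint multiplier of the group effect,
#'   `c(bsl, post, final)`; default `c(1, 0.5, 0.1)` so the planted contrast
#'   fades over the trial.
#' @param outcome_loading Loading of each functional scale on the latent
#'   cognition factor (default 0.9; the study-like regime where baseline
#'   index-outcome correlations are strong enough to survive BH adjustment
#'   at n = 18).
#' @param unnamed_fraction Fraction of metabolites given unnamed
#'   (`X-`-prefixed) ids, excluded from enrichment universes (default 0.1).
#' @param detection_limit Relative abundances below this value are recorded
#'   as structural zeros (default 1e-6).
#' @param intercept_sd Participant-level random-intercept SD on the log
#'   scale; the residual SD is chosen so the total SD is 1 (default 0.6).
#' @param seed RNG seed.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_lower = 3, n_higher = 15, n_species = 200,
                          n_metabolites = 1300, n_discriminant_species = 6,
                          n_discriminant_metabolites = 64, effect_size = 3.5,
                          attenuation = c(bsl = 1, post = 0.5, final = 0.1),
                          outcome_loading = 0.9, unnamed_fraction = 0.1,
                          detection_limit = 1e-6, intercept_sd = 0.6,
                          seed = 1L) {
  cfg <- list(n_lower = as.integer(n_lower), n_higher = as.integer(n_higher),
              n_species = as.integer(n_species),
              n_metabolites = as.integer(n_metabolites),
              n_discriminant_species = as.integer(n_discriminant_species),
              n_discriminant_metabolites = as.integer(n_discriminant_metabolites),
              effect_size = effect_size, attenuation = attenuation,
              outcome_loading = outcome_loading,
              unnamed_fraction = unnamed_fraction,
              detection_limit = detection_limit, intercept_sd = intercept_sd,
              seed = as.integer(seed))
  counts <- c("n_lower", "n_higher", "n_species", "n_metabolites")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop(f, " must be a positive integer")
  if (cfg$n_lower < 2 || cfg$n_higher < 2)
    stop("each group needs at least 2 participants")
  if (cfg$n_discriminant_species < 0 || cfg$n_discriminant_species > cfg$n_species)
    stop("n_discriminant_species must lie in [0, n_species]")
  if (cfg$n_discriminant_metabolites < 0 ||
      cfg$n_discriminant_metabolites > cfg$n_metabolites)
    stop("n_discriminant_metabolites must lie in [0, n_metabolites]")
  if (length(cfg$attenuation) != 3 || any(cfg$attenuation < 0) ||
      any(cfg$attenuation > 1))
    stop("attenuation must be three multipliers in [0, 1]")
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (cfg$intercept_sd < 0 || cfg$intercept_sd >= 1)
    stop("intercept_sd must lie in [0, 1)")
  class(cfg) <- "cohort_config"
  cfg
}

# Functional outcome scales and their loading sign on the latent cognition
# factor: quality of life and daily functioning improve with cognition,
# the symptom scales worsen.
OUTCOME_SIGNS <- c(qol = 1, daily_functioning = 1, depression = -1,
                   anxiety = -1, stress = -1, cns_symptoms = -1)
DOMAINS <- c("attention", "speed", "memory", "executive", "fluency", "motor")
TIMEPOINTS <- c("bsl", "post", "final")

#' Simulate a synthetic multi-omics neurocognition cohort
#'
#' Generates species relative-abundance tables (compositional, with
#' structural zeros below a detection limit), median-scaled metabolite
#' intensity tables, per-sample metadata (groups, sex, six domain z-scores,
#' functional outcome scales) for three timepoints, and the planted ground
#' truth used by recovery tests.  Species abundances are log-normal with
#' heavy-tailed base means plus participant random intercepts (so repeated
#' measures are positively correlated), then closed to sum one.  Planted
#' discriminant features are shifted on the log scale by
#' `effect_size * attenuation[t]` total-SDs in the Lower group.  Lower
#' participants are generated with baseline NPZ-6 <= -0.5 and Higher
#' participants > -0.5.
#'
#' @param config A [cohort_config].
#' @return A list of class `synthetic_cohort` with elements `tables` (per
#'   timepoint, each a list with `species` and `metabolites`
#'   [feature_table]s), `metadata` (one row per sample) and `truth` (planted
#'   feature sets, latent cognition, expected per-timepoint index
#'   separation).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_lower + config$n_higher
  participants <- sprintf("P%02d", seq_len(n))
  group <- factor(rep(c("Lower", "Higher"), c(config$n_lower, config$n_higher)),
                  levels = c("Lower", "Higher"))
  # one female, in the Lower group, mirroring the cohort's sex imbalance
  sex <- rep("male", n)
  if (config$n_lower >= 1) sex[config$n_lower] <- "female"
  arm <- rep(c("Intervention", "NoIntervention"), length.out = n)

  tau <- config$intercept_sd
  sigma <- sqrt(1 - tau^2)
  atten <- unname(config$attenuation)

  ## ---- species ----
  sp_ids <- sprintf("s__species_%03d", seq_len(config$n_species))
  k_sp <- config$n_discriminant_species
  n_lo <- ceiling(k_sp / 2); n_hi <- k_sp - n_lo
  lower_sp <- sp_ids[seq_len(n_lo)]
  higher_sp <- sp_ids[n_lo + seq_len(n_hi)]
  base_log <- stats::rnorm(config$n_species, log(1e-3), 2)  # heavy-tailed means
  # planted species moderately abundant (0.1%): detectable above the limit,
  # yet small enough that their shifted mass does not distort closure
  base_log[seq_len(k_sp)] <- log(0.001)
  sp_dir <- numeric(config$n_species)
  sp_dir[sp_ids %in% lower_sp] <- 1
  sp_dir[sp_ids %in% higher_sp] <- -1
  b_sp <- matrix(stats::rnorm(n * config$n_species, 0, tau), n)  # participant x feature

  species <- lapply(seq_along(TIMEPOINTS), function(t) {
    shift <- outer(ifelse(group == "Lower", 1, 0),
                   sp_dir * config$effect_size * atten[t])
    lg <- matrix(base_log, n, config$n_species, byrow = TRUE) + shift + b_sp +
      matrix(stats::rnorm(n * config$n_species, 0, sigma), n)
    v <- exp(lg)
    v <- v / rowSums(v)
    v[v < config$detection_limit] <- 0
    v <- v / rowSums(v)
    rownames(v) <- paste0(participants, "_", TIMEPOINTS[t])
    colnames(v) <- sp_ids
    feature_table(v, kind = "taxon", normalized = TRUE)
  })

  ## ---- metabolites ----
  n_unnamed <- round(config$unnamed_fraction * config$n_metabolites)
  n_named <- config$n_metabolites - n_unnamed
  met_ids <- c(sprintf("met_%04d", seq_len(n_named)),
               sprintf("X-%05d", seq_len(n_unnamed)))
  k_met <- config$n_discriminant_metabolites
  if (k_met > n_named)
    stop("planted metabolites must be named: increase n_metabolites or lower unnamed_fraction")
  n_up <- ceiling(k_met / 2); n_dn <- k_met - n_up
  met_up <- met_ids[seq_len(n_up)]
  met_dn <- met_ids[n_up + seq_len(n_dn)]
  met_dir <- numeric(config$n_metabolites)
  met_dir[met_ids %in% met_up] <- 1
  met_dir[met_ids %in% met_dn] <- -1
  # heterogeneous per-metabolite effect strength: discriminant sets found by
  # a p < 0.05 screen are dominated by effects near the detection boundary
  # with a minority of strong ones; the mixture below emulates that and is
  # also what gives the PC1 loadings of the shortlisting step a realistic
  # spread instead of a flat profile
  strong <- stats::runif(config$n_metabolites) < 0.25
  met_mult <- ifelse(strong, stats::runif(config$n_metabolites, 1.4, 1.8),
                     stats::runif(config$n_metabolites, 0.65, 1.0))
  met_dir <- met_dir * met_mult
  # planted metabolites form one correlated module (lipid-family-like),
  # up-shifted features loading positively and down-shifted negatively; the
  # strong tier carries high communality, so PC1 concentrates the way
  # co-regulated metabolite families do, while total noise SD stays 1
  lam <- numeric(config$n_metabolites)
  planted_met <- met_dir != 0
  lam[planted_met] <- sign(met_dir[planted_met]) *
    ifelse(strong[planted_met],
           stats::runif(sum(planted_met), 0.6, 0.9),
           stats::runif(sum(planted_met), 0.05, 0.3))
  met_base <- stats::rnorm(config$n_metabolites, log(1e5), 1)
  b_met <- matrix(stats::rnorm(n * config$n_metabolites, 0, tau), n)

  metab_raw <- lapply(seq_along(TIMEPOINTS), function(t) {
    shift <- outer(ifelse(group == "Lower", 1, 0),
                   met_dir * config$effect_size * atten[t])
    g_mod <- stats::rnorm(n)
    noise <- outer(g_mod, lam) +
      sweep(matrix(stats::rnorm(n * config$n_metabolites), n), 2,
            sqrt(1 - lam^2), "*")
    lg <- matrix(met_base, n, config$n_metabolites, byrow = TRUE) + shift + b_met +
      sigma * noise
    v <- exp(lg)
    rownames(v) <- paste0(participants, "_", TIMEPOINTS[t])
    colnames(v) <- met_ids
    v
  })
  # Metabolon-style per-feature median scaling across the whole study
  med <- apply(do.call(rbind, metab_raw), 2, stats::median)
  metabolites <- lapply(metab_raw, function(v)
    feature_table(sweep(v, 2, med, "/"), kind = "metabolite", normalized = FALSE))

  ## ---- cognition and outcomes ----
  mu_c <- ifelse(group == "Lower", -1.5, 0.3)
  sd_c <- ifelse(group == "Lower", 0.25, 0.4)
  gap <- 1.8   # latent-group gap recovered as the planted effect attenuates
  latent <- numeric(n)
  domains_bsl <- matrix(NA_real_, n, 6, dimnames = list(participants, DOMAINS))
  threshold <- -0.5
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      ci <- stats::rnorm(1, mu_c[i], sd_c[i])
      di <- ci + stats::rnorm(6, 0, 0.35)
      ok <- if (group[i] == "Lower") mean(di) <= threshold else mean(di) > threshold
      if (ok) break
    }
    if (!ok) stop("could not generate NPZ-6 scores on the required side of the threshold")
    latent[i] <- ci
    domains_bsl[i, ] <- di
  }

  meta <- vector("list", 3)
  for (t in seq_along(TIMEPOINTS)) {
    recover <- ifelse(group == "Lower", (1 - atten[t]) * gap, 0)
    c_t <- latent + recover
    dom <- if (t == 1) domains_bsl else
      c_t + matrix(stats::rnorm(n * 6, 0, 0.35), n)
    dom <- matrix(dom, n, 6, dimnames = list(NULL, DOMAINS))
    load <- config$outcome_loading
    out <- vapply(names(OUTCOME_SIGNS), function(s)
      OUTCOME_SIGNS[[s]] * load * c_t + stats::rnorm(n, 0, sqrt(max(1 - load^2, 0.05))),
      numeric(n))
    meta[[t]] <- data.frame(
      sample_id = paste0(participants, "_", TIMEPOINTS[t]),
      participant = participants, timepoint = TIMEPOINTS[t],
      npz6_group = as.character(group), sex = sex, arm = arm,
      dom, npz6 = rowMeans(dom), out,
      stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  tables <- lapply(seq_along(TIMEPOINTS), function(t)
    list(species = species[[t]], metabolites = metabolites[[t]]))
  names(tables) <- TIMEPOINTS

  truth <- list(
    enriched_lower_species = lower_sp,
    enriched_higher_species = higher_sp,
    discriminant_metabolites_up = met_up,
    discriminant_metabolites_down = met_dn,
    latent_cognition = stats::setNames(latent, participants),
    true_index_separation = stats::setNames(2 * config$effect_size * atten,
                                            TIMEPOINTS))
  structure(list(tables = tables, metadata = metadata, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("synthetic cohort: %d Lower + %d Higher participants, ",
                     "%d species, %d metabolites, 3 timepoints\n"),
              cfg$n_lower, cfg$n_higher, cfg$n_species, cfg$n_metabolites))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one species and one metabolite TSV per timepoint
#' (features-as-rows), a metadata TSV and the planted ground truth as JSON.
#' All tables round-trip through [read_feature_table()] /
#' [read_metadata()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Existing writable directory; a missing directory is an error
#'   and nothing is written.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  paths <- character(0)
  for (tp in names(cohort$tables)) {
    p1 <- file.path(dir, paste0("species_", tp, ".tsv"))
    write_feature_table(cohort$tables[[tp]]$species, p1)
    p2 <- file.path(dir, paste0("metabolites_", tp, ".tsv"))
    write_feature_table(cohort$tables[[tp]]$metabolites, p2)
    paths <- c(paths, p1, p2)
  }
  pm <- file.path(dir, "metadata.tsv")
  utils::write.table(format(cohort$metadata, digits = 17, trim = TRUE),
                     pm, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, pt, auto_unbox = FALSE, digits = NA)
  invisible(c(paths, pm, pt))
}
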