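#' Run configuration for the full volumetric pipeline
#'
#' Assembles every knob of [run_all()] with study-style defaults: the lamina
#' excluded, the six undefined central-brain regions as the reference volume,
#' isometric null slope 1 for volume-on-volume (3 for volume-on-wingspan),
#' adjusted R-squared inclusion threshold 0.6, 10,000 replicates for both
#' phylogenetic-signal tests, and average-linkage clustering. A YAML file may
#' override any field.
#'
#' @param tree,volumes,ecology File paths (Newick; delimited volume and
#'   ecology tables).
#' @param yaml Optional YAML file whose top-level keys override arguments.
#' @param undefined_neuropils Regions summed into the reference volume.
#' @param excluded_neuropils Regions dropped from all analyses.
#' @param excluded_species Named list: neuropil -> species to drop for that
#'   neuropil's analyses (e.g. a species whose mushroom-body lobes cannot be
#'   delineated).
#' @param b0,b0_wingspan Isometric null slopes.
#' @param alpha Significance level.
#' @param n_perm,n_sim Replicates for the K = 0 and K = 1 tests.
#' @param seed Master seed.
#' @param linkage Clustering linkage.
#' @param inclusion_threshold Adjusted R-squared cutoff for report inclusion.
#' @param output_dir Where [run_all()] writes its tables.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(tree, volumes, ecology, yaml = NULL,
                       undefined_neuropils = .reference_regions,
                       excluded_neuropils = "lamina",
                       excluded_species = list(),
                       b0 = 1, b0_wingspan = 3, alpha = 0.05,
                       n_perm = 10000L, n_sim = 10000L, seed = 1L,
                       linkage = "average", inclusion_threshold = 0.6,
                       output_dir = "results") {
  cfg <- list(tree = tree, volumes = volumes, ecology = ecology,
              undefined_neuropils = undefined_neuropils,
              excluded_neuropils = excluded_neuropils,
              excluded_species = excluded_species,
              b0 = b0, b0_wingspan = b0_wingspan, alpha = alpha,
              n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
              seed = as.integer(seed), linkage = linkage,
              inclusion_threshold = inclusion_threshold,
              output_dir = output_dir)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(ov)] <- ov
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Per-neuropil isometry (slope-index) report
#'
#' PGLS of each neuropil's natural-log species-mean volume on the natural-log
#' reference volume, with slope index si = b - b0, its Wald chi-squared test,
#' adjusted R-squared and the inclusion flag.
#'
#' @param traits A `"trait_matrix"` with `reference` filled in.
#' @param C Phylogenetic covariance, or `NULL`.
#' @param b0 Isometric null slope.
#' @param inclusion_threshold Adjusted R-squared cutoff.
#' @param alpha Significance level for the significance column.
#' @param ridge Passed to [pgls_fit()].
#' @return Data.frame, one row per neuropil.
#' @export
isometry_table <- function(traits, C = NULL, b0 = 1,
                           inclusion_threshold = 0.6, alpha = 0.05,
                           ridge = 0) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (is.null(traits$reference))
    stop("trait matrix needs reference volumes", call. = FALSE)
  logx <- log(traits$reference)
  rows <- lapply(colnames(traits$mean), function(np) {
    y <- log(traits$mean[, np])
    y <- y[!is.na(y)]
    if (length(y) < 4L)
      return(NULL)
    fit <- pgls_fit(y, design_matrix(logx[names(y)]), C, ridge = ridge)
    si <- slope_index(fit, b0)
    data.frame(neuropil = np, n = fit$n, b = si$b, se_b = si$se_b,
               si = si$si, chisq = si$chisq, p = si$p,
               r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
               included = fit$adj_r_squared > inclusion_threshold,
               significant = si$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-neuropil grade-shift report for a binary ecological grouping
#'
#' Runs [grade_shift()] for every neuropil: slope-equality test on the
#' interaction model, then (where slopes agree) the common-slope grade-shift
#' index and its intercept test. Benjamini-Hochberg adjusted p-values are
#' appended as a supplementary column; flags use the raw p-values.
#'
#' @param traits A `"trait_matrix"` with `reference` filled in.
#' @param groups Named 2-level grouping (names = species).
#' @param C Phylogenetic covariance, or `NULL`.
#' @param alpha Significance level.
#' @param inclusion_threshold Adjusted R-squared cutoff (applied to the
#'   reported model's adjusted R-squared).
#' @param ridge Passed to [pgls_fit()].
#' @return Data.frame, one row per neuropil.
#' @export
grade_shift_table <- function(traits, groups, C = NULL, alpha = 0.05,
                              inclusion_threshold = 0.6, ridge = 0) {
  stopifnot(inherits(traits, "trait_matrix"))
  logx <- log(traits$reference)
  rows <- lapply(colnames(traits$mean), function(np) {
    y <- log(traits$mean[, np])
    y <- y[!is.na(y)]
    gs <- tryCatch(grade_shift(y, logx, groups, C, alpha = alpha,
                               ridge = ridge),
                   error = function(e) NULL)
    if (is.null(gs)) return(NULL)
    fit <- if (!is.null(gs$fit_common)) gs$fit_common else gs$fit_interaction
    data.frame(neuropil = np, n = gs$n,
               group1 = gs$groups[1], group2 = gs$groups[2],
               slope_diff = gs$slope_diff, chisq_slope = gs$chisq_slope,
               p_slope = gs$p_slope, slopes_differ = gs$p_slope < alpha,
               b_common = gs$b_common, gsi = gs$gsi,
               gsi_valid = gs$gsi_valid,
               chisq_intercept = gs$chisq_intercept,
               p_intercept = gs$p_intercept,
               adj_r_squared = fit$adj_r_squared,
               included = fit$adj_r_squared > inclusion_threshold,
               significant_shift = !is.na(gs$p_intercept) &
                 gs$p_intercept < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_slope_bh <- stats::p.adjust(out$p_slope, "BH")
  out$p_intercept_bh <- stats::p.adjust(out$p_intercept, "BH")
  out
}

#' PGLS of total brain volume on wingspan
#'
#' Total brain volume is the per-species sum of all segmented neuropils
#' (after any exclusions already applied to the trait matrix) plus the
#' reference regions. The regression is natural-log volume on natural-log
#' wingspan; the isometric null for a volume-on-length pair is `b0` (default
#' 3).
#'
#' @param traits A `"trait_matrix"` with `reference` filled in.
#' @param wingspan Named numeric (mm), one value per species.
#' @param C Phylogenetic covariance, or `NULL`.
#' @param b0 Isometric null slope.
#' @param ridge Passed to [pgls_fit()].
#' @return List with `fit`, `si` (from [slope_index()]), `n`.
#' @export
wingspan_allometry <- function(traits, wingspan, C = NULL, b0 = 3, ridge = 0) {
  stopifnot(inherits(traits, "trait_matrix"))
  total <- rowSums(traits$mean, na.rm = TRUE) + traits$reference
  sp <- names(total)[!is.na(wingspan[names(total)])]
  if (length(sp) < 4L)
    stop("need at least 4 species with wingspan data", call. = FALSE)
  y <- log(total[sp])
  x <- stats::setNames(log(unlist(wingspan)[sp]), sp)
  fit <- pgls_fit(y, design_matrix(x), C, ridge = ridge)
  list(fit = fit, si = slope_index(fit, b0), n = fit$n)
}

#' Run the full phylogenetically corrected volumetric analysis
#'
#' Orchestrates every stage on files named in the configuration: input
#' validation and species reconciliation, paired-side summation, species
#' aggregation and reference normalization, the intra/inter variability
#' check, the Blomberg's K signal table, the isometry slope-index table,
#' grade-shift tables for activity period and migration, pairwise-slope
#' clustering, the leverage screen of every isometry fit, the two-factor
#' robustness table, and (when wingspans are present) the brain-on-wingspan
#' allometry. All tables are written as TSV under `cfg$output_dir` along with
#' a machine-readable run manifest.
#'
#' @param cfg A [run_config()].
#' @param write Write TSV outputs (default TRUE); the bundle is returned
#'   either way.
#' @return Invisibly, a named list with all report tables.
#' @export
run_all <- function(cfg, write = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  tree <- parse_newick(paste(readLines(cfg$tree, warn = FALSE), collapse = ""))
  vt <- read_volume_table(cfg$volumes)
  eco <- read_ecology_table(cfg$ecology)

  vt <- vt[!(vt$neuropil %in% cfg$excluded_neuropils), , drop = FALSE]
  check_species_match(tree$tip.label, vt$species, "volume table")
  miss_eco <- setdiff(unique(vt$species), eco$species)
  if (length(miss_eco))
    stop("species missing from ecology table: ",
         paste(miss_eco, collapse = ", "), call. = FALSE)

  summed <- sum_paired(vt)
  ref <- reference_volume(summed, cfg$undefined_neuropils)
  analysed <- summed[!(summed$neuropil %in% cfg$undefined_neuropils), ,
                     drop = FALSE]
  traits <- relative_volumes(species_aggregate(analysed), ref)
  for (np in names(cfg$excluded_species)) {
    drop_sp <- intersect(cfg$excluded_species[[np]], rownames(traits$mean))
    traits$mean[drop_sp, np] <- NA
    traits$sd[drop_sp, np] <- NA
    traits$relative[drop_sp, np] <- NA
  }

  C <- vcv_matrix(tree)
  activity <- stats::setNames(eco$activity, eco$species)
  migration <- stats::setNames(eco$migration, eco$species)

  bundle <- list(
    variability = variability_report(analysed),
    signal = signal_table(traits, tree, n_perm = cfg$n_perm,
                          n_sim = cfg$n_sim, seed = cfg$seed,
                          alpha = cfg$alpha),
    isometry = isometry_table(traits, C, b0 = cfg$b0,
                              inclusion_threshold = cfg$inclusion_threshold,
                              alpha = cfg$alpha),
    gradeshift_activity = grade_shift_table(traits, activity, C,
                                            alpha = cfg$alpha,
                                            inclusion_threshold = cfg$inclusion_threshold),
    gradeshift_migration = grade_shift_table(traits, migration, C,
                                             alpha = cfg$alpha,
                                             inclusion_threshold = cfg$inclusion_threshold)
  )

  sm <- pairwise_slopes(traits, C)
  dist <- to_distance(sm)
  clus <- hcluster(dist$distance, linkage = cfg$linkage, k = 2)
  bundle$slope_matrix <- sm$slope
  bundle$distance_matrix <- dist$distance
  bundle$dendrogram_newick <- clus$newick
  bundle$clusters <- clus$clusters

  logx <- log(traits$reference)
  lev <- lapply(colnames(traits$mean), function(np) {
    y <- log(traits$mean[, np]); y <- y[!is.na(y)]
    if (length(y) < 4L) return(NULL)
    fit <- pgls_fit(y, design_matrix(logx[names(y)]), C)
    out <- leverage_screen(fit)
    cbind(neuropil = np, out, stringsAsFactors = FALSE)
  })
  bundle$leverage <- do.call(rbind, lev)

  tf <- lapply(colnames(traits$mean), function(np) {
    y <- log(traits$mean[, np]); y <- y[!is.na(y)]
    res <- tryCatch(two_factor_pgls(y, logx, activity, migration, C),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(neuropil = np, res$tests, stringsAsFactors = FALSE)
  })
  bundle$two_factor <- do.call(rbind, tf)

  if ("wingspan" %in% names(eco) && any(!is.na(eco$wingspan))) {
    ws <- stats::setNames(eco$wingspan, eco$species)
    wa <- wingspan_allometry(traits, ws, C, b0 = cfg$b0_wingspan)
    bundle$wingspan <- data.frame(
      n = wa$n, b = wa$si$b, se_b = wa$si$se_b, si = wa$si$si,
      chisq = wa$si$chisq, p = wa$si$p, r_squared = wa$fit$r_squared,
      adj_r_squared = wa$fit$adj_r_squared)
  }

  bundle$manifest <- list(
    seed = cfg$seed, alpha = cfg$alpha, b0 = cfg$b0,
    n_perm = cfg$n_perm, n_sim = cfg$n_sim, linkage = cfg$linkage,
    inclusion_threshold = cfg$inclusion_threshold,
    excluded_neuropils = cfg$excluded_neuropils,
    n_species = length(tree$tip.label),
    n_neuropils = ncol(traits$mean),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("lepibrain")))

  if (write) .write_bundle(bundle, cfg$output_dir)
  invisible(bundle)
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) utils::write.table(
    x, file.path(dir, paste0(name, ".tsv")), sep = "\t", quote = FALSE,
    row.names = is.matrix(x))
  for (nm in c("variability", "signal", "isometry", "gradeshift_activity",
               "gradeshift_migration", "leverage", "two_factor"))
    if (!is.null(bundle[[nm]])) wr(bundle[[nm]], nm)
  wr(bundle$slope_matrix, "slope_matrix")
  wr(bundle$distance_matrix, "distance_matrix")
  if (!is.null(bundle$wingspan)) wr(bundle$wingspan, "wingspan")
  writeLines(bundle$dendrogram_newick, file.path(dir, "dendrogram.nwk"))
  utils::write.table(
    data.frame(neuropil = names(bundle$clusters),
               cluster = unname(bundle$clusters)),
    file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
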