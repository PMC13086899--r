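#' Simulate a pure-birth phylogeny scaled to unit depth
#'
#' Yule (pure-birth) tree with `n_species` tips, rescaled so every tip sits at
#' depth 1. Unit depth makes the Brownian-motion rate `sigma2` directly
#' interpretable as the expected between-species trait variance at the tips,
#' independent of `n_species`.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed; the tree is reproducible given the seed.
#' @return An ultrametric `"phylo"` object with tips `t1 ... tn` and depth 1.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(tree_depths(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Recursive accumulation from the root: each node's value is its parent's
#' value plus a Normal(0, sigma2 * branch length) increment. Tip covariance is
#' therefore `sigma2 * C`, with `C` the shared-branch-length matrix of
#' [vcv_matrix()].
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 BM rate (trait variance per unit branch length), >= 0.
#' @param root_state Trait value at the root.
#' @param seed Optional integer seed; `NULL` leaves the RNG stream alone so
#'   callers can manage their own stream.
#' @return Named numeric vector of tip values in `tree$tip.label` order.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  edge <- tree$edge
  nn <- max(edge)
  val <- numeric(nn)
  root <- n + 1L
  val[root] <- root_state
  incr <- stats::rnorm(nrow(edge), mean = 0,
                       sd = sqrt(sigma2 * tree$edge.length))
  # preorder: parents are assigned before their children
  for (e in rev(ape::postorder(tree))) {
    val[edge[e, 2]] <- val[edge[e, 1]] + incr[e]
  }
  out <- val[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Default neuropil specification for the synthetic generator
#'
#' A 24-region panel emulating a lepidopteran central-brain segmentation:
#' paired sensory neuropils (optic-lobe regions, antennal lobe), paired
#' mushroom-body and lateral-complex components, and unpaired midline
#' central-complex neuropils. Intercepts are on the natural-log scale relative
#' to the reference volume; slopes are allometric exponents against the
#' reference volume. By default both ecological groups share each neuropil's
#' intercept and slope (no planted grade shifts); named arguments of
#' `grade_shift_log` / `slope_shift` plant group differences for selected
#' neuropils (group 1 minus group 2 on the log-intercept, and on the slope).
#'
#' @param grade_shift_log Named numeric: added to group 1's log intercept.
#' @param slope_shift Named numeric: added to group 1's slope.
#' @return A data.frame with columns `neuropil`, `paired`, `log_a1`, `log_a2`,
#'   `b1`, `b2`, `resid_sigma2`.
#' @export
default_neuropils <- function(grade_shift_log = numeric(), slope_shift = numeric()) {
  nm <- c("ME", "LO", "LOP", "AME", "AL", "AOTU_UU", "AOTU_LUC", "CA", "PED",
          "VL", "ML", "VGL", "MGL", "YL", "SPU", "LAL", "BU", "GA", "POTU",
          "OCN", "EB", "FB", "PB", "NO")
  paired <- !(nm %in% c("EB", "FB", "PB", "NO"))
  # typical log relative volumes (natural log of neuropil/reference ratio) and
  # near-isometric slopes with mild spread
  log_a <- stats::setNames(c(-0.5, -1.5, -2.5, -6.0, -2.0, -4.0, -5.0, -2.8,
                             -3.5, -4.2, -4.0, -5.5, -5.3, -4.8, -6.5, -3.8,
                             -6.8, -7.0, -7.5, -7.8, -4.5, -3.6, -5.0, -6.2), nm)
  b <- stats::setNames(rep(c(1.15, 1.0, 0.85, 1.05), 6), nm)
  spec <- data.frame(neuropil = nm, paired = paired,
                     log_a1 = log_a, log_a2 = log_a, b1 = b, b2 = b,
                     resid_sigma2 = 0.05, row.names = NULL,
                     stringsAsFactors = FALSE)
  if (length(grade_shift_log)) {
    idx <- match(names(grade_shift_log), spec$neuropil)
    if (anyNA(idx)) stop("unknown neuropil in grade_shift_log", call. = FALSE)
    spec$log_a1[idx] <- spec$log_a1[idx] + unname(grade_shift_log)
  }
  if (length(slope_shift)) {
    idx <- match(names(slope_shift), spec$neuropil)
    if (anyNA(idx)) stop("unknown neuropil in slope_shift", call. = FALSE)
    spec$b1[idx] <- spec$b1[idx] + unname(slope_shift)
  }
  spec
}

#' Configuration for the synthetic dataset generator
#'
#' Bundles all knobs of [simulate_dataset()] with the defaults that emulate
#' the statistical structure of a 15-species lepidopteran volumetric study:
#' an ultrametric tree, Brownian-motion reference volume and residuals,
#' log-linear allometries per neuropil with optional group-specific intercepts
#' (grade shifts) and slopes, 3 individuals per species, and multiplicative
#' within-species noise one order of magnitude below the between-species
#' spread.
#'
#' @param n_species Number of species.
#' @param tree Optional user-supplied `"phylo"`; `NULL` simulates a pure-birth
#'   tree of unit depth.
#' @param sigma2_bm BM rate of the log reference volume (per unit depth).
#' @param root_state Root value of the log reference volume (natural log of
#'   cubic micrometres; default ~ log 2e7).
#' @param neuropils Neuropil specification as from [default_neuropils()].
#' @param individuals_per_species Specimens per species (>= 1).
#' @param intra_cv Within-species coefficient of variation of raw volumes.
#' @param activity,migration Optional named character vectors assigning each
#'   species `"diurnal"`/`"nocturnal"` and `"migratory"`/`"non-migratory"`;
#'   `NULL` assigns alternating groups deterministically.
#' @param seed Master integer seed; all per-neuropil streams derive from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 15L,
                       tree = NULL,
                       sigma2_bm = 0.5,
                       root_state = log(2e7),
                       neuropils = default_neuropils(),
                       individuals_per_species = 3L,
                       intra_cv = 0.05,
                       activity = NULL,
                       migration = NULL,
                       seed = 1L) {
  stopifnot(sigma2_bm >= 0, intra_cv >= 0, individuals_per_species >= 1)
  cfg <- list(n_species = as.integer(n_species), tree = tree,
              sigma2_bm = sigma2_bm, root_state = root_state,
              neuropils = neuropils,
              individuals_per_species = as.integer(individuals_per_species),
              intra_cv = intra_cv, activity = activity, migration = migration,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Six regions whose per-specimen sum is the reference ("central brain") volume.
.reference_regions <- c("superior", "ventrolateral", "ventromedial",
                        "inferior", "circumesophageal", "gnathal")
.reference_fractions <- c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10)

#' Simulate a full volumetric dataset on a phylogeny
#'
#' Generative model: the log reference volume of each species evolves by
#' Brownian motion on the tree. For every neuropil, the species log mean is
#' `log a_g + b_g * log x` plus an independent BM residual, where the group
#' `g` is the species' diurnal/nocturnal assignment. Individuals get
#' multiplicative Gaussian noise on the raw scale (truncated to stay
#' positive); paired neuropils are emitted as left/right records summing to
#' the individual's total. The six reference regions are emitted per specimen
#' so that the downstream reference-volume step runs unchanged on synthetic
#' data.
#'
#' @param cfg A [sim_config()] object.
#' @return List with elements `tree` (`"phylo"`), `volumes` (long data.frame:
#'   species, specimen, neuropil, side, volume), `ecology` (data.frame:
#'   species, activity, migration, wingspan), and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- if (is.null(cfg$tree)) {
    simulate_tree(cfg$n_species, seed = sample.int(.Machine$integer.max - 1L, 1))
  } else cfg$tree
  sp <- tree$tip.label
  ns <- length(sp)

  activity <- cfg$activity
  if (is.null(activity))
    activity <- stats::setNames(rep(c("diurnal", "nocturnal"), length.out = ns), sp)
  migration <- cfg$migration
  if (is.null(migration))
    migration <- stats::setNames(
      rep(c("migratory", "non-migratory", "non-migratory", "migratory"),
          length.out = ns), sp)
  if (!all(sp %in% names(activity)) || !all(sp %in% names(migration)))
    stop("every species needs an activity and migration assignment", call. = FALSE)
  if (!all(activity[sp] %in% c("diurnal", "nocturnal")) ||
      !all(migration[sp] %in% c("migratory", "non-migratory")))
    stop("invalid ecology category", call. = FALSE)

  np <- cfg$neuropils
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(np) + 2L)
  log_ref <- simulate_bm(tree, cfg$sigma2_bm, cfg$root_state, seed = seeds[1])

  g1 <- activity[sp] == "diurnal" # ecology group 1 in the generative model
  # species-level log means per neuropil
  logmean <- matrix(NA_real_, ns, nrow(np), dimnames = list(sp, np$neuropil))
  for (k in seq_len(nrow(np))) {
    resid <- simulate_bm(tree, np$resid_sigma2[k], 0, seed = seeds[k + 1L])
    la <- ifelse(g1, np$log_a1[k], np$log_a2[k])
    b <- ifelse(g1, np$b1[k], np$b2[k])
    logmean[, k] <- la + b * log_ref[sp] + resid[sp]
  }

  set.seed(seeds[nrow(np) + 2L])
  nind <- cfg$individuals_per_species
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    spec_ids <- sprintf("%s_%02d", sp[i], seq_len(nind))
    recs <- list()
    for (j in seq_len(nind)) {
      # reference regions: noisy specimen-level reference split into 6 parts
      ref_j <- exp(log_ref[sp[i]]) * .trunc_noise(1L, cfg$intra_cv)
      recs[[length(recs) + 1L]] <- data.frame(
        species = sp[i], specimen = spec_ids[j],
        neuropil = .reference_regions, side = "unpaired",
        volume = ref_j * .reference_fractions, stringsAsFactors = FALSE)
      vols <- exp(logmean[i, ]) * .trunc_noise(nrow(np), cfg$intra_cv)
      for (k in seq_len(nrow(np))) {
        if (np$paired[k]) {
          p <- min(max(stats::rnorm(1, 0.5, 0.02), 0.35), 0.65)
          recs[[length(recs) + 1L]] <- data.frame(
            species = sp[i], specimen = spec_ids[j],
            neuropil = np$neuropil[k], side = c("left", "right"),
            volume = vols[k] * c(p, 1 - p), stringsAsFactors = FALSE)
        } else {
          recs[[length(recs) + 1L]] <- data.frame(
            species = sp[i], specimen = spec_ids[j],
            neuropil = np$neuropil[k], side = "unpaired",
            volume = vols[k], stringsAsFactors = FALSE)
        }
      }
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  volumes <- do.call(rbind, rows)
  rownames(volumes) <- NULL

  # wingspan: isometric length proxy, volume^(1/3) times a lognormal deviate
  wing <- exp(log_ref[sp] / 3 + stats::rnorm(ns, 0, 0.05)) / 20
  ecology <- data.frame(species = sp, activity = unname(activity[sp]),
                        migration = unname(migration[sp]),
                        wingspan = unname(wing), stringsAsFactors = FALSE)
  list(tree = tree, volumes = volumes, ecology = ecology, config = cfg)
}

# multiplicative noise factor 1 + N(0, cv), truncated to stay positive
.trunc_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  f <- 1 + stats::rnorm(n, 0, cv)
  pmax(f, .Machine$double.eps)
}

#' Write a simulated dataset to delimited text and Newick files
#'
#' Emits the same formats the pipeline consumes: `tree.nwk`, `volumes.csv`,
#' `ecology.csv`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             volumes = file.path(dir, "volumes.csv"),
             ecology = file.path(dir, "ecology.csv"))
  write_newick(sim$tree, paths["tree"])
  utils::write.csv(sim$volumes, paths["volumes"], row.names = FALSE)
  utils::write.csv(sim$ecology, paths["ecology"], row.names = FALSE)
  invisible(paths)
}
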