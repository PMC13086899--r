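#' Read an individual-level volume table
#'
#' Delimited text (comma or tab, auto-detected from the header line) with
#' required columns `species`, `specimen`, `neuropil`, `side`, `volume`.
#' Volumes are cubic micrometres and must be finite and positive; `side` is
#' `left`, `right` or `unpaired`; `(species, specimen, neuropil, side)` must
#' be unique.
#'
#' @param path File path.
#' @return A data.frame with normalized species labels.
#' @export
read_volume_table <- function(path) {
  vt <- .read_delim_auto(path)
  req <- c("species", "specimen", "neuropil", "side", "volume")
  miss <- setdiff(req, names(vt))
  if (length(miss))
    stop("volume table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vt$species <- normalize_labels(vt$species)
  validate_volume_table(vt)
  vt
}

#' @rdname read_volume_table
#' @param vt A volume table data.frame.
#' @export
validate_volume_table <- function(vt) {
  if (!is.numeric(vt$volume) || anyNA(vt$volume) || any(!is.finite(vt$volume)))
    stop("volumes must be finite numbers", call. = FALSE)
  if (any(vt$volume <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (!all(vt$side %in% c("left", "right", "unpaired")))
    stop("side must be one of left/right/unpaired", call. = FALSE)
  key <- paste(vt$species, vt$specimen, vt$neuropil, vt$side, sep = "\r")
  if (anyDuplicated(key)) {
    d <- vt[duplicated(key), c("species", "specimen", "neuropil", "side")]
    stop("duplicate volume records, e.g. ",
         paste(unlist(d[1, ]), collapse = "/"), call. = FALSE)
  }
  invisible(vt)
}

#' Read a species-level ecology table
#'
#' Columns `species`, `activity` (`diurnal`/`nocturnal`), `migration`
#' (`migratory`/`non-migratory`), optional `wingspan` (mm).
#'
#' @param path File path.
#' @return A data.frame with normalized species labels.
#' @export
read_ecology_table <- function(path) {
  eco <- .read_delim_auto(path)
  req <- c("species", "activity", "migration")
  miss <- setdiff(req, names(eco))
  if (length(miss))
    stop("ecology table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  eco$species <- normalize_labels(eco$species)
  if (anyDuplicated(eco$species))
    stop("duplicate species in ecology table", call. = FALSE)
  if (!all(eco$activity %in% c("diurnal", "nocturnal")))
    stop("activity must be diurnal or nocturnal", call. = FALSE)
  if (!all(eco$migration %in% c("migratory", "non-migratory")))
    stop("migration must be migratory or non-migratory", call. = FALSE)
  eco
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE)
}

#' Sum paired neuropils to one total per specimen
#'
#' Left and right records of the same neuropil in the same specimen are summed
#' into a single `unpaired` record; already-unpaired records pass through. A
#' lone side is an error in strict mode, or kept with a warning otherwise.
#'
#' @param vt A validated volume table.
#' @param strict If `TRUE` (default), a paired neuropil missing one side
#'   errors; otherwise the lone side is used with a warning.
#' @return A volume table with one record per (species, specimen, neuropil).
#' @export
sum_paired <- function(vt, strict = TRUE) {
  validate_volume_table(vt)
  key <- interaction(vt$species, vt$specimen, vt$neuropil, drop = TRUE)
  out <- lapply(split(vt, key), function(g) {
    sides <- g$side
    if (all(sides == "unpaired")) return(g)
    if ("unpaired" %in% sides)
      stop("mixed unpaired and sided records for ",
           g$species[1], "/", g$specimen[1], "/", g$neuropil[1], call. = FALSE)
    if (length(sides) == 1L) {
      msg <- paste0("only one side recorded for ", g$species[1], "/",
                    g$specimen[1], "/", g$neuropil[1])
      if (strict) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    data.frame(species = g$species[1], specimen = g$specimen[1],
               neuropil = g$neuropil[1], side = "unpaired",
               volume = sum(g$volume), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate specimen volumes to species means and SDs
#'
#' Mean and sample standard deviation (n-1 denominator; `NA` at n = 1) of the
#' side-summed volumes, per species and neuropil.
#'
#' @param vt A side-summed volume table (see [sum_paired()]).
#' @return A list of class `"trait_matrix"` with matrices `mean`, `sd`, `n`
#'   (species x neuropil; `NA`/0 where a cell is empty).
#' @export
species_aggregate <- function(vt) {
  sp <- sort(unique(vt$species))
  np <- sort(unique(vt$neuropil))
  m <- s <- matrix(NA_real_, length(sp), length(np), dimnames = list(sp, np))
  n <- matrix(0L, length(sp), length(np), dimnames = list(sp, np))
  agg_m <- tapply(vt$volume, list(vt$species, vt$neuropil), mean)
  agg_s <- tapply(vt$volume, list(vt$species, vt$neuropil), stats::sd)
  agg_n <- tapply(vt$volume, list(vt$species, vt$neuropil), length)
  m[rownames(agg_m), colnames(agg_m)] <- agg_m
  s[rownames(agg_s), colnames(agg_s)] <- agg_s
  nn <- agg_n; nn[is.na(nn)] <- 0L
  n[rownames(agg_n), colnames(agg_n)] <- nn
  out <- list(mean = m, sd = s, n = n, reference = NULL, relative = NULL)
  class(out) <- "trait_matrix"
  out
}

#' Per-species reference volume from the undefined central-brain regions
#'
#' The reference ("central brain") volume is the per-specimen sum of the
#' undefined neuropils — by default the superior, ventrolateral, ventromedial,
#' inferior, circumesophageal and gnathal regions — averaged across a
#' species' specimens. Using only undefined neuropil as the allometric
#' control keeps every analysed (dependent) region out of the denominator.
#'
#' @param vt A side-summed volume table.
#' @param undefined_neuropils Regions whose sum defines the reference.
#' @param strict Error when a listed region is missing for a specimen
#'   (default); otherwise sum what is present with a warning.
#' @return Named numeric vector of species reference volumes.
#' @export
reference_volume <- function(vt, undefined_neuropils = .reference_regions,
                             strict = TRUE) {
  if (length(undefined_neuropils) == 0L)
    stop("undefined_neuropils must be non-empty", call. = FALSE)
  sub <- vt[vt$neuropil %in% undefined_neuropils, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no reference regions found in the volume table", call. = FALSE)
  per_spec <- tapply(sub$volume, list(sub$species, sub$specimen), sum)
  cnt <- tapply(sub$neuropil, list(sub$species, sub$specimen),
                function(x) length(unique(x)))
  incomplete <- which(!is.na(cnt) & cnt < length(undefined_neuropils),
                      arr.ind = TRUE)
  if (nrow(incomplete)) {
    msg <- paste0("reference region(s) missing for ",
                  nrow(incomplete), " specimen(s), e.g. ",
                  rownames(cnt)[incomplete[1, 1]], "/",
                  colnames(cnt)[incomplete[1, 2]])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  ref <- apply(per_spec, 1, mean, na.rm = TRUE)
  ref[sort(names(ref))]
}

#' Attach reference and relative volumes to a trait matrix
#'
#' Divides each species' mean volumes by that species' reference volume.
#' Missing cells stay missing. Relative volumes are dimensionless; the
#' operation is invariant to rescaling all volumes of a species by a common
#' factor applied to both numerator and reference.
#'
#' @param m A `"trait_matrix"` from [species_aggregate()].
#' @param reference Named numeric vector from [reference_volume()].
#' @return The trait matrix with `reference` and `relative` filled in.
#' @export
relative_volumes <- function(m, reference) {
  stopifnot(inherits(m, "trait_matrix"))
  sp <- rownames(m$mean)
  miss <- setdiff(sp, names(reference))
  if (length(miss))
    stop("no reference volume for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ref <- reference[sp]
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("reference volumes must be finite and > 0", call. = FALSE)
  m$reference <- ref
  m$relative <- sweep(m$mean, 1, ref, "/")
  m
}

#' Intra- versus inter-species variability per neuropil
#'
#' For each neuropil: the mean within-species coefficient of variation of raw
#' specimen volumes (species with >= 2 specimens), the between-species CV of
#' the species means, the same two dispersions as SDs of log volumes, and the
#' inter/intra ratio of CVs. Phylogenetic regression on species means is
#' justified when the ratio is large.
#'
#' @param vt A side-summed volume table.
#' @return Data.frame, one row per neuropil, with columns `neuropil`,
#'   `intra_cv`, `inter_cv`, `intra_sd_log`, `inter_sd_log`, `ratio`.
#' @export
variability_report <- function(vt) {
  res <- lapply(split(vt, vt$neuropil), function(g) {
    by_sp <- split(g$volume, g$species)
    cvs <- vapply(by_sp, function(v)
      if (length(v) >= 2) stats::sd(v) / mean(v) else NA_real_, numeric(1))
    sds_log <- vapply(by_sp, function(v)
      if (length(v) >= 2) stats::sd(log(v)) else NA_real_, numeric(1))
    means <- vapply(by_sp, mean, numeric(1))
    inter_cv <- if (length(means) >= 2) stats::sd(means) / mean(means) else NA_real_
    inter_sd_log <- if (length(means) >= 2) stats::sd(log(means)) else NA_real_
    intra_cv <- mean(cvs, na.rm = TRUE)
    data.frame(neuropil = g$neuropil[1],
               intra_cv = ifelse(is.nan(intra_cv), NA_real_, intra_cv),
               inter_cv = inter_cv,
               intra_sd_log = mean(sds_log, na.rm = TRUE),
               inter_sd_log = inter_sd_log,
               ratio = inter_cv / ifelse(is.nan(intra_cv), NA_real_, intra_cv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
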