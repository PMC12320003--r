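# Atlas-hierarchy seed connectivity: seed time courses, Fisher-z seed
# maps, multi-level correlation matrices, thresholded connectogram edge
# lists, seed-size scaling, and group averaging. The connectogram z
# threshold of 0.2 follows the usual reporting convention for these maps.

.Z_CAP_R <- 1 - 1e-7   # |r| clip before atanh

#' Mean time course of an atlas region
#'
#' Unweighted mean over all resolved voxels per frame. With
#' `include_descendants` (default) a parent region's course is the
#' voxel-mean over every descendant voxel (volume-weighted), not the mean
#' of child means.
#'
#' @param series `Image4D`.
#' @param atlas `AtlasHierarchy` on the series grid.
#' @param region_id region id.
#' @param include_descendants logical, default TRUE.
#' @param mask optional `Image3D` restricting the voxels.
#' @return numeric vector, one value per frame.
#' @export
seed_timecourse <- function(series, atlas, region_id,
                            include_descendants = TRUE, mask = NULL) {
  vox <- resolve_region(atlas, region_id, include_descendants)
  if (!is.null(mask)) vox <- intersect(vox, which(mask$data > 0))
  if (length(vox) == 0) stop("region ", region_id, " has no voxels in mask")
  nt <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nt)
  colMeans(flat[vox, , drop = FALSE])
}

#' Fisher-z seed connectivity map
#'
#' Pearson correlation of every voxel with the seed region's mean time
#' course, Fisher-transformed (`z = atanh(r)` with |r| clipped at
#' 1 - 1e-7, so a voxel identical to the seed hits the documented z cap).
#' Zero-variance voxels are undefined (NA). The threshold is stored, not
#' applied.
#'
#' @param series `Image4D` (>= 10 frames).
#' @param atlas `AtlasHierarchy`.
#' @param region_id seed region.
#' @param include_descendants resolve descendants into the seed.
#' @param threshold z threshold recorded on the map (default 0.2).
#' @param mask optional `Image3D`.
#' @return An object of class `SeedMap`: `zmap` (`Image3D`),
#'   `seed_region_id`, `n_seed_voxels`, `threshold`, `seed_voxels`
#'   (linear indices, flagged so suprathreshold accounting can exclude
#'   them).
#' @export
seed_map <- function(series, atlas, region_id, include_descendants = TRUE,
                     threshold = 0.2, mask = NULL) {
  nt <- dim(series$data)[4]
  if (nt < 10) stop("need at least 10 frames")
  seed_vox <- resolve_region(atlas, region_id, include_descendants)
  tc <- seed_timecourse(series, atlas, region_id, include_descendants,
                        mask)
  flat <- matrix(series$data, ncol = nt)
  tc_c <- tc - mean(tc)
  sd_tc <- sqrt(sum(tc_c^2))
  if (sd_tc == 0) stop("seed time course has zero variance")
  mu <- rowMeans(flat)
  num <- as.vector(flat %*% tc_c) - nt * mu * mean(tc_c)
  den <- sqrt(rowSums(flat^2) - nt * mu^2) * sd_tc
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -.Z_CAP_R), .Z_CAP_R)
  z <- atanh(r)
  if (!is.null(mask)) z[as.vector(mask$data) <= 0] <- NA_real_
  dm <- dim(series$data)[1:3]
  structure(list(zmap = image3d(array(z, dm), affine = series$affine,
                                kind = "anatomical"),
                 seed_region_id = region_id,
                 n_seed_voxels = length(seed_vox),
                 threshold = threshold,
                 seed_voxels = seed_vox),
            class = "SeedMap")
}

#' Region-by-region Fisher-z matrix at a hierarchy level
#'
#' Pairwise Fisher-z correlations of region mean time courses for all
#' regions at the given depth. Each region's course is the voxel-mean over
#' all its descendant voxels. The diagonal carries the sentinel NA.
#'
#' @param series `Image4D`.
#' @param atlas `AtlasHierarchy`.
#' @param level hierarchy depth (0 = roots).
#' @param mask optional `Image3D`.
#' @return An object of class `ConnectivityMatrix`: `z` (symmetric R x R),
#'   `region_ids`, `acronyms`, `level`.
#' @export
hierarchical_matrix <- function(series, atlas, level, mask = NULL) {
  regs <- regions_at_level(atlas, level)
  if (nrow(regs) < 2)
    stop("level ", level, " has fewer than 2 regions")
  keep <- vapply(regs$region_id, function(id) {
    vox <- resolve_region(atlas, id, TRUE)
    if (!is.null(mask)) vox <- intersect(vox, which(mask$data > 0))
    length(vox) > 0
  }, logical(1))
  regs <- regs[keep, , drop = FALSE]
  if (nrow(regs) < 2) stop("fewer than 2 regions with voxels at level ",
                           level)
  tcs <- vapply(regs$region_id, function(id)
    seed_timecourse(series, atlas, id, TRUE, mask),
    numeric(dim(series$data)[4]))
  r <- stats::cor(tcs)
  r <- pmin(pmax(r, -.Z_CAP_R), .Z_CAP_R)
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(regs$region_id, regs$region_id)
  structure(list(z = z, region_ids = regs$region_id,
                 acronyms = regs$acronym, level = level),
            class = "ConnectivityMatrix")
}

#' Suprathreshold connectogram edge list
#'
#' Undirected edges with z above the threshold, each unordered pair
#' reported once, sorted by |z| descending.
#'
#' @param mat `ConnectivityMatrix` (or plain symmetric matrix).
#' @param threshold z threshold (default 0.2).
#' @return data frame (region_a, region_b, z); zero rows allowed.
#' @export
connectogram_edges <- function(mat, threshold = 0.2) {
  z <- if (inherits(mat, "ConnectivityMatrix")) mat$z else mat
  ids <- if (!is.null(rownames(z))) rownames(z) else as.character(seq_len(nrow(z)))
  ut <- which(upper.tri(z) & !is.na(z) & z > threshold, arr.ind = TRUE)
  out <- data.frame(region_a = ids[ut[, 1]], region_b = ids[ut[, 2]],
                    z = z[ut])
  out[order(-abs(out$z)), , drop = FALSE]
}

#' Seed-size scaling of connectivity strength and extent
#'
#' For each seed region: suprathreshold mean z and voxel count at the
#' given threshold, and ordinary least-squares slopes of log(mean z) and
#' log(count) against log(seed size). Seed voxels are excluded from the
#' suprathreshold accounting by default, avoiding self-correlation
#' inflation; set `include_seed = TRUE` for the inclusive variant.
#'
#' @param series `Image4D`.
#' @param atlas `AtlasHierarchy`.
#' @param region_ids seed regions (>= 3 with distinct sizes recommended).
#' @param threshold z threshold (default 0.2).
#' @param include_seed include seed voxels in suprathreshold counts.
#' @param mask optional `Image3D`.
#' @return list: `table` (region_id, n_seed_voxels, mean_suprathreshold_z,
#'   n_suprathreshold, missing flag), `slope_strength`, `slope_count`
#'   (log-log OLS slopes).
#' @export
seed_size_scaling <- function(series, atlas, region_ids, threshold = 0.2,
                              include_seed = FALSE, mask = NULL) {
  if (length(region_ids) < 2)
    stop("need at least 2 seed regions for a scaling fit")
  rows <- lapply(region_ids, function(id) {
    sm <- seed_map(series, atlas, id, TRUE, threshold, mask)
    z <- as.vector(sm$zmap$data)
    if (!include_seed) z[sm$seed_voxels] <- NA_real_
    supra <- which(!is.na(z) & z > threshold)
    data.frame(region_id = id, n_seed_voxels = sm$n_seed_voxels,
               mean_suprathreshold_z = if (length(supra)) mean(z[supra])
                                       else NA_real_,
               n_suprathreshold = length(supra),
               missing = length(supra) == 0)
  })
  tab <- do.call(rbind, rows)
  fitdat <- tab[!tab$missing, , drop = FALSE]
  if (nrow(fitdat) < 2)
    stop("fewer than 2 regions with suprathreshold voxels: fit impossible")
  sl_strength <- stats::coef(stats::lm(
    log(mean_suprathreshold_z) ~ log(n_seed_voxels), data = fitdat))[[2]]
  sl_count <- stats::coef(stats::lm(
    log(n_suprathreshold) ~ log(n_seed_voxels), data = fitdat))[[2]]
  list(table = tab, slope_strength = sl_strength, slope_count = sl_count)
}

#' Average seed maps across subjects
#'
#' Voxel-wise mean in the Fisher-z domain over maps on a common grid;
#' optionally a one-sample t map.
#'
#' @param maps list of `SeedMap` on identical grids.
#' @param t_map also compute a per-voxel one-sample t statistic.
#' @return `SeedMap` whose `zmap` is the group mean; attribute `n` gives
#'   the subject count, attribute `tmap` the t map if requested.
#' @export
group_average <- function(maps, t_map = FALSE) {
  if (length(maps) == 0) stop("no maps")
  dm <- dim(maps[[1]]$zmap$data)
  for (m in maps) if (!all(dim(m$zmap$data) == dm)) stop("grid mismatch")
  stack <- vapply(maps, function(m) as.vector(m$zmap$data),
                  numeric(prod(dm)))
  mu <- rowMeans(stack)
  out <- maps[[1]]
  out$zmap <- image3d(array(mu, dm), affine = maps[[1]]$zmap$affine,
                      kind = "anatomical")
  attr(out, "n") <- length(maps)
  if (t_map && length(maps) >= 2) {
    sdv <- apply(stack, 1, stats::sd)
    tv <- ifelse(sdv > 0, mu / (sdv / sqrt(length(maps))), NA_real_)
    attr(out, "tmap") <- image3d(array(tv, dm),
                                 affine = maps[[1]]$zmap$affine,
                                 kind = "anatomical")
  }
  out
}

#' Write a connectivity matrix as CSV (region-id header)
#' @param mat `ConnectivityMatrix`.
#' @param path output path.
#' @export
write_connectivity_csv <- function(mat, path) {
  df <- as.data.frame(mat$z)
  utils::write.csv(cbind(region_id = rownames(mat$z), df), path,
                   row.names = FALSE)
  invisible(path)
}
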