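# Quality-control metrics and the end-to-end pipeline runner. The stage
# order is fixed: distortion-shift computation -> denoise -> motion
# estimation -> one-shot warp -> nuisance cleaning -> (optional) alignment
# -> connectome. Denoising precedes motion estimation because RMT-PCA
# assumes stationary thermal noise and a denoised series registers better;
# all spatial corrections still collapse into the single warp.

#' Temporal signal-to-noise ratio map
#'
#' Per-voxel temporal mean divided by temporal SD of the linearly
#' detrended series. Zero-SD voxels are NA.
#'
#' @param series `Image4D` (>= 3 frames).
#' @param mask optional `Image3D`; outside voxels are NA.
#' @return `Image3D` tSNR map.
#' @export
tsnr_map <- function(series, mask = NULL) {
  stopifnot(inherits(series, "Image4D"))
  dm <- dim(series$data)
  nt <- dm[4]
  if (nt < 3) stop("need at least 3 frames for tSNR")
  flat <- matrix(series$data, ncol = nt)
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  beta <- flat %*% X %*% solve(crossprod(X))
  resid <- flat - beta %*% t(X)
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums(resid^2) / (nt - 2))
  # a residual SD at numerical-noise level means the voxel has no temporal
  # fluctuation left; its tSNR is undefined, not astronomically large
  tsnr <- ifelse(sdv > 1e-8 * pmax(abs(mu), 1e-300), mu / sdv, NA_real_)
  if (!is.null(mask)) tsnr[as.vector(mask$data) <= 0] <- NA_real_
  image3d(array(tsnr, dm[1:3]), affine = series$affine,
          kind = "anatomical")
}

#' Masked Pearson correlation between two volumes
#' @param a,b `Image3D` on one grid.
#' @param mask optional `Image3D`.
#' @return Pearson r.
#' @export
image_correlation <- function(a, b, mask = NULL) {
  if (!all(dim(a$data) == dim(b$data))) stop("grids differ")
  mk <- if (is.null(mask)) rep(TRUE, length(a$data)) else as.vector(mask$data > 0)
  va <- as.vector(a$data)[mk]; vb <- as.vector(b$data)[mk]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance inside mask")
  stats::cor(va, vb)
}

#' Default pipeline configuration
#'
#' @param seed RNG seed for the run.
#' @param out_dir output directory (NULL: in-memory only).
#' @return named list of stage toggles and parameters; see the fields.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    denoise = list(enabled = TRUE, window = c(3L, 3L), stride = 1L,
                   method = "mp_edge", tw_p = 0.95),
    motion = list(enabled = TRUE,
                  stages = c("pe2d", "rigid3d", "nonrigid"),
                  nonrigid_patch = 20L),
    fieldmap = list(enabled = TRUE, pe_polarity = 1),
    warp = list(interp = "cubic_spline", upsample = 1L),
    clean = list(enabled = TRUE, band_hz = c(0.01, 0.1),
                 drift = list(type = "cosine", cutoff_hz = 0.01)),
    connectome = list(seeds = NULL, levels = NULL, threshold = 0.2)
  )
}

.config_validate <- function(config) {
  need <- c("seed", "denoise", "motion", "fieldmap", "warp", "clean",
            "connectome")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  stopifnot(is.numeric(config$seed),
            config$warp$interp %in% c("linear", "cubic_spline", "sinc"))
  invisible(config)
}

.provenance <- function(config, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  c(list(config = config, config_md5 = hash,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("laminarfc")),
         timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Run the full preprocessing + connectome pipeline
#'
#' Executes the branches in order: field-map shift computation, RMT-PCA
#' denoising, staged motion estimation, one-shot composed warp, nuisance
#' regression and band-pass, then atlas connectivity. After each starred
#' stage a QC record is appended (tSNR, residual Gaussianity, correlation
#' to reference, FWHM). Fully deterministic given `config$seed`.
#'
#' @param func `Image4D` functional series.
#' @param config list from [pipeline_config()].
#' @param fieldmap optional `Image3D` (kind fieldmap_hz) on the EPI grid.
#' @param acq [acquisition_params()]; required when a field map is given.
#' @param atlas optional `AtlasHierarchy` in EPI space (after alignment).
#' @param anat optional `Image3D` used for QC correlation.
#' @param verbose print stage progress.
#' @return list: `cleaned` (`Image4D`), `denoised`, `corrected`, `motion`,
#'   `matrices` (per level), `seed_maps`, `edges`, `qc` (list of stage
#'   records), `provenance`.
#' @export
run_pipeline <- function(func, config = pipeline_config(),
                         fieldmap = NULL, acq = NULL, atlas = NULL,
                         anat = NULL, verbose = FALSE) {
  .config_validate(config)
  set.seed(config$seed)
  qc <- list()
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  stage_rec <- function(name, ...) {
    rec <- list(stage = name,
                wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                ...)
    qc[[name]] <<- rec
    say("[", name, "] done (", round(rec$wall_s, 1), " s)")
  }
  dm <- dim(func$data)[1:3]
  nt <- dim(func$data)[4]
  pe <- func$pe_axis + 1L
  spacing <- .affine_spacing(func$affine)
  # QC mask from the temporal mean (metrics are meaningless in background)
  mean_img <- image3d(apply(func$data, 1:3, mean), affine = func$affine,
                      kind = "anatomical")
  qc_mask <- tryCatch(make_brain_mask(mean_img), error = function(e) NULL)

  # field-map shift (Fmap branch)
  b0_field <- NULL
  if (config$fieldmap$enabled && !is.null(fieldmap)) {
    if (is.null(acq)) stop("field map given but no acquisition parameters")
    b0_field <- fieldmap_to_shift(fieldmap, acq, pe_axis = func$pe_axis,
                                  pe_polarity = config$fieldmap$pe_polarity)
    stage_rec("fieldmap", max_shift_vox = max(abs(b0_field$shifts)))
  }

  # denoise (Func branch)
  denoised <- func
  if (config$denoise$enabled) {
    dn <- denoise_series(func, window = config$denoise$window,
                         stride = config$denoise$stride,
                         mask = NULL, method = config$denoise$method,
                         tw_p = config$denoise$tw_p)
    denoised <- dn$denoised
    gauss <- residual_gaussianity(dn$noise_residual, mask = qc_mask)
    tsnr_raw <- mean(tsnr_map(func, qc_mask)$data, na.rm = TRUE)
    tsnr_dn <- mean(tsnr_map(denoised, qc_mask)$data, na.rm = TRUE)
    stage_rec("denoise", tsnr_raw = tsnr_raw, tsnr_denoised = tsnr_dn,
              tsnr_gain = tsnr_dn / tsnr_raw,
              residual_sigma = gauss$sigma,
              residual_ad_stat = gauss$statistic,
              residual_ad_p = gauss$p_value)
  }

  # motion estimation (never resamples the delivered data)
  motion <- NULL
  if (config$motion$enabled) {
    motion <- estimate_motion(denoised, stages = config$motion$stages,
                              spacing = spacing,
                              nonrigid_patch = config$motion$nonrigid_patch,
                              verbose = verbose)
    stage_rec("motion",
              quality = stats::setNames(motion$quality$mean_corr,
                                        motion$quality$stage))
  }

  # one-shot warp: compose B0 + pe2d + rigid + nonrigid per frame
  corrected <- denoised
  if (!is.null(b0_field) || !is.null(motion)) {
    fields <- vector("list", nt)
    for (t in seq_len(nt)) {
      maps <- list()
      if (!is.null(b0_field))
        maps <- c(maps, list(list(type = "field", field = b0_field)))
      if (!is.null(motion)) {
        if ("pe2d" %in% config$motion$stages)
          maps <- c(maps, list(list(
            type = "pe_translate",
            shifts = -motion$rigid$per_slice_pe_shift[t, ], axis = pe)))
        if ("rigid3d" %in% config$motion$stages)
          maps <- c(maps, list(list(
            type = "rigid",
            par = as.numeric(motion$rigid$per_frame[t, ]),
            spacing = spacing, dm = dm, inverse = TRUE)))
        if ("nonrigid" %in% config$motion$stages && !is.null(motion$nonrigid))
          maps <- c(maps, list(list(type = "field",
                                    field = motion$nonrigid[[t]])))
      }
      fields[[t]] <- compose_shifts(maps, dm,
                                    upsample = config$warp$upsample)
    }
    corrected <- resample_once(denoised, fields,
                               interp = config$warp$interp)
    fw <- estimate_fwhm(corrected)
    rec <- list(fwhm = fw$average, interp = config$warp$interp)
    if (!is.null(anat) && all(dim(anat$data) == dim(corrected$data)[1:3])) {
      corr_mean <- image3d(apply(corrected$data, 1:3, mean),
                           affine = corrected$affine, kind = "anatomical")
      rec$corr_to_anat <- image_correlation(corr_mean, anat)
    }
    do.call(stage_rec, c(list("warp"), rec))
  }

  # nuisance cleaning
  cleaned <- corrected
  if (config$clean$enabled) {
    design <- suppressWarnings(
      build_design(motion$rigid %||% NULL, nt, tr_s = func$tr_s,
                   drift_spec = config$clean$drift))
    design <- bandpass_design(design, config$clean$band_hz, func$tr_s)
    cleaned <- regress_nuisance(corrected, design)
    cleaned <- bandpass(cleaned, config$clean$band_hz)
    stage_rec("clean", n_regressors = ncol(design$regressors),
              band_hz = config$clean$band_hz)
  }

  # connectome
  matrices <- list(); smaps <- list(); edges <- list()
  if (!is.null(atlas)) {
    if (config$warp$upsample != 1L)
      stop("atlas connectivity with an upsampled warp grid requires an ",
           "upsampled atlas; provide one or set warp$upsample = 1")
    levels <- config$connectome$levels
    if (is.null(levels)) levels <- sort(unique(atlas$regions$depth))
    for (lv in levels) {
      if (nrow(regions_at_level(atlas, lv)) < 2) next
      key <- as.character(lv)
      matrices[[key]] <- hierarchical_matrix(cleaned, atlas, lv)
      edges[[key]] <- connectogram_edges(matrices[[key]],
                                         config$connectome$threshold)
    }
    seeds <- config$connectome$seeds
    if (!is.null(seeds))
      for (s in seeds)
        smaps[[as.character(s)]] <- seed_map(cleaned, atlas, s,
          threshold = config$connectome$threshold)
    stage_rec("connectome", n_levels = length(matrices),
              n_seed_maps = length(smaps))
  }

  prov <- .provenance(config, list(n_frames = nt, dim = dm))
  out <- list(cleaned = cleaned, denoised = denoised,
              corrected = corrected, motion = motion,
              matrices = matrices, seed_maps = smaps, edges = edges,
              qc = qc, provenance = prov)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(cleaned, file.path(config$out_dir, "cleaned.nii.gz"))
    if (!is.null(motion))
      write_motion_tsv(motion$rigid, file.path(config$out_dir,
                                               "motion.tsv"))
    for (key in names(matrices))
      write_connectivity_csv(matrices[[key]],
        file.path(config$out_dir, paste0("matrix_level", key, ".csv")))
    for (key in names(edges))
      utils::write.table(edges[[key]],
        file.path(config$out_dir, paste0("edges_level", key, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(prov, file.path(config$out_dir,
                                         "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    jsonlite::write_json(qc, file.path(config$out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
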