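# Layered digital brain phantom with known ground truth: concentric
# cortical layer bands (thickness proportions mirroring barrel-field
# laminae, ~0.12/0.25/0.20/0.27/0.32 mm of a 1.16 mm cortex), a white
# matter band, subcortical nuclei, a 3-level region hierarchy, planted
# band-limited BOLD correlations, rigid/non-rigid motion, a B0 field map
# and Gaussian thermal noise. Every pipeline stage can be validated
# against the planted truth.

.default_layer_weights <- c(0.12, 0.25, 0.20, 0.27, 0.32)

#' Generate a layered brain phantom and its atlas hierarchy
#'
#' Builds an elliptical "brain" with a cortical shell split into
#' `n_layers` concentric bands, a white-matter band, and two subcortical
#' nuclei. The hierarchy has three levels: region (CTX, SUB, WM) ->
#' subregion (left/right sectors) -> layer/nucleus leaves. Cortical bands
#' are delimited on an equal-area radial coordinate so band voxel counts
#' are proportional to the requested thickness weights.
#'
#' @param shape integer (nx, ny, nz), nx and ny >= 32.
#' @param n_layers number of cortical layers (>= 2).
#' @param seed RNG seed for the anatomical texture.
#' @param layer_weights relative layer thicknesses, outermost first;
#'   default mirrors barrel-field laminar thicknesses. Recycled/truncated
#'   to `n_layers` and renormalised.
#' @param spacing voxel spacing in mm (default 0.25 in-plane, 0.5 through
#'   plane).
#' @param psf_sigma Gaussian sigma (voxels) of the imaging point-spread
#'   function applied to the anatomical intensities (labels stay crisp);
#'   real MRI is band-limited, and voxel-sharp edges would be
#'   unrealistically aliased. Default 0.8.
#' @return list: `anatomical` (`Image3D`), `atlas` (`AtlasHierarchy`).
#' @export
make_layered_phantom <- function(shape = c(96L, 48L, 9L), n_layers = 5L,
                                 seed = 1L,
                                 layer_weights = .default_layer_weights,
                                 spacing = c(0.25, 0.25, 0.5),
                                 psf_sigma = 0.8) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  if (nx < 32 || ny < 32) stop("shape too small: need nx, ny >= 32")
  if (n_layers < 2 || n_layers > 9)
    stop("n_layers must be between 2 and 9 (region-id scheme)")
  w <- rep_len(layer_weights, n_layers)
  w <- w / sum(w)
  rx <- 0.44 * nx; ry <- 0.44 * ny
  u_c <- 0.62                      # inner cortex radius (normalized)
  u_w <- 0.46                      # inner white-matter radius
  # every band sector must hold at least a voxel (equal-area banding:
  # expected count = shell area x weight / 2 sectors)
  shell_area <- pi * rx * ry * (1 - u_c^2)
  if (shell_area * min(w) / 2 < 1)
    stop("shape too small to hold ", n_layers, " bands >= 1 voxel thick")
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  xg <- matrix(rep(seq_len(nx), ny), nx, ny)
  yg <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  # ellipsoid taper: slice radii shrink toward the volume ends so the
  # through-plane direction carries real anatomical gradients
  fz <- if (nz > 1) sqrt(pmax(1 - 0.5 * ((seq_len(nz) - cz) / (nz / 2))^2,
                              0.3))
        else 1
  labels <- array(0, c(nx, ny, nz))
  # region table ids
  reg <- list()
  add <- function(id, acr, parent) {
    reg[[length(reg) + 1L]] <<- data.frame(region_id = id, acronym = acr,
                                           parent_id = parent)
  }
  add(1L, "CTX", NA); add(2L, "SUB", NA); add(3L, "WM", NA)
  add(10L, "CTX-L", 1L); add(20L, "CTX-R", 1L)
  add(30L, "SUB-L", 2L); add(40L, "SUB-R", 2L)
  add(50L, "WM-b", 3L)
  for (k in seq_len(n_layers)) {
    add(10L + k, paste0("CTX-L-L", k), 10L)
    add(20L + k, paste0("CTX-R-L", k), 20L)
  }
  add(31L, "SUB-L-n", 30L); add(41L, "SUB-R-n", 40L)
  add(51L, "WM-b-c", 50L)
  regions <- do.call(rbind, reg)

  # cortical shell on equal-area coordinate: a in (0, 1], outer edge a = 1
  cum <- cumsum(w)                 # from outermost band inwards
  set.seed(seed)
  anat <- array(0, c(nx, ny, nz))
  tex <- smooth_gauss(array(stats::rnorm(nx * ny * nz), c(nx, ny, nz)), 1.2)
  tex <- tex / stats::sd(tex) * 6
  ripple <- 5 * sin(2 * pi * xg / 11) * cos(2 * pi * yg / 7)
  for (z in seq_len(nz)) {
    rz_ <- rx * fz[min(z, length(fz))]
    ry_ <- ry * fz[min(z, length(fz))]
    u2 <- ((xg - cx) / rz_)^2 + ((yg - cy) / ry_)^2
    a_coord <- (u2 - u_c^2) / (1 - u_c^2)
    lab2d <- matrix(0L, nx, ny)
    in_cortex <- u2 <= 1 & u2 > u_c^2
    for (k in seq_len(n_layers)) {
      lo <- 1 - cum[k]
      hi <- if (k == 1) 1 else 1 - cum[k - 1]
      band <- in_cortex & a_coord > lo & a_coord <= hi
      lab2d[band & xg <  cx] <- 10L + k
      lab2d[band & xg >= cx] <- 20L + k
    }
    lab2d[u2 <= u_c^2 & u2 > u_w^2] <- 51L
    in_sub <- u2 <= u_w^2
    lab2d[in_sub & xg <  cx] <- 31L
    lab2d[in_sub & xg >= cx] <- 41L
    labels[, , z] <- lab2d
    base2d <- matrix(0, nx, ny)
    for (k in seq_len(n_layers)) {
      v <- 85 + 8 * k                   # laminar intensity gradient
      base2d[lab2d %in% c(10L + k, 20L + k)] <- v
    }
    base2d[lab2d == 51L] <- 150
    base2d[lab2d %in% c(31L, 41L)] <- 70
    sl <- base2d
    sl[lab2d > 0] <- sl[lab2d > 0] + ripple[lab2d > 0] + tex[, , z][lab2d > 0]
    anat[, , z] <- sl
  }
  anat[anat < 0] <- 0
  if (psf_sigma > 0) anat <- smooth_gauss(anat, psf_sigma)
  aff <- diag(c(spacing, 1))
  anat_img <- image3d(anat, affine = aff, kind = "anatomical")
  atlas <- atlas_hierarchy(image3d(labels, affine = aff, kind = "label"),
                           regions)
  list(anatomical = anat_img, atlas = atlas)
}

# band-limiting FFT mask filter: keeps frequency content in [lo, hi] Hz,
# columns of x are time series
.band_filter_cols <- function(x, tr_s, band_hz) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)             # two-sided frequency magnitude
  keep <- f >= band_hz[1] & f <= band_hz[2]
  if (!any(keep)) {
    # series too short to resolve the band: keep the nonzero frequency
    # pair closest to the band centre so the signal survives
    tgt <- mean(band_hz)
    cand <- which(f > 0)
    kbin <- cand[which.min(abs(f[cand] - tgt))]
    keep[abs(f - f[kbin]) < 1e-12] <- TRUE
  }
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Simulate band-limited BOLD fluctuations with planted correlations
#'
#' Every leaf region of the atlas receives a latent band-limited time
#' course; the latent courses are mixed so that region pairs listed in
#' `network_corr` attain the planted Pearson correlations (all other pairs
#' are independent). Voxels within a region share the region course plus
#' small independent band-limited jitter. The output is the zero-mean
#' fluctuation series (add a baseline for a full EPI signal model).
#'
#' @param atlas `AtlasHierarchy`.
#' @param network_corr data frame (region_a, region_b, r) of planted
#'   correlations between leaf regions; NULL plants none.
#' @param n_frames number of frames.
#' @param tr_s repetition time (s).
#' @param band_hz fluctuation band, default c(0.01, 0.1) — the infra-slow
#'   band BOLD fluctuations live in.
#' @param seed RNG seed.
#' @param amplitude region-course standard deviation (intensity units).
#' @param jitter_sd voxel-level jitter SD as a fraction of `amplitude`
#'   (default 0.1).
#' @return `Image4D` of fluctuations on the atlas grid.
#' @export
simulate_bold <- function(atlas, network_corr = NULL, n_frames = 300L,
                          tr_s = 1, band_hz = c(0.01, 0.1), seed = 1L,
                          amplitude = 1, jitter_sd = 0.1) {
  stopifnot(inherits(atlas, "AtlasHierarchy"))
  if (band_hz[2] >= 1 / (2 * tr_s)) stop("band exceeds Nyquist")
  reg <- atlas$regions
  leaves <- reg$region_id[!reg$region_id %in% reg$parent_id]
  leaves <- leaves[leaves %in% unique(as.vector(atlas$labels$data))]
  R <- length(leaves)
  C <- diag(R)
  if (!is.null(network_corr) && nrow(network_corr) > 0) {
    for (i in seq_len(nrow(network_corr))) {
      a <- match(network_corr$region_a[i], leaves)
      b <- match(network_corr$region_b[i], leaves)
      if (is.na(a) || is.na(b))
        stop("network_corr names a region that is not a labelled leaf")
      C[a, b] <- C[b, a] <- network_corr$r[i]
    }
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("planted correlation table is not positive semidefinite")
  L <- t(chol(C + diag(1e-10, R)))
  set.seed(seed)
  S <- matrix(stats::rnorm(n_frames * R), n_frames, R)
  S <- .band_filter_cols(S, tr_s, band_hz)
  S <- scale(S)                          # unit variance, zero mean
  Y <- S %*% t(L)                        # planted correlation structure
  Y <- sweep(Y, 2, apply(Y, 2, stats::sd), "/") * amplitude
  dm <- dim(atlas$labels$data)
  out <- array(0, c(dm, n_frames))
  flat <- matrix(out, ncol = n_frames)
  lab <- as.vector(atlas$labels$data)
  for (j in seq_len(R)) {
    vox <- which(lab == leaves[j])
    if (length(vox) == 0) next
    flat[vox, ] <- matrix(Y[, j], length(vox), n_frames, byrow = TRUE)
    if (jitter_sd > 0) {
      jit <- matrix(stats::rnorm(length(vox) * n_frames), n_frames,
                    length(vox))
      jit <- .band_filter_cols(jit, tr_s, band_hz)
      sdj <- apply(jit, 2, stats::sd)
      jit <- sweep(jit, 2, ifelse(sdj > 0, sdj, 1), "/") *
        (jitter_sd * amplitude)
      flat[vox, ] <- flat[vox, ] + t(jit)
    }
  }
  image4d(array(flat, c(dm, n_frames)), affine = atlas$labels$affine,
          tr_s = tr_s, pe_axis = 1L)
}

#' Assemble a complete phantom truth bundle
#'
#' Generates anatomy + atlas, a clean EPI series (tissue baseline plus
#' planted BOLD fluctuations), ground-truth rigid and non-rigid motion, a
#' per-slice phase-encode drift, a smooth B0 field map, and the thermal
#' noise level. Defaults give a pre-denoising tSNR of about 10.
#'
#' @param shape (nx, ny, nz).
#' @param n_frames frames.
#' @param seed RNG seed driving all randomness.
#' @param tr_s repetition time (s).
#' @param noise_sigma thermal noise SD (intensity units); the default 6
#'   against a mean brain baseline of about 60 gives tSNR ~ 10.
#' @param bold_amplitude region BOLD fluctuation SD (default 2).
#' @param motion_scale scales the ground-truth motion amplitudes (0
#'   disables motion).
#' @param fieldmap_hz peak off-resonance of the B0 blob (default 40 Hz).
#' @param network_corr planted correlation table; the default plants
#'   r = 0.6 between homotopic layer-2 cortex and between the subcortical
#'   nuclei, and r = 0.5 between left layer-4 and the left nucleus.
#' @param n_layers cortical layers (default 5).
#' @return An object of class `PhantomTruth`: `clean_series`,
#'   `anatomical`, `atlas`, `rigid_motion`, `nonrigid_field_per_frame`,
#'   `fieldmap`, `network_corr`, `noise_sigma`, `acq`, `baseline`.
#' @export
make_phantom_truth <- function(shape = c(48L, 48L, 3L), n_frames = 200L,
                               seed = 1L, tr_s = 1, noise_sigma = 6,
                               bold_amplitude = 2, motion_scale = 1,
                               fieldmap_hz = 40, network_corr = NULL,
                               n_layers = 5L) {
  ph <- make_layered_phantom(shape, n_layers = n_layers, seed = seed)
  atlas <- ph$atlas
  dm <- shape
  if (is.null(network_corr)) {
    network_corr <- data.frame(
      region_a = c(12L, 31L, 14L),
      region_b = c(22L, 41L, 31L),
      r = c(0.6, 0.6, 0.5))
  }
  bold <- simulate_bold(atlas, network_corr, n_frames = n_frames,
                        tr_s = tr_s, seed = seed + 1L,
                        amplitude = bold_amplitude)
  # EPI baseline: anatomical contrast compressed toward EPI-like contrast
  baseline <- 20 + 0.55 * ph$anatomical$data
  baseline[atlas$labels$data == 0] <- 0
  clean <- bold$data
  for (t in seq_len(n_frames))
    clean[, , , t] <- clean[, , , t] + as.vector(baseline)
  aff <- ph$anatomical$affine
  clean_series <- image4d(clean, affine = aff, tr_s = tr_s, pe_axis = 1L)

  set.seed(seed + 2L)
  tt <- seq_len(n_frames)
  mk_wave <- function(amp, period, phase) amp * sin(2 * pi * tt / period + phase)
  spacing <- .affine_spacing(aff)
  per_frame <- data.frame(
    tx = motion_scale * mk_wave(0.35 * spacing[1], 37, 0.3),
    ty = motion_scale * mk_wave(0.30 * spacing[2], 53, 1.1),
    tz = 0,
    rx = 0, ry = 0,
    rz = motion_scale * mk_wave(0.6, 41, 2.0))
  per_frame[1, ] <- 0                      # reference frame is motion-free
  pe_drift <- matrix(0, n_frames, dm[3])
  for (z in seq_len(dm[3]))
    pe_drift[, z] <- motion_scale * mk_wave(0.25 + 0.05 * z, 29 + 3 * z,
                                            0.5 * z)
  pe_drift[1, ] <- 0
  rm_truth <- rigid_motion(per_frame, pe_drift)

  # slowly varying non-rigid deformation, shared spatial mode per frame
  xg <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2])
  yg <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2])
  mode_x <- sin(pi * xg / dm[1]) * sin(2 * pi * yg / dm[2])
  mode_y <- sin(2 * pi * xg / dm[1]) * sin(pi * yg / dm[2])
  amp_t <- motion_scale * 0.3 * sin(2 * pi * tt / 61 + 0.7)
  amp_t[1] <- 0
  nonrigid <- lapply(seq_len(n_frames), function(t) {
    sh <- array(0, c(dm, 3L))
    for (z in seq_len(dm[3])) {
      sh[, , z, 1] <- amp_t[t] * mode_x
      sh[, , z, 2] <- amp_t[t] * mode_y
    }
    displacement_field(sh)
  })

  fm2d <- fieldmap_hz * exp(-(((xg - dm[1] * 0.6) / (0.25 * dm[1]))^2 +
                              ((yg - dm[2] * 0.45) / (0.25 * dm[2]))^2))
  fm <- array(0, dm)
  for (z in seq_len(dm[3])) fm[, , z] <- fm2d
  fieldmap <- image3d(fm, affine = aff, kind = "fieldmap_hz")

  acq <- acquisition_params(tr_s = tr_s, matrix = c(dm[1], dm[2]),
                            fov_mm = c(dm[1] * spacing[1],
                                       dm[2] * spacing[2]))
  structure(list(clean_series = clean_series, anatomical = ph$anatomical,
                 atlas = atlas, rigid_motion = rm_truth,
                 nonrigid_field_per_frame = nonrigid, fieldmap = fieldmap,
                 network_corr = network_corr, noise_sigma = noise_sigma,
                 acq = acq, baseline = baseline, seed = seed),
            class = "PhantomTruth")
}

#' Apply the acquisition forward model to a clean series
#'
#' Per frame, the physical corruption chain is applied in the fixed order
#' non-rigid deformation -> rigid motion -> per-slice PE translation ->
#' B0 distortion shift, composed into one mapping and applied with a
#' single interpolation; i.i.d. Gaussian thermal noise of `noise_sigma`
#' is then added. With zero motion, zero field map, and zero noise the
#' output equals the input exactly.
#'
#' @param clean `Image4D` clean series.
#' @param truth `PhantomTruth` (its motion/fieldmap/noise fields are used).
#' @param acq [acquisition_params()]; defaults to `truth$acq`.
#' @param seed RNG seed for the noise draw.
#' @param interp interpolation kernel for the forward resampling.
#' @return `Image4D` acquired series.
#' @export
apply_acquisition <- function(clean, truth, acq = NULL, seed = 1L,
                              interp = "cubic_spline") {
  stopifnot(inherits(clean, "Image4D"), inherits(truth, "PhantomTruth"))
  if (is.null(acq)) acq <- truth$acq
  dm <- dim(clean$data)[1:3]
  nt <- dim(clean$data)[4]
  if (!all(dim(truth$fieldmap$data) == dm))
    stop("truth geometry does not match the clean series")
  pe <- clean$pe_axis + 1L
  spacing <- .affine_spacing(clean$affine)
  b0 <- fieldmap_to_shift(truth$fieldmap, acq, pe_axis = clean$pe_axis,
                          pe_polarity = 1)
  b0_fwd <- displacement_field(-b0$shifts)   # forward distortion pullback
  pf <- as.matrix(truth$rigid_motion$per_frame)
  pe_drift <- truth$rigid_motion$per_slice_pe_shift
  fields <- vector("list", nt)
  for (t in seq_len(nt)) {
    maps <- list(
      list(type = "field", field = b0_fwd),
      list(type = "pe_translate", shifts = -pe_drift[t, ], axis = pe),
      list(type = "rigid", par = pf[t, ], spacing = spacing, dm = dm,
           inverse = TRUE),
      list(type = "field", field = truth$nonrigid_field_per_frame[[t]]))
    fields[[t]] <- compose_shifts(maps, dm)
  }
  acquired <- resample_once(clean, fields, interp = interp)
  if (truth$noise_sigma > 0) {
    set.seed(seed)
    acquired$data <- acquired$data +
      array(stats::rnorm(prod(dim(acquired$data)), sd = truth$noise_sigma),
            dim(acquired$data))
  }
  acquired
}

#' Write the phantom truth bundle to disk
#' @param truth `PhantomTruth`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_phantom_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_image(truth$clean_series, file.path(dir, "clean.nii.gz"))
  write_image(truth$anatomical, file.path(dir, "anat.nii.gz"))
  write_image(truth$atlas$labels, file.path(dir, "atlas_labels.nii.gz"))
  write_image(truth$fieldmap, file.path(dir, "fieldmap.nii.gz"))
  write_region_table(truth$atlas$regions, file.path(dir, "regions.csv"))
  write_motion_tsv(truth$rigid_motion, file.path(dir, "motion_truth.tsv"))
  utils::write.csv(truth$network_corr, file.path(dir, "network_corr.csv"),
                   row.names = FALSE)
  invisible(dir)
}
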