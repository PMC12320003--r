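# Shared fixtures, memoised per test session so heavy phantoms are built
# once, and small numeric oracles used across test files.

.fix_env <- new.env(parent = emptyenv())
get_fixture <- function(name, fn) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- fn()
  .fix_env[[name]]
}

phantom48 <- function() get_fixture("phantom48", function()
  make_layered_phantom(c(48L, 48L, 3L), 5L, seed = 1L))

phantom48z5 <- function() get_fixture("phantom48z5", function()
  make_layered_phantom(c(48L, 48L, 5L), 5L, seed = 2L))

# exact periodic sub-voxel shift via Fourier phase ramp (test oracle,
# independent of the package's interpolation machinery)
fourier_shift_2d <- function(img, s1, s2) {
  dm <- dim(img)
  f1 <- ((seq_len(dm[1]) - 1) + floor(dm[1] / 2)) %% dm[1] - floor(dm[1] / 2)
  f2 <- ((seq_len(dm[2]) - 1) + floor(dm[2] / 2)) %% dm[2] - floor(dm[2] / 2)
  ph <- exp(-2i * pi * (outer(f1, rep(1, dm[2])) * s1 / dm[1] +
                        outer(rep(1, dm[1]), f2) * s2 / dm[2]))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / prod(dm)
}

# wrap a raw matrix as a Casorati container
as_casorati <- function(m) {
  structure(list(values = m, patch_origin = c(1L, 1L, 1L),
                 window = c(3L, 3L)),
            class = "CasoratiMatrix")
}

# binary mask Image3D of a phantom's labelled support
support_mask <- function(ph) {
  image3d(array(as.numeric(ph$atlas$labels$data > 0),
                dim(ph$atlas$labels$data)),
          affine = ph$atlas$labels$affine, kind = "mask")
}

# homogeneous-tissue anatomy on a phantom's support (for bias-field tests:
# tissue with only mild texture, so a smooth gain is identifiable)
homogeneous_anat <- function(ph, texture_sd = 1, seed = 4L) {
  dm <- dim(ph$atlas$labels$data)
  mk <- ph$atlas$labels$data > 0
  set.seed(seed)
  tex <- laminarfc:::smooth_gauss(array(stats::rnorm(prod(dm)), dm), 1.2)
  tex <- tex / stats::sd(tex) * texture_sd
  a <- array(1e-3, dm)
  a[mk] <- 100 + tex[mk]
  image3d(a, affine = ph$atlas$labels$affine, kind = "anatomical")
}

# pullback-warp a 3D array by a shift array (test-side generator)
warp_by_field <- function(vol, sh, method = "sinc") {
  dm <- dim(vol)
  pts <- laminarfc:::.grid_coords(dm)
  p <- pts + matrix(sh, ncol = 3)
  array(laminarfc:::interp3(vol, p[, 1], p[, 2], p[, 3], method,
                            fill = "edge"), dm)
}

# rigid-recovery replicates (shared by module and acceptance tests):
# random in-plane truths on the layered phantom, errors vs the analytic
# inverse parameters
rigid_recovery_reps <- function() get_fixture("rigid_reps", function() {
  # 9-slice slab: out-of-plane rotation is identifiable, matching the
  # acquisition geometry the method targets
  ph <- get_fixture("phantom48z9", function()
    make_layered_phantom(c(48L, 48L, 9L), 5L, seed = 1L))
  vol <- ph$anatomical$data
  set.seed(22)
  out <- data.frame(trans_err = numeric(20), rot_err = numeric(20))
  for (i in 1:20) {
    par_true <- c(runif(1, -1, 1), runif(1, -1, 1), 0,
                  runif(1, -1, 1), 0, runif(1, -2.5, 2.5))
    moved <- laminarfc:::transform_rigid_3d(vol, par_true, c(1, 1, 1),
                                            method = "sinc", fill = "edge")
    fit <- estimate_rigid_3d(moved, vol, c(1, 1, 1))
    expected <- invert_linear(list(model = "rigid", par = par_true,
                                   spacing = c(1, 1, 1),
                                   dm = dim(vol)))$par
    out$trans_err[i] <- max(abs(fit$par[1:3] - expected[1:3]))
    out$rot_err[i] <- max(abs(fit$par[4:6] - expected[4:6]))
  }
  out
})

# non-rigid sinusoidal recovery (shared): RMS error in the brain mask
# against the numerically inverted truth field, over seeded variants
nonrigid_recovery_reps <- function() get_fixture("nonrigid_reps", function() {
  ph <- phantom48()
  vol <- ph$anatomical$data
  dm <- dim(vol)
  mk <- ph$atlas$labels$data > 0
  set.seed(24)
  vapply(1:20, function(i) {
    amp <- runif(2, 0.8, 1.5) * sample(c(-1, 1), 2, replace = TRUE)
    sh <- sinusoid_field(dm, amp[1], amp[2])
    frame <- warp_by_field(vol, sh)
    est <- estimate_nonrigid_patch(frame, vol)
    truth <- invert_field(displacement_field(sh))
    sqrt(mean(c(
      (est$shifts[, , , 1][mk] - truth$shifts[, , , 1][mk])^2,
      (est$shifts[, , , 2][mk] - truth$shifts[, , , 2][mk])^2)))
  }, numeric(1))
})

# long planted-correlation BOLD run (shared by phantom + acceptance tests)
bold5000 <- function() get_fixture("bold5000", function()
  simulate_bold(phantom48()$atlas,
                data.frame(region_a = c(12L, 31L), region_b = c(22L, 41L),
                           r = c(0.6, 0)),
                n_frames = 5000L, tr_s = 1, seed = 11L))

# smooth single-period sinusoidal in-plane field, constant across slices
sinusoid_field <- function(dm, ax = 1.5, ay = 1.5) {
  xg <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2])
  yg <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2])
  sh <- array(0, c(dm, 3))
  for (z in seq_len(dm[3])) {
    sh[, , z, 1] <- ax * sin(pi * xg / dm[1]) * sin(pi * yg / dm[2])
    sh[, , z, 2] <- ay * sin(pi * yg / dm[2]) * cos(pi * xg / (2 * dm[1]))
  }
  sh
}
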