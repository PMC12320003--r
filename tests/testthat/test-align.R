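test_that("bias correction recovers a smooth gain and respects scaling", {
  ph <- phantom48z5()
  dm <- dim(ph$atlas$labels$data)
  mk <- ph$atlas$labels$data > 0
  mimg <- support_mask(ph)
  hom <- homogeneous_anat(ph)
  pts <- laminarfc:::.grid_coords(dm)
  gx <- (pts[, 1] - 24) / 24; gy <- (pts[, 2] - 24) / 24
  gain <- array(1 + 0.25 * gx + 0.2 * gy * gx - 0.15 * gy^2, dm)

  biased <- image3d(hom$data * gain, kind = "anatomical")
  bc <- bias_correct(biased, mask = mimg)
  expect_gt(cor(bc$field$data[mk], gain[mk]), 0.95)

  bc0 <- bias_correct(hom, mask = mimg)
  expect_lt(max(abs(bc0$field$data[mk] - 1)), 0.02)

  bc2 <- bias_correct(image3d(biased$data * 7.3, kind = "anatomical"),
                      mask = mimg)
  expect_equal(bc2$field$data, bc$field$data, tolerance = 1e-10)

  neg <- hom; neg$data[which(mk)[1]] <- -1
  expect_error(bias_correct(neg, mask = mimg), "nonpositive")
})

test_that("brain masking reproduces a clean support and survives speckle", {
  ps <- make_layered_phantom(c(48L, 48L, 5L), 5L, seed = 2L, psf_sigma = 0)
  m <- make_brain_mask(ps$anatomical)
  expect_identical(m$data > 0, ps$atlas$labels$data > 0)

  sp <- ps$anatomical
  set.seed(9)
  sp$data[sample(which(ps$anatomical$data == 0), 30)] <- 200
  m2 <- make_brain_mask(sp)
  comp <- laminarfc:::.largest_component_3d(m2$data > 0)
  expect_equal(sum(m2$data), sum(comp))            # single component
  expect_error(make_brain_mask(image3d(array(0, c(8, 8, 2)))), "constant")
})

test_that("linear registration recovers rigid and affine ground truth", {
  ph <- phantom48z5()
  anat <- ph$anatomical
  # self-registration is the identity
  tfs <- register_linear(anat, anat, model = "rigid")
  expect_lt(max(abs(tfs$par)), 0.05)
  expect_gte(tfs$metric_after, tfs$metric_before - 1e-9)

  A <- matrix(c(1.05, 0.02, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tv <- c(2, -1, 0)
  tf_true <- list(model = "affine", A = A, t = tv,
                  dm = dim(anat$data))
  mov <- image3d(laminarfc:::.apply_linear(anat$data, tf_true,
                                           method = "sinc", fill = "edge"),
                 kind = "anatomical")
  tf <- register_linear(anat, mov, model = "affine", metric = "corr")
  expect_lt(max(abs(tf$A - A)), 0.01)
  expect_lt(max(abs(tf$t - tv)), 0.2)
  expect_gt(tf$metric_after, tf$metric_before)
})

test_that("mutual-information metric also drives registration", {
  ph <- phantom48()
  anat <- ph$anatomical
  moved <- image3d(laminarfc:::transform_rigid_3d(anat$data,
                                                  c(1.5, -1, 0, 0, 0, 0),
                                                  method = "sinc",
                                                  fill = "edge"),
                   kind = "anatomical")
  tf <- register_linear(moved, anat, model = "rigid",
                        metric = "mutual_info")
  # the stored transform maps moved onto anat (the inverse of the applied
  # motion) with translations in mm: voxel spacing here is 0.25 mm
  expect_lt(max(abs(tf$par[1:2] - c(-1.5, 1) * 0.25)), 0.0625)
})

test_that("demons recovers a smooth deformation and names its backend", {
  ph <- phantom48z5()
  vol <- ph$anatomical$data
  dm <- dim(vol)
  mk <- ph$atlas$labels$data > 0
  f0 <- register_nonlinear(ph$anatomical, ph$anatomical)
  expect_lt(max(abs(f0$shifts)), 0.1)

  sh <- sinusoid_field(dm, 1.6, -1.4)
  warped <- image3d(warp_by_field(vol, sh), kind = "anatomical")
  fld <- register_nonlinear(warped, ph$anatomical)
  truth <- invert_field(displacement_field(sh))
  err <- sqrt(mean(c(
    (fld$shifts[, , , 1][mk] - truth$shifts[, , , 1][mk])^2,
    (fld$shifts[, , , 2][mk] - truth$shifts[, , , 2][mk])^2)))
  expect_lt(err, 0.5)
  expect_error(register_nonlinear(warped, ph$anatomical,
                                  backend = "external_syn"),
               "internal_demons")
})

test_that("atlas chains beat linear-only alignment and invert cleanly", {
  res <- get_fixture("chain_fixture", function() {
    n <- 64L
    ph <- make_layered_phantom(c(n, n, 5L), 5L, seed = 2L)
    anat <- ph$anatomical; labels <- ph$atlas$labels
    dm <- dim(labels$data)
    par_rig <- c(1.2, -0.8, 0, 0, 0, 2.5)
    epi <- image3d(laminarfc:::transform_rigid_3d(anat$data, par_rig,
                                                  c(1, 1, 1), "sinc",
                                                  fill = "edge"),
                   kind = "anatomical")
    tf1 <- register_linear(anat, epi, model = "rigid")
    sh <- sinusoid_field(dm, 1.0, -0.9)
    atlas_anat <- image3d(warp_by_field(anat$data, sh), kind = "anatomical")
    pts <- laminarfc:::.grid_coords(dm)
    p <- pts + matrix(sh, ncol = 3)
    atlas_labels <- image3d(array(laminarfc:::interp3(
      labels$data, p[, 1], p[, 2], p[, 3], "nearest"), dm), kind = "label")
    fld <- register_nonlinear(atlas_anat, anat)
    ch <- build_chain(list(
      list(transform = tf1, from_space = "EPI", to_space = "anat"),
      list(transform = fld, from_space = "anat", to_space = "atlas")))
    rmap <- laminarfc:::rigid_map(pts, par_rig, c(1, 1, 1), dm,
                                  inverse = TRUE)
    lab_true <- image3d(array(laminarfc:::interp3(
      labels$data, rmap[, 1], rmap[, 2], rmap[, 3], "nearest"), dm),
      kind = "label")
    list(ph = ph, ch = ch, tf1 = tf1, atlas_labels = atlas_labels,
         lab_true = lab_true)
  })
  coarse <- function(l) {
    o <- l$data * 0
    o[l$data %in% c(11:15, 21:25)] <- 1
    o[l$data %in% c(31, 41)] <- 2
    o[l$data == 51] <- 3
    image3d(o, kind = "label")
  }
  lab_est <- apply_chain(res$ch, res$atlas_labels)
  d_full <- dice_overlap(coarse(res$lab_true), coarse(lab_est))
  expect_true(all(d_full > 0.9))
  ch_lin <- build_chain(list(res$ch$steps[[1]]))
  d_lin <- dice_overlap(coarse(res$lab_true),
                        coarse(apply_chain(ch_lin, res$atlas_labels)))
  expect_gt(mean(d_full), mean(d_lin))

  # labels resampled through a chain stay integer (nearest-neighbour only)
  expect_true(all(lab_est$data == round(lab_est$data)))
  expect_true(all(lab_est$data %in% c(0, res$ph$atlas$regions$region_id)))

  # chain then inverse chain returns the original within boundary error
  back <- apply_chain(invert_chain(res$ch), lab_est)
  expect_gt(mean(back$data == res$atlas_labels$data), 0.85)

  # empty chain is the identity; mismatched spaces refuse to chain
  e <- apply_chain(build_chain(list()), res$ph$anatomical)
  expect_identical(e$data, res$ph$anatomical$data)
  expect_error(build_chain(list(
    list(transform = res$tf1, from_space = "EPI", to_space = "anat"),
    list(transform = res$tf1, from_space = "atlas", to_space = "x"))),
    "space mismatch")
})

test_that("rigid + field chains round trip continuous images", {
  ph <- phantom48()
  anat <- ph$anatomical
  dm <- dim(anat$data)
  tfr <- list(model = "rigid", par = c(0.8, -0.4, 0, 0, 0, 1.5),
              spacing = c(1, 1, 1), dm = dm)
  fld <- displacement_field(sinusoid_field(dm, 0.8, 0.6))
  ch <- build_chain(list(
    list(transform = tfr, from_space = "a", to_space = "b"),
    list(transform = fld, from_space = "b", to_space = "c")))
  fwd <- apply_chain(ch, anat, interp = "sinc")
  back <- apply_chain(invert_chain(ch), fwd, interp = "sinc")
  mk <- ph$atlas$labels$data > 0
  rms <- sqrt(mean((back$data[mk] - anat$data[mk])^2))
  expect_lt(rms, 0.1 * sd(anat$data[mk]))
})
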