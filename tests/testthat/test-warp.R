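test_that("field-map shift follows the echo-spacing arithmetic", {
  dm <- c(16L, 16L, 2L)
  fmap <- image3d(array(50, dm), kind = "fieldmap_hz")
  acq <- acquisition_params(matrix = c(16L, 16L),
                            eff_echo_spacing_s = 0.02 / 16)
  sh <- fieldmap_to_shift(fmap, acq, pe_axis = 1L)
  expect_equal(unique(as.vector(sh$shifts[, , , 2])), 1.0)
  expect_equal(max(abs(sh$shifts[, , , c(1, 3)])), 0)
  z <- fieldmap_to_shift(image3d(array(0, dm), kind = "fieldmap_hz"), acq)
  expect_equal(max(abs(z$shifts)), 0)
  acq$eff_echo_spacing_s <- NULL
  expect_error(fieldmap_to_shift(fmap, acq), "echo spacing")
})

test_that("composition is functional, associative, and matches brute force", {
  dm <- c(32L, 32L, 3L)
  f1 <- zero_field(dm); f1$shifts[, , , 1] <- 1
  f2 <- zero_field(dm); f2$shifts[, , , 1] <- 2
  comp <- compose_shifts(list(list(type = "field", field = f1),
                              list(type = "field", field = f2)), dm)
  expect_equal(unique(as.vector(comp$shifts[, , , 1])), 3)

  par <- c(0.7, -0.3, 0, 0, 0, 3)
  inv <- invert_linear(list(model = "rigid", par = par,
                            spacing = c(1, 1, 1), dm = dm))$par
  comp2 <- compose_shifts(list(
    list(type = "rigid", par = par, spacing = c(1, 1, 1), dm = dm,
         inverse = TRUE),
    list(type = "rigid", par = inv, spacing = c(1, 1, 1), dm = dm,
         inverse = TRUE)), dm)
  expect_lt(max(abs(comp2$shifts)), 1e-6)

  mkf <- function(seed) {
    set.seed(seed)
    sh <- array(0, c(dm, 3))
    for (k in 1:2)
      sh[, , , k] <- laminarfc:::smooth_gauss(
        array(rnorm(prod(dm)), dm), c(4, 4, 0)) * 8
    displacement_field(sh)
  }
  fa <- mkf(5); fb <- mkf(6); fc <- mkf(7)
  specs <- list(list(type = "field", field = fa),
                list(type = "field", field = fb),
                list(type = "field", field = fc))
  comp3 <- compose_shifts(specs, dm)
  pts <- laminarfc:::.grid_coords(dm)
  p <- pts
  for (s in specs) p <- laminarfc:::map_points(p, s)
  expect_lt(max(abs(matrix(comp3$shifts, ncol = 3) - (p - pts))), 1e-9)
  # associativity: composing (a b) then c equals a then (b c). Linear
  # interpolation represents affine fields exactly, so the algebraic
  # property can be checked to machine precision on affine fields
  aff_field <- function(a0, gx) {
    sh <- array(0, c(dm, 3))
    sh[, , , 1] <- a0[1] + gx[1] * (matrix(rep(seq_len(dm[1]), dm[2]),
                                           dm[1], dm[2]) - dm[1] / 2) / dm[1]
    sh[, , , 2] <- a0[2]
    displacement_field(sh)
  }
  ga <- aff_field(c(0.5, -0.3), 0.4)
  gb <- aff_field(c(-0.2, 0.6), -0.2)
  gc <- aff_field(c(0.3, 0.1), 0.1)
  gspecs <- list(list(type = "field", field = ga),
                 list(type = "field", field = gb),
                 list(type = "field", field = gc))
  full <- compose_shifts(gspecs, dm)
  ab <- compose_shifts(gspecs[1:2], dm)
  left <- compose_shifts(list(list(type = "field", field = ab),
                              gspecs[[3]]), dm)
  expect_lt(max(abs(left$shifts - full$shifts)), 1e-6)
})

test_that("one-pass resampling is exact in the degenerate cases", {
  set.seed(31)
  dm <- c(24L, 24L, 2L)
  ser <- image4d(array(rnorm(prod(dm) * 4), c(dm, 4L)))
  for (itp in c("linear", "cubic_spline", "sinc")) {
    out <- resample_once(ser, zero_field(dm), interp = itp)
    expect_identical(out$data, ser$data)
  }
  fi <- zero_field(dm); fi$shifts[, , , 2] <- 2
  outi <- resample_once(ser, fi, interp = "linear")
  expect_lt(max(abs(outi$data[, 1:22, , ] - ser$data[, 3:24, , ])), 1e-9)
  expect_error(resample_once(ser, rep(list(zero_field(dm)), 3L)),
               "per frame")
})

test_that("exactly one interpolation runs per non-trivial frame", {
  set.seed(32)
  dm <- c(16L, 16L, 2L)
  ser <- image4d(array(rnorm(prod(dm) * 5), c(dm, 5L)))
  f <- zero_field(dm); f$shifts[, , , 1] <- 0.3
  laminarfc:::interp_counter(reset = TRUE)
  invisible(resample_once(ser, f))
  expect_identical(laminarfc:::interp_counter(), 5L)
  laminarfc:::interp_counter(reset = TRUE)
  invisible(resample_once(ser, zero_field(dm)))   # identity short-circuits
  expect_identical(laminarfc:::interp_counter(), 0L)
})

test_that("warp round trips shrink with better kernels", {
  ph <- phantom48()
  ser <- image4d(array(rep(laminarfc:::smooth_gauss(ph$anatomical$data, 1),
                           2), c(48, 48, 3, 2)))
  sh <- sinusoid_field(c(48L, 48L, 3L), 1.2, 1.0)
  f <- displacement_field(sh)
  fi <- invert_field(f)
  err <- vapply(c(linear = "linear", sinc = "sinc"), function(itp) {
    fwd <- resample_once(ser, f, interp = itp)
    back <- resample_once(fwd, fi, interp = itp)
    mk <- ph$atlas$labels$data > 0
    sqrt(mean((back$data[, , , 1][mk] - ser$data[, , , 1][mk])^2))
  }, numeric(1))
  expect_lt(err["sinc"], err["linear"])
  expect_lt(err["linear"], 0.1 * sd(ser$data))
})

test_that("upsampled grids double in-plane resolution and halve spacing", {
  ph <- phantom48()
  ser <- image4d(array(ph$anatomical$data, c(48, 48, 3, 1)),
                 affine = ph$anatomical$affine)
  comp <- compose_shifts(list(), c(48L, 48L, 3L), upsample = 2L)
  up <- resample_once(ser, comp, interp = "linear")
  expect_equal(dim(up$data)[1:2], c(96L, 96L))
  expect_equal(laminarfc:::.affine_spacing(up$affine)[1],
               laminarfc:::.affine_spacing(ser$affine)[1] / 2)
  # voxel-centre alignment: block-averaging the upsampled grid returns
  # close to the original
  coarse <- 0.25 * (up$data[seq(1, 95, 2), seq(1, 95, 2), , 1] +
                    up$data[seq(2, 96, 2), seq(1, 95, 2), , 1] +
                    up$data[seq(1, 95, 2), seq(2, 96, 2), , 1] +
                    up$data[seq(2, 96, 2), seq(2, 96, 2), , 1])
  expect_gt(cor(as.vector(coarse), as.vector(ser$data[, , , 1])), 0.99)
})

test_that("field inversion reaches the stated tolerance", {
  sh <- sinusoid_field(c(48L, 48L, 3L), 1.5, 1.5)
  f <- displacement_field(sh)
  fi <- invert_field(f, tol = 0.002)
  pts <- laminarfc:::.grid_coords(c(48L, 48L, 3L))
  p <- laminarfc:::map_points(pts, list(type = "field", field = f))
  p2 <- laminarfc:::map_points(p, list(type = "field", field = fi))
  inner <- pts[, 1] > 4 & pts[, 1] < 44 & pts[, 2] > 4 & pts[, 2] < 44
  expect_lt(max(abs(p2[inner, ] - pts[inner, ])), 0.05)
})

test_that("FWHM estimation matches known smoothing kernels", {
  set.seed(33)
  wn <- image3d(array(rnorm(64 * 64 * 8), c(64, 64, 8)))
  expect_lt(max(estimate_fwhm(wn)$per_axis[1:2]), 0.5)

  ests <- replicate(50, {
    x <- laminarfc:::smooth_gauss(array(rnorm(64 * 64 * 4), c(64, 64, 4)),
                                  c(2 / 2.355, 2 / 2.355, 0))
    estimate_fwhm(image3d(x))$per_axis[1]
  })
  expect_equal(mean(ests), 2.0, tolerance = 0.1)
  expect_lt(sd(ests), 0.2)

  widths <- vapply(1:4, function(w) {
    x <- laminarfc:::smooth_gauss(array(rnorm(64 * 64 * 4), c(64, 64, 4)),
                                  c(w / 2.355, w / 2.355, 0))
    estimate_fwhm(image3d(x))$per_axis[1]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(estimate_fwhm(image3d(array(1, c(8, 8, 2)))), "constant")
})

test_that("one-pass resampling blurs less than sequential passes", {
  set.seed(34)
  dm <- c(48L, 48L, 3L)
  base <- laminarfc:::smooth_gauss(array(rnorm(prod(dm)), dm),
                                   c(0.8, 0.8, 0))
  ser <- image4d(array(base, c(dm, 1L)))
  mk_shift <- function(ax, amt) {
    f <- zero_field(dm); f$shifts[, , , ax] <- amt; f
  }
  srcs <- list(mk_shift(1L, 0.4), mk_shift(2L, -0.6), mk_shift(1L, 0.3))
  seq_out <- ser
  for (f in srcs) seq_out <- resample_once(seq_out, f, interp = "cubic_spline")
  comp <- compose_shifts(lapply(srcs, function(f)
    list(type = "field", field = f)), dm)
  once_out <- resample_once(ser, comp, interp = "cubic_spline")
  fw_seq <- estimate_fwhm(image3d(seq_out$data[, , , 1]))$per_axis[1:2]
  fw_once <- estimate_fwhm(image3d(once_out$data[, , , 1]))$per_axis[1:2]
  expect_lt(mean(fw_once), mean(fw_seq))
})
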