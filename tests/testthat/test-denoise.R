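test_that("Casorati construction maps patch voxels in raster order", {
  set.seed(5)
  ser <- image4d(array(rnorm(6 * 5 * 2 * 20), c(6, 5, 2, 20)))
  cm <- build_casorati(ser, c(2L, 3L, 2L), c(3L, 3L))
  expect_equal(dim(cm$values), c(9L, 20L))
  # brute-force index-mapping oracle: row k = (dx + 3*dy) raster order
  for (k in 0:8) for (t in c(1L, 7L, 20L)) {
    dx <- k %% 3L; dy <- k %/% 3L
    expect_identical(cm$values[k + 1L, t],
                     ser$data[2L + dx, 3L + dy, 2L, t])
  }
  # 1x1 window is the voxel's series as a row
  c1 <- build_casorati(ser, c(4L, 4L, 1L), c(1L, 1L))
  expect_equal(as.vector(c1$values), ser$data[4, 4, 1, ])
  expect_error(build_casorati(ser, c(5L, 4L, 1L), c(3L, 3L)), "bounds")
})

test_that("noise edge splits spectra correctly in closed cases", {
  # zero matrix: zero spectrum
  sp0 <- suppressWarnings(estimate_noise_edge(as_casorati(matrix(0, 9, 100))))
  expect_identical(sp0$n_signal, 0L)
  expect_identical(sp0$sigma_hat, 0)
  # spiked matrix at 10x the edge is always found
  set.seed(8)
  hits <- 0L
  for (i in 1:25) {
    m <- matrix(rnorm(9 * 310), 9, 310)
    base <- estimate_noise_edge(as_casorati(m))
    u <- rnorm(9); v <- rnorm(310)
    m2 <- m + 10 * base$noise_edge * (u / sqrt(sum(u^2))) %*%
      t(v / sqrt(sum(v^2)))
    sp <- estimate_noise_edge(as_casorati(m2), method = "tw_quantile")
    hits <- hits + (sp$n_signal >= 1L)
    # retained values are exactly those above the edge
    expect_identical(sp$n_signal,
                     sum(sp$singular_values > sp$noise_edge))
  }
  expect_identical(hits, 25L)
  # sigma is estimated accurately despite the spike
  expect_equal(sp0$P, 9L)
})

test_that("sigma-hat is close to truth on pure noise", {
  set.seed(9)
  errs <- replicate(40, {
    sp <- estimate_noise_edge(as_casorati(matrix(rnorm(9 * 310, sd = 2.5),
                                                 9, 310)))
    sp$sigma_hat
  })
  expect_equal(mean(errs), 2.5, tolerance = 0.02)
})

test_that("T <= P triggers the reliability warning", {
  set.seed(2)
  expect_warning(estimate_noise_edge(as_casorati(matrix(rnorm(81), 9, 9))),
                 "unreliable")
})

test_that("signal cleaning preserves noiseless input and flattens pure mean", {
  set.seed(10)
  A <- outer(rnorm(9), sin((1:200) / 9)) + outer(rnorm(9), cos((1:200) / 5))
  sp <- suppressWarnings(estimate_noise_edge(as_casorati(A)))
  cl <- clean_signal_components(as_casorati(A), sp)
  expect_lt(sqrt(mean((cl$values - A)^2)) / sd(A), 1e-3)

  # n_signal = 0: output is the row-mean (temporal-mean) matrix
  m <- matrix(rnorm(9 * 310), 9, 310)
  sp2 <- estimate_noise_edge(as_casorati(m))
  if (sp2$n_signal == 0L) {
    cl2 <- clean_signal_components(as_casorati(m), sp2)
    expect_equal(cl2$values, matrix(rowMeans(m), 9, 310),
                 tolerance = 1e-12)
  }
  expect_error(clean_signal_components(as_casorati(matrix(0, 4, 10)), sp2),
               "inconsistent")
})

test_that("spiked-model shrinkage beats hard truncation on planted signal", {
  set.seed(11)
  P <- 9L; T <- 120L
  mse_shrunk <- mse_trunc <- numeric(100)
  for (i in 1:100) {
    U <- qr.Q(qr(matrix(rnorm(P * 3), P, 3)))
    V <- qr.Q(qr(matrix(rnorm(T * 3), T, 3)))
    signal <- U %*% diag(c(30, 22, 16)) %*% t(V)
    noisy <- signal + matrix(rnorm(P * T), P, T)
    sp <- estimate_noise_edge(as_casorati(noisy))
    cl <- clean_signal_components(as_casorati(noisy), sp)
    mse_shrunk[i] <- mean((cl$values - signal)^2)
    # hard truncation: same split, no debiasing
    k <- sp$n_signal
    mu <- sp$row_means
    Ac <- noisy - mu
    if (k > 0) {
      Uk <- sp$U[, seq_len(k), drop = FALSE]
      hard <- Uk %*% crossprod(Uk, Ac) + mu
    } else hard <- matrix(mu, P, T)
    mse_trunc[i] <- mean((hard - signal)^2)
  }
  expect_lt(mean(mse_shrunk), mean(mse_trunc))
})

test_that("denoised + residual reconstructs the input exactly", {
  tr <- make_phantom_truth(shape = c(40L, 40L, 2L), n_frames = 60L,
                           seed = 3L, motion_scale = 0, fieldmap_hz = 0)
  acq <- apply_acquisition(tr$clean_series, tr, seed = 4L)
  dn <- denoise_series(acq, window = c(3L, 3L), stride = 2L)
  # the residual is the exact float difference, so this is bit-for-bit
  expect_identical(acq$data - dn$denoised$data, dn$noise_residual$data)
  # the rearranged sum agrees to within rounding of the larger summand
  expect_lt(max(abs(dn$denoised$data + dn$noise_residual$data - acq$data)),
            1e-10)
})

test_that("denoising is equivariant to global intensity scaling", {
  tr <- make_phantom_truth(shape = c(40L, 40L, 1L), n_frames = 50L,
                           seed = 5L, motion_scale = 0, fieldmap_hz = 0)
  acq <- apply_acquisition(tr$clean_series, tr, seed = 6L)
  dn1 <- denoise_series(acq, stride = 3L)
  scaled <- image4d(acq$data * 3.7, affine = acq$affine, tr_s = acq$tr_s)
  dn2 <- denoise_series(scaled, stride = 3L)
  expect_equal(dn2$denoised$data, 3.7 * dn1$denoised$data,
               tolerance = 1e-10)
})

test_that("denoising raises masked tSNR and leaves Gaussian residuals", {
  tr <- make_phantom_truth(shape = c(40L, 40L, 2L), n_frames = 120L,
                           seed = 7L, noise_sigma = 6, motion_scale = 0,
                           fieldmap_hz = 0)
  acq <- apply_acquisition(tr$clean_series, tr, seed = 8L)
  dn <- denoise_series(acq)
  mk <- image3d(array(as.numeric(tr$atlas$labels$data > 0), c(40, 40, 2)),
                kind = "mask")
  gain <- mean(tsnr_map(dn$denoised, mk)$data, na.rm = TRUE) /
    mean(tsnr_map(acq, mk)$data, na.rm = TRUE)
  expect_gt(gain, 1.5)
  ad <- residual_gaussianity(dn$noise_residual, mk)
  expect_gt(ad$p_value, 0.01)
  # zero-noise input (deterministic region signal, no voxel jitter)
  # passes through almost unchanged
  bold0 <- simulate_bold(tr$atlas, tr$network_corr, n_frames = 60L,
                         seed = 31L, jitter_sd = 0)
  clean0 <- bold0
  clean0$data <- bold0$data + 100
  dn0 <- denoise_series(clean0, stride = 2L)
  relerr <- sqrt(mean((dn0$denoised$data - clean0$data)^2)) /
    sd(clean0$data)
  expect_lt(relerr, 1e-3)
})

test_that("pure-noise variance is almost fully removed", {
  set.seed(12)
  noise <- image4d(array(rnorm(30 * 30 * 1 * 120, sd = 4),
                         c(30, 30, 1, 120)))
  dn <- denoise_series(noise, stride = 2L)
  flat <- matrix(dn$denoised$data, ncol = 120)
  vr <- mean(apply(flat, 1, var)) / 16
  expect_lt(vr, 0.1)
})

test_that("stride too large for the mask is an error", {
  set.seed(13)
  ser <- image4d(array(rnorm(20 * 20 * 1 * 30), c(20, 20, 1, 30)))
  mk <- array(0, c(20, 20, 1)); mk[10, 10, 1] <- 1
  expect_error(denoise_series(ser, window = c(3L, 3L), stride = 30L,
                              mask = image3d(mk, kind = "mask")),
               "stride")
  expect_error(denoise_series(ser, window = c(4L, 3L)), "odd")
})

test_that("residual_gaussianity is calibrated and detects heavy tails", {
  set.seed(14)
  pvals <- replicate(120, {
    r <- image4d(array(rnorm(2000), c(10, 10, 2, 10)))
    residual_gaussianity(r)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(replicate(60, {
    r <- image4d(array(stats::rt(2000, df = 3), c(10, 10, 2, 10)))
    residual_gaussianity(r)$p_value < 0.05
  }))
  expect_gt(rej, 0.9)
  expect_error(residual_gaussianity(image4d(array(1, c(10, 10, 2, 10)))),
               "variance")
  expect_error(residual_gaussianity(image4d(array(rnorm(8), c(2, 2, 1, 2)))),
               "1000")
})
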