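# small deterministic atlas for closed-form cases: 4 regions of sizes
# 1 / 2 / 4 / 8 voxels under two parents
toy_atlas <- function() {
  lab <- array(0, c(6, 6, 1))
  lab[1, 1, 1] <- 11
  lab[2, 1:2, 1] <- 12
  lab[3:4, 1:2, 1] <- 21
  lab[5:6, 1:4, 1] <- 22
  regions <- data.frame(
    region_id = c(1L, 2L, 11L, 12L, 21L, 22L),
    acronym = c("A", "B", "A1", "A2", "B1", "B2"),
    parent_id = c(NA, NA, 1L, 1L, 2L, 2L))
  atlas_hierarchy(image3d(lab, kind = "label"), regions)
}

test_that("seed time courses are plain voxel means", {
  at <- toy_atlas()
  set.seed(51)
  arr <- array(rnorm(6 * 6 * 1 * 40), c(6, 6, 1, 40))
  ser <- image4d(arr)
  expect_equal(seed_timecourse(ser, at, 11L), arr[1, 1, 1, ])
  expect_equal(seed_timecourse(ser, at, 12L),
               (arr[2, 1, 1, ] + arr[2, 2, 1, ]) / 2)
  # parent = voxel mean over all descendants, not mean of child means
  vox <- resolve_region(at, 1L)
  expect_equal(seed_timecourse(ser, at, 1L),
               colMeans(matrix(arr, ncol = 40)[vox, ]))
  expect_error(seed_timecourse(ser, at, 11L,
                               mask = image3d(array(0, c(6, 6, 1)),
                                              kind = "mask")),
               "no voxels")
})

test_that("seed maps Fisher-transform and cap correctly", {
  at <- toy_atlas()
  set.seed(52)
  arr <- array(rnorm(6 * 6 * 1 * 60), c(6, 6, 1, 60))
  arr[6, 6, 1, ] <- 0                      # zero-variance voxel
  ser <- image4d(arr)
  sm <- seed_map(ser, at, 11L)             # single-voxel seed
  expect_equal(sm$zmap$data[1, 1, 1], atanh(1 - 1e-7))  # cap at the seed
  expect_true(is.na(sm$zmap$data[6, 6, 1]))
  # z equals atanh(r) against a direct cor() computation
  r_direct <- cor(arr[3, 2, 1, ], arr[1, 1, 1, ])
  expect_equal(sm$zmap$data[3, 2, 1], atanh(r_direct), tolerance = 1e-12)
  expect_equal(atanh(0.2), 0.202732554054, tolerance = 1e-9)
  expect_error(seed_map(image4d(arr[, , , 1:5, drop = FALSE]), at, 11L),
               "10 frames")
})

test_that("correlations are invariant to affine intensity rescaling", {
  at <- toy_atlas()
  set.seed(53)
  arr <- array(rnorm(6 * 6 * 1 * 50, mean = 10), c(6, 6, 1, 50))
  ser <- image4d(arr)
  sm1 <- seed_map(ser, at, 21L)
  ser2 <- image4d(arr * 4.2 + 11)
  sm2 <- seed_map(ser2, at, 21L)
  expect_equal(sm1$zmap$data, sm2$zmap$data, tolerance = 1e-9)
})

test_that("hierarchical matrices agree with seed primitives bit-for-bit", {
  ph <- phantom48()
  nc <- data.frame(region_a = 12L, region_b = 22L, r = 0.6)
  bold <- get_fixture("bold_hier", function()
    simulate_bold(phantom48()$atlas, data.frame(region_a = 12L,
                                                region_b = 22L, r = 0.6),
                  n_frames = 400L, seed = 13L))
  hm <- hierarchical_matrix(bold, ph$atlas, 2L)
  # time courses are bit-identical to the seed primitive; correlations
  # agree to rounding (joint vs pairwise summation order)
  tcs <- vapply(hm$region_ids, function(id)
    seed_timecourse(bold, ph$atlas, id), numeric(400))
  r <- stats::cor(tcs)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  zz <- atanh(r); diag(zz) <- NA_real_
  dimnames(zz) <- dimnames(hm$z)
  expect_identical(hm$z, zz)
  for (i in c(1L, 4L)) {
    tci <- seed_timecourse(bold, ph$atlas, hm$region_ids[i])
    expect_identical(tci, tcs[, i])
    for (j in c(2L, 7L))
      expect_equal(hm$z[i, j],
                   atanh(cor(tci, tcs[, j])), tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(hm$z))))
  expect_equal(hm$z, t(hm$z))
  expect_error(hierarchical_matrix(bold, ph$atlas, 9L), "fewer than 2")

  # within-network exceeds between-network on planted block structure
  expect_gt(hm$z["12", "22"],
            max(abs(hm$z["11", "41"]), abs(hm$z["15", "31"])))
})

test_that("connectogram edges equal a brute-force triangle scan", {
  z <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  z[1, 2] <- z[2, 1] <- 0.35
  diag(z) <- NA
  ed <- connectogram_edges(z, 0.2)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$z, 0.35)
  expect_equal(nrow(connectogram_edges(matrix(0, 4, 4), 0.2)), 0L)

  set.seed(54)
  zz <- matrix(rnorm(100, sd = 0.3), 10, 10)
  zz <- (zz + t(zz)) / 2; diag(zz) <- NA
  ed2 <- connectogram_edges(zz, 0.2)
  expect_equal(nrow(ed2), sum(zz[upper.tri(zz)] > 0.2))
  expect_true(all(diff(abs(ed2$z)) <= 0))
})

test_that("seed-size scaling matches closed-form OLS and recomputation", {
  at <- toy_atlas()
  set.seed(55)
  # common latent signal so every region lights up the others
  n <- 120L
  sig <- as.vector(scale(cumsum(rnorm(n))))
  arr <- array(rnorm(6 * 6 * 1 * n, sd = 0.4), c(6, 6, 1, n))
  for (v in which(array(TRUE, c(6, 6, 1))))
    arr[, , 1, ] <- arr[, , 1, ]           # no-op, keep shapes clear
  for (i in 1:6) for (j in 1:6)
    arr[i, j, 1, ] <- arr[i, j, 1, ] + sig
  ser <- image4d(arr)
  ss <- seed_size_scaling(ser, at, c(11L, 12L, 21L, 22L), threshold = 0.2)
  tab <- ss$table
  expect_equal(tab$n_seed_voxels, c(1L, 2L, 4L, 8L))
  # closed-form OLS on the produced table
  fit <- lm(log(mean_suprathreshold_z) ~ log(n_seed_voxels),
            data = tab[!tab$missing, ])
  expect_equal(ss$slope_strength, unname(coef(fit)[2]), tolerance = 1e-12)
  fit2 <- lm(log(n_suprathreshold) ~ log(n_seed_voxels),
             data = tab[!tab$missing, ])
  expect_equal(ss$slope_count, unname(coef(fit2)[2]), tolerance = 1e-12)
  # brute-force recomputation of one row
  sm <- seed_map(ser, at, 21L, threshold = 0.2)
  zz <- as.vector(sm$zmap$data)
  zz[sm$seed_voxels] <- NA
  expect_equal(tab$n_suprathreshold[tab$region_id == 21L],
               sum(zz > 0.2, na.rm = TRUE))
  # the seed-inclusion flag changes the accounting
  ss2 <- seed_size_scaling(ser, at, c(11L, 12L, 21L, 22L),
                           include_seed = TRUE)
  expect_true(all(ss2$table$n_suprathreshold >= tab$n_suprathreshold))
  expect_error(seed_size_scaling(ser, at, 11L), "at least 2")
})

test_that("group averaging works in the Fisher domain", {
  at <- toy_atlas()
  set.seed(56)
  mk_map <- function(seed) {
    set.seed(seed)
    ser <- image4d(array(rnorm(6 * 6 * 1 * 60), c(6, 6, 1, 60)))
    seed_map(ser, at, 21L)
  }
  m1 <- mk_map(1)
  same <- group_average(list(m1, m1, m1))
  expect_equal(same$zmap$data, m1$zmap$data)
  neg <- m1
  neg$zmap$data <- -m1$zmap$data
  zero <- group_average(list(m1, neg))
  expect_lt(max(abs(zero$zmap$data), na.rm = TRUE), 1e-12)
  badgrid <- m1
  badgrid$zmap <- image3d(array(0, c(5, 5, 1)))
  expect_error(group_average(list(m1, badgrid)), "grid")
})

test_that("group mean z converges to the planted correlation", {
  ph <- phantom48()
  nc <- data.frame(region_a = 12L, region_b = 22L, r = 0.4)
  zs <- vapply(1:20, function(s) {
    bold <- simulate_bold(ph$atlas, nc, n_frames = 600L, seed = 100L + s,
                          jitter_sd = 0)
    atanh(cor(seed_timecourse(bold, ph$atlas, 12L),
              seed_timecourse(bold, ph$atlas, 22L)))
  }, numeric(1))
  n_eff <- 2 * 0.09 * 600
  se <- 1 / sqrt(n_eff - 3) / sqrt(20)
  expect_lt(abs(mean(zs) - atanh(0.4)), 3 * se + 0.02)
})

test_that("connectivity matrices serialise with a region-id header", {
  ph <- phantom48()
  bold <- get_fixture("bold_hier", function()
    simulate_bold(phantom48()$atlas, data.frame(region_a = 12L,
                                                region_b = 22L, r = 0.6),
                  n_frames = 400L, seed = 13L))
  hm <- hierarchical_matrix(bold, ph$atlas, 0L)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "mat.csv")
  write_connectivity_csv(hm, p)
  back <- read.csv(p, check.names = FALSE)
  expect_equal(as.character(back$region_id), rownames(hm$z))
})
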