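# Internal resampling and Fourier helpers shared by warp, motion and align.
# All samplers are pullback-style: given sample positions in 1-based array
# index coordinates, they gather interpolated values from the source array.

# clamp positions to the valid support and remember which were outside
# a point within 1e-3 voxel of the support still counts as inside:
# composed mappings carry floating-point noise, and zero-filling a sample
# that is epsilon outside would put a hard discontinuity on the boundary
.interp_prepare <- function(n, p) {
  inside <- p >= 1 - 1e-3 & p <= n + 1e-3
  list(inside = inside, p = pmin(pmax(p, 1), n))
}

# Keys cubic convolution kernel, a = -0.5 (interpolating, C1)
.keys <- function(s) {
  s <- abs(s)
  a <- -0.5
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * (s[i2]^3 - 5 * s[i2]^2 + 8 * s[i2] - 4)
  w
}

# Lanczos-3 windowed sinc
.lanczos <- function(s, a = 3) {
  w <- numeric(length(s))
  nz <- abs(s) < a
  x <- s[nz]
  w[nz] <- ifelse(x == 0, 1,
                  a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2))
  w
}

# Sample a 3D array at arbitrary positions (1-based index coords).
# method: "linear" (trilinear), "cubic_spline" (separable Keys cubic),
# "sinc" (separable Lanczos-3), "nearest".
# Out-of-support positions return `fill`; fill = "edge" clamps to the
# boundary value (cliff-free, for registration cost functions).
interp3 <- function(vol, xi, yi, zi, method = "linear", fill = 0) {
  dm <- dim(vol)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  px <- .interp_prepare(nx, xi); py <- .interp_prepare(ny, yi)
  pz <- .interp_prepare(nz, zi)
  inside <- px$inside & py$inside & pz$inside
  x <- px$p; y <- py$p; z <- pz$p
  out <- numeric(length(x))
  if (method == "nearest") {
    ix <- pmin(pmax(round(x), 1), nx)
    iy <- pmin(pmax(round(y), 1), ny)
    iz <- pmin(pmax(round(z), 1), nz)
    out <- vol[cbind(ix, iy, iz)]
  } else if (method == "linear") {
    x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
    z0 <- if (nz > 1) pmin(floor(z), nz - 1) else rep(1, length(z))
    fx <- x - x0; fy <- y - y0; fz <- if (nz > 1) z - z0 else rep(0, length(z))
    z1 <- pmin(z0 + 1, nz)
    gather <- function(ix, iy, iz) vol[cbind(ix, iy, iz)]
    out <- (1 - fz) * ((1 - fy) * ((1 - fx) * gather(x0, y0, z0) +
                                   fx * gather(x0 + 1, y0, z0)) +
                       fy * ((1 - fx) * gather(x0, y0 + 1, z0) +
                             fx * gather(x0 + 1, y0 + 1, z0))) +
           fz * ((1 - fy) * ((1 - fx) * gather(x0, y0, z1) +
                             fx * gather(x0 + 1, y0, z1)) +
                 fy * ((1 - fx) * gather(x0, y0 + 1, z1) +
                       fx * gather(x0 + 1, y0 + 1, z1)))
  } else {
    taps <- switch(method, cubic_spline = 2L, sinc = 3L,
                   stop("unknown interpolation method: ", method))
    kern <- switch(method, cubic_spline = .keys, sinc = .lanczos)
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    acc <- numeric(length(x))
    wsum <- numeric(length(x))
    offs <- seq.int(-taps + 1L, taps)
    zoffs <- if (nz >= 2L) offs else 0L
    for (dz in zoffs) {
      iz <- pmin(pmax(z0 + dz, 1), nz)
      wz <- if (nz >= 2L) kern(z - (z0 + dz)) else rep(1, length(z))
      if (all(wz == 0)) next
      for (dy in offs) {
        iy <- pmin(pmax(y0 + dy, 1), ny)
        wy <- kern(y - (y0 + dy))
        wzy <- wz * wy
        if (all(wzy == 0)) next
        for (dx in offs) {
          ix <- pmin(pmax(x0 + dx, 1), nx)
          wx <- kern(x - (x0 + dx))
          w <- wzy * wx
          acc <- acc + w * vol[cbind(ix, iy, iz)]
          wsum <- wsum + w
        }
      }
    }
    out <- acc / ifelse(wsum == 0, 1, wsum)
  }
  if (!identical(fill, "edge")) out[!inside] <- fill
  out
}

# grid of all voxel index coordinates of a (nx,ny,nz) array, as a 3-col matrix
.grid_coords <- function(dm) {
  cbind(
    rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]), each = dm[1] * dm[2]))
}

# separable Gaussian smoothing with reflected boundaries; sigma in voxels,
# sigma of 0 along an axis skips that axis
smooth_gauss <- function(arr, sigma) {
  dm <- dim(arr)
  nd <- length(dm)
  if (length(sigma) == 1L) sigma <- rep(sigma, nd)
  conv_axis <- function(a, axis, sg) {
    if (sg <= 0) return(a)
    r <- max(1L, ceiling(3 * sg))
    k <- exp(-((-r:r)^2) / (2 * sg^2)); k <- k / sum(k)
    n <- dim(a)[axis]
    # reflect-pad along axis then filter via matrix multiplication
    idx <- c(pmin(r:1 + 1L, n), seq_len(n), pmax(n - (1:r), 1L))
    perm <- c(axis, setdiff(seq_len(nd), axis))
    ap <- aperm(a, perm)
    dmp <- dim(ap)
    m <- matrix(ap, nrow = dmp[1])
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    ap <- array(out, dmp)
    aperm(ap, order(perm))
  }
  for (ax in seq_len(nd)) arr <- conv_axis(arr, ax, sigma[ax])
  arr
}

# ---- phase correlation --------------------------------------------------

# raised-cosine (Hann) taper window for a 2D patch
.hann2 <- function(nx, ny) {
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
  outer(wx, wy)
}

# Local upsampled cross-correlation by matrix-multiply DFT around a shift
# estimate (Guizar-Sicairos style). Q is the cross-power spectrum.
# `radius` may be per-axis; a zero radius pins that axis at shift0.
.upsampled_xcorr <- function(Q, shift0, usf = 100, radius = c(1.5, 1.5)) {
  dm <- dim(Q)
  radius <- rep_len(radius, 2L)
  nr <- ceiling(radius * usf) * 2 + 1
  off <- (nr - 1) / 2
  kern1 <- function(n, cent, nri, offi) {
    fr <- ((seq_len(n) - 1) + floor(n / 2)) %% n - floor(n / 2)
    samples <- (seq_len(nri) - 1 - offi) / usf + cent
    exp(2i * pi * outer(samples, fr) / n)
  }
  k1 <- kern1(dm[1], shift0[1], nr[1], off[1])
  k2 <- kern1(dm[2], shift0[2], nr[2], off[2])
  cc <- k1 %*% Q %*% t(k2)
  pk <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
  shift <- shift0 + (pk - 1 - off) / usf
  list(shift = shift, peak = max(abs(cc)) / (dm[1] * dm[2]))
}

# Sub-voxel 2D phase correlation between two equally-sized images.
# Returns the shift s (in voxels, per axis) such that b is a displaced by s:
# b(x) ~= a(x - s). `constrain_axis` (1 or 2) restricts the search to that
# axis (shift on the other axis fixed at 0).
phase_corr_2d <- function(a, b, usf = 100, taper = TRUE,
                          constrain_axis = NULL) {
  dm <- dim(a)
  if (!all(dm == dim(b))) stop("images must have equal shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant image: phase correlation undefined")
  if (taper) {
    w <- .hann2(dm[1], dm[2])
    a <- (a - mean(a)) * w
    b <- (b - mean(b)) * w
  }
  A <- stats::fft(a); B <- stats::fft(b)
  Q <- B * Conj(A)
  Qn <- Q / pmax(Mod(Q), 1e-12)
  cc <- Re(stats::fft(Qn, inverse = TRUE)) / prod(dm)
  if (!is.null(constrain_axis)) {
    # zero-out shifts off the allowed axis
    keep <- array(FALSE, dm)
    if (constrain_axis == 1L) keep[, 1] <- TRUE else keep[1, ] <- TRUE
    cc[!keep] <- -Inf
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # map to signed integer shift
  s0 <- pk - 1
  s0 <- ifelse(s0 > dm / 2, s0 - dm, s0)
  radius <- c(1.5, 1.5)
  if (!is.null(constrain_axis)) {
    other <- setdiff(1:2, constrain_axis)
    s0[other] <- 0
    radius[other] <- 0
  }
  ref <- .upsampled_xcorr(Qn, s0, usf = usf, radius = radius)
  s <- ref$shift
  # normalized confidence: phase-correlation peak height in [0, 1]
  conf <- min(1, max(cc[is.finite(cc)]))
  list(shift = s, confidence = conf)
}
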