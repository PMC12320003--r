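# Nuisance regression (motion parameters + slow drift) and zero-phase
# temporal band-pass filtering. Regression runs before filtering, with the
# motion regressors themselves band-pass matched, the standard remedy for
# the regression/filtering frequency-mismatch interaction.

#' Build a nuisance design matrix
#'
#' Combines the six rigid motion parameters, their per-slice PE-shift mean,
#' a drift basis (polynomial or cosine/DCT set), and a constant column.
#' Non-constant columns are standardized; all-zero columns (e.g. motion
#' parameters of a motion-free run) are dropped with a warning. The
#' number of cosines for a cutoff `f_c` over duration `D` seconds is
#' `floor(2 * D * f_c)`.
#'
#' @param motion `RigidMotion` or NULL (drift-only design).
#' @param n_frames number of frames.
#' @param tr_s repetition time (s).
#' @param drift_spec list: `type` `"cosine"` (default) or `"poly"`;
#'   `cutoff_hz` (cosine cutoff, default 0.01) or `order` (polynomial
#'   order, default 2).
#' @return An object of class `NuisanceDesign`: `regressors`
#'   (frames x k matrix), `names`.
#' @export
build_design <- function(motion, n_frames, tr_s = 1,
                         drift_spec = list(type = "cosine",
                                           cutoff_hz = 0.01)) {
  cols <- list()
  if (!is.null(motion)) {
    pf <- as.matrix(motion$per_frame[c("tx", "ty", "tz", "rx", "ry", "rz")])
    if (nrow(pf) != n_frames)
      stop("motion length ", nrow(pf), " != n_frames ", n_frames)
    for (j in seq_len(ncol(pf)))
      cols[[colnames(pf)[j]]] <- pf[, j]
    if (!is.null(motion$per_slice_pe_shift) &&
        any(motion$per_slice_pe_shift != 0))
      cols[["pe_shift_mean"]] <- rowMeans(motion$per_slice_pe_shift)
  }
  type <- drift_spec$type %||% "cosine"
  if (type == "cosine") {
    cutoff <- drift_spec$cutoff_hz %||% 0.01
    dur <- n_frames * tr_s
    K <- floor(2 * dur * cutoff)
    tt <- seq_len(n_frames) - 0.5
    for (k in seq_len(K))
      cols[[paste0("cos", k)]] <- cos(pi * k * tt / n_frames)
  } else if (type == "poly") {
    ord <- drift_spec$order %||% 2
    tt <- seq_len(n_frames)
    if (ord >= 1) {
      pb <- stats::poly(tt, degree = ord)
      for (k in seq_len(ord)) cols[[paste0("poly", k)]] <- pb[, k]
    }
  } else stop("unknown drift type: ", type)
  zero <- vapply(cols, function(v) stats::sd(v) == 0, logical(1))
  if (any(zero)) {
    warning("dropping constant regressors: ",
            paste(names(cols)[zero], collapse = ", "))
    cols <- cols[!zero]
  }
  X <- cbind(constant = rep(1, n_frames),
             vapply(cols, function(v) (v - mean(v)) / stats::sd(v),
                    numeric(n_frames)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (1L %in% setdiff(seq_len(ncol(X)), keep))
      stop("design rank-deficient and constant column not retainable")
    stop("design rank-deficient after pruning; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(regressors = X, names = colnames(X)),
            class = "NuisanceDesign")
}

#' Regress nuisance signals out of a series
#'
#' Per-voxel ordinary least squares projection onto the design's column
#' space is removed; the voxel temporal mean is restored. Residuals are
#' orthogonal to every regressor.
#'
#' @param series `Image4D`.
#' @param design `NuisanceDesign`.
#' @param mask optional `Image3D`; voxels outside are passed through.
#' @return `Image4D` of residuals (+ restored means).
#' @export
regress_nuisance <- function(series, design, mask = NULL) {
  stopifnot(inherits(series, "Image4D"), inherits(design, "NuisanceDesign"))
  X <- design$regressors
  dm <- dim(series$data)
  nt <- dm[4]
  if (nrow(X) != nt)
    stop("design rows ", nrow(X), " != frames ", nt)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  flat <- t(matrix(series$data, ncol = nt))      # time x voxels
  mk <- if (is.null(mask)) rep(TRUE, prod(dm[1:3])) else as.vector(mask$data > 0)
  res <- flat
  res[, mk] <- stats::residuals(stats::lm.fit(X, flat[, mk, drop = FALSE]))
  res[, mk] <- sweep(res[, mk, drop = FALSE], 2,
                     colMeans(flat[, mk, drop = FALSE]), "+")
  out <- array(t(res), dm)
  image4d(out, affine = series$affine, tr_s = series$tr_s,
          pe_axis = series$pe_axis)
}

# two-sided Butterworth magnitude-squared gain on the DFT frequency grid
.butter_gain <- function(n, tr_s, band_hz, order) {
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)               # fold to magnitude
  g <- rep(1, n)
  if (band_hz[2] > 0) g <- g / (1 + (f / band_hz[2])^(2 * order))
  if (band_hz[1] > 0) {
    hp <- ifelse(f > 0, 1 / (1 + (band_hz[1] / f)^(2 * order)), 0)
    g <- g * hp
  }
  g
}

# zero-phase frequency-domain filtering of matrix columns (time on rows)
.fft_filter_cols <- function(x, tr_s, band_hz, order) {
  g <- .butter_gain(nrow(x), tr_s, band_hz, order)
  X <- stats::mvfft(x)
  Re(stats::mvfft(X * g, inverse = TRUE)) / nrow(x)
}

#' Zero-phase temporal band-pass filter
#'
#' The squared-magnitude response of an order-`order` Butterworth filter
#' (the response a forward-backward IIR pass would have) is applied in the
#' frequency domain, giving exactly zero phase and no start-up transients.
#' The monotone Butterworth response has no pass-band ripple; stop-band
#' attenuation at frequency f is `1/(1 + (f/hi)^(2*order))` per side.
#' `lo = 0` gives a pure low-pass (the temporal mean passes unchanged);
#' `lo > 0` removes the mean exactly. Frame count is unchanged.
#'
#' @param series `Image4D`.
#' @param band_hz numeric (lo, hi) in Hz; `hi` must be below Nyquist.
#' @param order Butterworth order (default 4; the effective roll-off is
#'   `2*order` poles).
#' @param mask optional `Image3D`; voxels outside pass through unchanged.
#' @return filtered `Image4D`.
#' @export
bandpass <- function(series, band_hz = c(0.01, 0.1), order = 4L,
                     mask = NULL) {
  stopifnot(inherits(series, "Image4D"))
  lo <- band_hz[1]; hi <- band_hz[2]
  nyq <- 1 / (2 * series$tr_s)
  if (lo < 0 || hi <= lo || hi >= nyq)
    stop("invalid band: need 0 <= lo < hi < Nyquist (", nyq, " Hz)")
  dm <- dim(series$data)
  nt <- dm[4]
  flat <- matrix(series$data, ncol = nt)
  mk <- if (is.null(mask)) rep(TRUE, nrow(flat)) else as.vector(mask$data > 0)
  flat[mk, ] <- t(.fft_filter_cols(t(flat[mk, , drop = FALSE]),
                                   series$tr_s, band_hz, order))
  image4d(array(flat, dm), affine = series$affine, tr_s = series$tr_s,
          pe_axis = series$pe_axis)
}

#' Band-pass filter the columns of a nuisance design
#'
#' Matches the motion regressors' frequency content to the data band so
#' regression does not reintroduce filtered-out frequencies. The constant
#' column is left untouched.
#'
#' @param design `NuisanceDesign`.
#' @param band_hz (lo, hi) Hz.
#' @param tr_s repetition time (s).
#' @param order Butterworth order.
#' @return filtered `NuisanceDesign` (columns re-standardized; columns that
#'   become constant are dropped).
#' @export
bandpass_design <- function(design, band_hz = c(0.01, 0.1), tr_s = 1,
                            order = 4L) {
  X <- design$regressors
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == "constant") next
    v <- as.vector(.fft_filter_cols(matrix(X[, j], ncol = 1), tr_s,
                                    band_hz, order))
    if (stats::sd(v) < 1e-12) { keep[j] <- FALSE; next }
    X[, j] <- (v - mean(v)) / stats::sd(v)
  }
  structure(list(regressors = X[, keep, drop = FALSE],
                 names = colnames(X)[keep]),
            class = "NuisanceDesign")
}
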