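# Scan-quality and reliability statistics: SNR within white matter, CNR
# between tissue classes, ABC/2 lesion volumetry, and the intraclass
# correlation coefficient for inter-rater agreement.

.masked_values <- function(volume, mask, what) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.logical(mask) || !identical(dim(mask), dim(volume$data)))
    stop(what, " mask must be a logical array with the volume's shape")
  x <- volume$data[mask]
  if (length(x) == 0L) stop(what, " mask is empty")
  x
}

#' Signal-to-noise ratio within a tissue mask
#'
#' Mean intensity over sample SD within the white-matter segmentation (or
#' any mask).  Invariant under positive multiplicative intensity scaling;
#' not invariant under intensity offsets.
#'
#' @param volume a [voxel_volume].
#' @param wm logical mask array.
#' @return the SNR (dimensionless).
#' @export
snr <- function(volume, wm) {
  x <- .masked_values(volume, wm, "WM")
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("constant region: SD of masked intensities is 0")
  mean(x) / s
}

.contrast <- function(xa, xb) {
  abs(mean(xa) - mean(xb)) / sqrt((stats::var(xa) + stats::var(xb)) / 2)
}

#' Contrast-to-noise ratio from tissue segmentations
#'
#' Average of the WM-GM and GM-CSF contrasts, with
#' `contrast(a, b) = |mean_a - mean_b| / sqrt((var_a + var_b)/2)`
#' (pooled-SD normalization).  Invariant under intensity offsets and
#' positive scaling.
#'
#' @param volume a [voxel_volume].
#' @param masks a [tissue_masks] object.
#' @return the CNR (dimensionless).
#' @export
cnr <- function(volume, masks) {
  stopifnot(inherits(masks, "tissue_masks"))
  wm <- .masked_values(volume, masks$wm, "WM")
  gm <- .masked_values(volume, masks$gm, "GM")
  csf <- .masked_values(volume, masks$csf, "CSF")
  (.contrast(wm, gm) + .contrast(gm, csf)) / 2
}

#' ABC/2 lesion volume from caliper diameters
#'
#' The bedside estimate: product of the two largest perpendicular in-slice
#' diameters (A, B) and the craniocaudal extent (C), divided by 2.
#' Symmetric in its three arguments.
#'
#' @param a_mm,b_mm,c_mm diameters in mm, all positive.
#' @return volume in ml.
#' @export
abc2 <- function(a_mm, b_mm, c_mm) {
  if (any(c(a_mm, b_mm, c_mm) <= 0)) stop("ABC/2 diameters must be positive")
  a_mm * b_mm * c_mm / 2000
}

#' ABC/2 lesion volume measured from a binary mask
#'
#' Slices are taken along the third array axis (axial).  On the slice with
#' the largest lesion cross-section (ties: lowest slice index), A is the
#' maximum pairwise distance between lesion voxel centers and B the
#' maximum extent perpendicular to A's direction; C is the number of
#' slices containing lesion times the slice thickness.
#'
#' @param mask logical 3-D array.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @return volume in ml, with attributes `A_mm`, `B_mm`, `C_mm`.
#' @export
abc2_from_mask <- function(mask, voxel_size = c(1, 1, 1)) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3-D array")
  if (!any(mask)) stop("empty mask")
  vs <- as.numeric(voxel_size)
  per_slice <- apply(mask, 3L, sum)
  c_mm <- sum(per_slice > 0) * vs[3L]
  k <- which.max(per_slice)            # which.max takes the lowest tied index
  sl <- mask[, , k]
  ij <- which(sl, arr.ind = TRUE)
  pts <- cbind(ij[, 1L] * vs[1L], ij[, 2L] * vs[2L])
  if (nrow(pts) == 1L) {
    a_mm <- vs[1L]; b_mm <- vs[2L]     # single voxel: one voxel's footprint
  } else {
    d2 <- as.matrix(stats::dist(pts))
    mx <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
    a_mm <- max(d2)
    dir <- pts[mx[2L], ] - pts[mx[1L], ]
    dir <- dir / sqrt(sum(dir^2))
    perp <- c(-dir[2L], dir[1L])
    proj <- pts %*% perp
    b_mm <- max(proj) - min(proj)
    if (b_mm == 0) b_mm <- min(vs[1:2])  # collinear set: one voxel wide
  }
  structure(abc2(a_mm, b_mm, c_mm), A_mm = a_mm, B_mm = b_mm, C_mm = c_mm)
}

#' Intraclass correlation coefficient for inter-rater reliability
#'
#' Two-way, single-measurement ICC from the subjects-by-raters mean
#' squares.  `form = "agreement"` gives the two-way random-effects,
#' absolute-agreement coefficient ICC(2,1) (the default);
#' `form = "consistency"` gives the two-way mixed, consistency coefficient
#' ICC(3,1).  Confidence intervals use the standard F-based constructions
#' (exact for consistency, Satterthwaite-approximated for agreement).
#'
#' @param measurements numeric matrix, subjects in rows, raters in columns;
#'   no missing entries, at least 2 of each.
#' @param confidence confidence level for the interval (default 0.95).
#' @param form `"agreement"` or `"consistency"`.
#' @return list with `estimate`, `ci_lower`, `ci_upper`, `form`,
#'   `confidence`, `n_subjects`, `n_raters`, and the mean squares
#'   `ms_rows`, `ms_cols`, `ms_error`.
#' @export
icc <- function(measurements, confidence = 0.95,
                form = c("agreement", "consistency")) {
  form <- match.arg(form)
  x <- as.matrix(measurements)
  if (anyNA(x)) stop("missing entries are not allowed in the rater matrix")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rowm, colm, "+") + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - confidence
  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  # degenerate perfect-agreement data (zero error mean square) collapses the
  # F-based interval; report the point estimate as both bounds then
  lo <- if (is.finite(lo)) min(lo, est) else est
  hi <- if (is.finite(hi)) max(hi, est) else est
  list(estimate = est, ci_lower = lo, ci_upper = hi,
       form = form, confidence = confidence,
       n_subjects = n, n_raters = k,
       ms_rows = msr, ms_cols = msc, ms_error = mse)
}
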