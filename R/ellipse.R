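#' Direct least-squares ellipse fit
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` to planar
#' points by minimizing the algebraic distance under the ellipse-specific
#' normalization `4ac - b^2 = 1` (numerically stable block decomposition),
#' which guarantees the solution is an ellipse. Points are centred on
#' their centroid before fitting, so the fit is exactly translation
#' invariant.
#'
#' @param points n x 2 numeric matrix of (x, y) coordinates (cm); at
#'   least 5 non-collinear points.
#' @return object of class `ellipse_fit` with fields `conic` (named
#'   a..f), `center` (cm), `semi_major`, `semi_minor` (cm), `orientation`
#'   (radians in `[0, pi)`, undefined-but-reported for circles) and
#'   `rms_algebraic` (RMS algebraic residual).
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be an n x 2 matrix")
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 5L) stop("degenerate ROI: need >= 5 points")
  ctr <- colMeans(points)
  x <- points[, 1] - ctr[1]; y <- points[, 2] - ctr[2]
  if (abs(det(stats::cov(cbind(x, y)))) < 1e-24)
    stop("degenerate ROI: points are collinear")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # pick the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (length(k) == 0) stop("degenerate ROI: no ellipse solution")
  a1 <- Re(ev$vectors[, k[1]])
  coef <- c(a1, Tm %*% a1)
  # undo the centroid shift: substitute x -> x - cx, y -> y - cy
  a <- coef[1]; b <- coef[2]; cc <- coef[3]
  d <- coef[4]; e <- coef[5]; f <- coef[6]
  d2 <- d - 2 * a * ctr[1] - b * ctr[2]
  e2 <- e - 2 * cc * ctr[2] - b * ctr[1]
  f2 <- f + a * ctr[1]^2 + b * ctr[1] * ctr[2] + cc * ctr[2]^2 -
    d * ctr[1] - e * ctr[2]
  conic <- c(a = a, b = b, c = cc, d = d2, e = e2, f = f2)
  geo <- conic_to_geometric(conic)
  res <- conic[1] * points[, 1]^2 + conic[2] * points[, 1] * points[, 2] +
    conic[3] * points[, 2]^2 + conic[4] * points[, 1] +
    conic[5] * points[, 2] + conic[6]
  structure(c(list(conic = conic, rms_algebraic = sqrt(mean(res^2))), geo),
            class = "ellipse_fit")
}

# conic coefficients -> center / semi-axes / orientation
conic_to_geometric <- function(k) {
  if (k[["a"]] + k[["c"]] < 0) k <- -k   # fix overall conic scale sign
  a <- k[["a"]]; b <- k[["b"]]; cc <- k[["c"]]
  d <- k[["d"]]; e <- k[["e"]]; f <- k[["f"]]
  disc <- b^2 - 4 * a * cc
  if (disc >= 0) stop("conic is not an ellipse (discriminant >= 0)")
  x0 <- (2 * cc * d - b * e) / disc
  y0 <- (2 * a * e - b * d) / disc
  lam <- 2 * (a * e^2 + cc * d^2 + f * b^2 - b * d * e - 4 * a * cc * f)
  s <- sqrt((a - cc)^2 + b^2)
  semi_major <- -sqrt(lam * ((a + cc) + s)) / disc
  semi_minor <- -sqrt(lam * ((a + cc) - s)) / disc
  # major-axis direction: eigenvector of the smaller quadratic-form
  # eigenvalue of [[a, b/2], [b/2, c]]
  Q <- matrix(c(a, b / 2, b / 2, cc), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  v <- eg$vectors[, which.min(eg$values)]
  th <- atan2(v[2], v[1]) %% pi
  list(center = c(x0, y0), semi_major = semi_major,
       semi_minor = semi_minor, orientation = th)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(paste0("ellipse_fit: center (%.3f, %.3f) cm, semi-axes ",
                     "%.3f x %.3f cm, orientation %.1f deg\n"),
              x$center[1], x$center[2], x$semi_major, x$semi_minor,
              x$orientation * 180 / pi))
  invisible(x)
}

#' Area of a fitted ellipse
#' @param fit an `ellipse_fit`.
#' @return area in cm^2 (`pi * semi_major * semi_minor`).
#' @export
ellipse_area <- function(fit) pi * fit$semi_major * fit$semi_minor

# boundary points (cm) of a binary slice via the 0.5-level contour
slice_boundary_points <- function(sl, vox_cm) {
  padded <- matrix(0, nrow(sl) + 2, ncol(sl) + 2)
  padded[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl
  xs <- (seq_len(nrow(padded)) - 1.5) * vox_cm[1]   # voxel-centre coords
  ys <- (seq_len(ncol(padded)) - 1.5) * vox_cm[2]
  cl <- grDevices::contourLines(xs, ys, padded, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  do.call(rbind, lapply(cl, function(p) cbind(p$x, p$y)))
}

#' Measure a lesion ROI: maximum diameter and slice-profile volume
#'
#' Fits an ellipse to each slice's ROI boundary (0.5-level contour of the
#' mask, in cm). The maximum diameter is twice the largest per-slice
#' semi-major axis; the volume is the slice profile (slice thickness +
#' gap, in cm) times the sum of per-slice areas. Areas come from the
#' fitted ellipse by default, or from the raw pixel count
#' (`area_method = "pixel"`).
#'
#' @param roi a binary [mask3d()] (nonzero = lesion) carrying voxel size
#'   and slice geometry.
#' @param area_method `"ellipse"` (default) or `"pixel"`.
#' @return object of class `lesion_measurement` with `max_diameter_cm`,
#'   `volume_cc`, `slice_profile_cm`, `n_slices`, `fits` (per-slice
#'   [fit_ellipse()] results, named by slice index).
#' @export
measure_lesion <- function(roi, area_method = c("ellipse", "pixel")) {
  area_method <- match.arg(area_method)
  stopifnot(inherits(roi, "mask3d"))
  m <- roi$labels > 0
  if (!any(m)) stop("empty lesion ROI")
  vox_cm <- roi$voxel_size[1:2] / 10
  profile_cm <- (roi$slice_thickness + roi$slice_gap) / 10
  fits <- list(); areas <- numeric(0)
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k] * 1
    if (!any(sl > 0)) next
    pts <- slice_boundary_points(sl, vox_cm)
    fit <- tryCatch(fit_ellipse(pts), error = function(e) NULL)
    if (is.null(fit)) {
      warning("slice ", k, ": degenerate ROI, skipped")
      next
    }
    fits[[as.character(k)]] <- fit
    areas <- c(areas, switch(area_method,
      ellipse = ellipse_area(fit),
      pixel = sum(sl) * vox_cm[1] * vox_cm[2]))
  }
  if (length(fits) == 0) stop("all slices degenerate: cannot measure lesion")
  structure(list(
    max_diameter_cm = 2 * max(vapply(fits, `[[`, numeric(1), "semi_major")),
    volume_cc = profile_cm * sum(areas),
    slice_profile_cm = profile_cm,
    n_slices = length(fits), fits = fits, area_method = area_method),
    class = "lesion_measurement")
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf(paste0("lesion_measurement: max diameter %.3f cm, volume ",
                     "%.3f cc over %d slice(s) (profile %.1f cm)\n"),
              x$max_diameter_cm, x$volume_cc, x$n_slices,
              x$slice_profile_cm))
  invisible(x)
}
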