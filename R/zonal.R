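#' Build a probabilistic zonal atlas from aligned training subjects
#'
#' The statistical atlas is the voxelwise mean intensity over training
#' subjects aligned to the target grid; the PZ and TZ probability maps are
#' the fraction of training subjects whose zone mask contains each voxel.
#' Zone intensity means are computed on per-subject min-max-normalized
#' intensities.
#'
#' @param training list of subjects, each a list with elements `volume`
#'   (a [volume3d()] or array), `pz` and `tz` ([mask3d()] or logical
#'   arrays), all on the target grid.
#' @return object of class `probabilistic_atlas` with fields `p_pz`,
#'   `p_tz`, `statistical_atlas`, `mu_pz`, `mu_tz`, `n_subjects`.
#' @export
build_atlas <- function(training) {
  if (length(training) < 1) stop("need at least one training subject")
  arr <- function(x) if (inherits(x, "volume3d")) x$data else
    if (inherits(x, "mask3d")) x$labels else x
  dm <- dim(arr(training[[1]]$volume))
  n <- length(training)
  sum_img <- array(0, dm); cnt_pz <- array(0L, dm); cnt_tz <- array(0L, dm)
  mu_pz <- mu_tz <- 0
  for (s in training) {
    v <- arr(s$volume); pz <- arr(s$pz) > 0; tz <- arr(s$tz) > 0
    if (!identical(dim(v), dm) || !identical(dim(pz), dm) ||
        !identical(dim(tz), dm))
      stop("training subject not on the target grid")
    sum_img <- sum_img + v
    cnt_pz <- cnt_pz + pz
    cnt_tz <- cnt_tz + tz
    vn <- normalize01(v)
    mu_pz <- mu_pz + mean(vn[pz])
    mu_tz <- mu_tz + mean(vn[tz])
  }
  structure(list(p_pz = cnt_pz / n, p_tz = cnt_tz / n,
                 statistical_atlas = sum_img / n,
                 mu_pz = mu_pz / n, mu_tz = mu_tz / n, n_subjects = n),
            class = "probabilistic_atlas")
}

#' @export
print.probabilistic_atlas <- function(x, ...) {
  cat(sprintf(paste0("probabilistic_atlas: %d subject(s), ",
                     "mu_PZ = %.3f, mu_TZ = %.3f (normalized)\n"),
              x$n_subjects, x$mu_pz, x$mu_tz))
  invisible(x)
}

normalize01 <- function(v) {
  r <- range(v)
  if (diff(r) < 1e-300) return(array(0, dim(v)))
  (v - r[1]) / diff(r)
}

#' Threshold atlas probabilities into zone masks
#'
#' Gland voxels with zone probability strictly above the threshold are
#' assigned to that zone; voxels at or below the threshold for both zones
#' form the partial-volume (PV) set awaiting [pv_correct()]. If both
#' probabilities exceed the threshold the larger wins (PZ on exact tie).
#'
#' @param atlas a [build_atlas()] result.
#' @param gland binary [mask3d()] (or logical array) of the gland.
#' @param threshold probability threshold, default 0.5.
#' @return list of logical arrays `pz`, `tz`, `pv` — pairwise disjoint,
#'   union = gland.
#' @export
threshold_zones <- function(atlas, gland, threshold = 0.5) {
  g <- if (inherits(gland, "mask3d")) gland$labels > 0 else gland > 0
  if (!identical(dim(g), dim(atlas$p_pz)))
    stop("atlas is not on the gland grid")
  ppz <- atlas$p_pz; ptz <- atlas$p_tz
  pz <- g & ppz > threshold & !(ptz > threshold & ptz > ppz)
  tz <- g & ptz > threshold & !pz
  pv <- g & !pz & !tz
  list(pz = pz, tz = tz, pv = pv)
}

#' Partial-volume cost weights
#'
#' Weights of the three belongingness-cost terms: normalized intensity
#' difference, (one minus) zone probability, and normalized Euclidean
#' distance to the zone. Defaults weight the terms equally.
#'
#' @param w_int,w_prob,w_dist nonnegative weights, sum > 0.
#' @param tie zone assigned when costs are exactly equal (`"pz"` default:
#'   ambiguous boundary voxels err toward the zone under analysis).
#' @return list of class `pv_cost_params`.
#' @export
pv_cost_params <- function(w_int = 1 / 3, w_prob = 1 / 3, w_dist = 1 / 3,
                           tie = c("pz", "tz")) {
  tie <- match.arg(tie)
  stopifnot(w_int >= 0, w_prob >= 0, w_dist >= 0,
            w_int + w_prob + w_dist > 0)
  structure(list(w_int = w_int, w_prob = w_prob, w_dist = w_dist,
                 tie = tie), class = "pv_cost_params")
}

# voxel coordinates (mm) of TRUE entries of a logical array
coords_mm <- function(m, vox_mm) {
  idx <- which(m, arr.ind = TRUE)
  sweep(idx, 2, vox_mm, `*`)
}

# boundary voxels of a region: region voxels with a 6-neighbour outside
region_boundary <- function(m) {
  dm <- dim(m)
  interior <- m
  shift_and <- function(d) {
    s <- array(FALSE, dm)
    lo <- pmax(1 - d, 1); hi <- pmin(dm - d, dm)
    if (any(lo > hi)) return(s)   # neighbour entirely outside the grid
    i1 <- lo[1]:hi[1]; j1 <- lo[2]:hi[2]; k1 <- lo[3]:hi[3]
    s[i1, j1, k1] <- m[i1 + d[1], j1 + d[2], k1 + d[3]]
    s
  }
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_and(d)
  m & !interior
}

# min distance (mm) from each row of `pts` to the point set `ref` (chunked)
min_dist_to_set <- function(pts, ref, chunk = 256L) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    blk <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(ref^2), `+`) -
      2 * blk %*% t(ref)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Assign partial-volume voxels to a zone by belongingness cost
#'
#' Each PV voxel is assigned to the zone minimizing
#' `w_int * |I(v) - mu_z| + w_prob * (1 - p_z(v)) + w_dist * d(v, z)`,
#' where `I` is the min-max-normalized intensity, `mu_z` the zone's
#' normalized intensity mean computed from the subject's thresholded zone
#' voxels, `p_z` the atlas probability, and `d` the Euclidean distance
#' (mm) to the nearest voxel of the zone, normalized by the gland's
#' bounding-box diagonal. Exact cost ties go to the zone named in
#' `params$tie`.
#'
#' @param pv logical array (or [mask3d()]) of unassigned gland voxels.
#' @param volume the intensity [volume3d()] used for the intensity term.
#' @param atlas a [build_atlas()] result.
#' @param pz,tz logical arrays of already-assigned zone voxels (nonempty).
#' @param params a [pv_cost_params()].
#' @return list of logical arrays `pz`, `tz` forming an exact partition
#'   of `pz | tz | pv`.
#' @export
pv_correct <- function(pv, volume, atlas, pz, tz,
                       params = pv_cost_params()) {
  as_l <- function(x) if (inherits(x, "mask3d")) x$labels > 0 else x > 0
  pv <- as_l(pv); pz <- as_l(pz); tz <- as_l(tz)
  if (!any(pz) || !any(tz))
    stop("cannot compute zone statistics: PZ or TZ empty before correction")
  if (!any(pv)) return(list(pz = pz, tz = tz))
  v <- if (inherits(volume, "volume3d")) volume$data else volume
  vox_mm <- if (inherits(volume, "volume3d")) volume$voxel_size else
    rep(1, 3)
  vn <- normalize01(v)
  mu_pz <- mean(vn[pz]); mu_tz <- mean(vn[tz])
  gl <- pz | tz | pv
  gc_mm <- coords_mm(gl, vox_mm)
  diam <- sqrt(sum((apply(gc_mm, 2, max) - apply(gc_mm, 2, min))^2))
  if (diam <= 0) diam <- 1
  pv_pts <- coords_mm(pv, vox_mm)
  d_pz <- min_dist_to_set(pv_pts, coords_mm(region_boundary(pz), vox_mm)) / diam
  d_tz <- min_dist_to_set(pv_pts, coords_mm(region_boundary(tz), vox_mm)) / diam
  ii <- which(pv)
  cost_pz <- params$w_int * abs(vn[ii] - mu_pz) +
    params$w_prob * (1 - atlas$p_pz[ii]) + params$w_dist * d_pz
  cost_tz <- params$w_int * abs(vn[ii] - mu_tz) +
    params$w_prob * (1 - atlas$p_tz[ii]) + params$w_dist * d_tz
  to_pz <- if (params$tie == "pz") cost_pz <= cost_tz else cost_pz < cost_tz
  pz2 <- pz; tz2 <- tz
  pz2[ii[to_pz]] <- TRUE
  tz2[ii[!to_pz]] <- TRUE
  list(pz = pz2, tz = tz2)
}

#' Atlas-based zonal segmentation of a segmented gland
#'
#' Thresholds the probabilistic atlas at the given probability and
#' resolves the remaining partial-volume voxels with [pv_correct()],
#' returning an exact PZ/TZ partition of the gland.
#'
#' @param gland binary [mask3d()] of the gland.
#' @param volume intensity [volume3d()] (the DWI channel).
#' @param atlas a [build_atlas()] result.
#' @param threshold atlas probability threshold (default 0.5).
#' @param params a [pv_cost_params()].
#' @return list of [mask3d()] `pz` and `tz`.
#' @export
segment_zones <- function(gland, volume, atlas, threshold = 0.5,
                          params = pv_cost_params()) {
  thr <- threshold_zones(atlas, gland, threshold)
  fixed <- if (any(thr$pv)) pv_correct(thr$pv, volume, atlas, thr$pz,
                                       thr$tz, params)
           else list(pz = thr$pz, tz = thr$tz)
  mk <- function(x) mask3d(x, voxel_size = volume$voxel_size,
                           slice_thickness = volume$slice_thickness,
                           slice_gap = volume$slice_gap)
  list(pz = mk(fixed$pz), tz = mk(fixed$tz))
}
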