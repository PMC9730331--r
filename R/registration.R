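#' 12-parameter affine transform
#'
#' A 3D affine map with a 3x3 linear block (shear, scale, rotation) and a
#' translation vector — 12 free parameters. The map acts on continuous
#' voxel coordinates about the grid centre `c`:
#' `x' = A (x - c) + t + c`, so scales and rotations pivot on the volume
#' centre rather than the array corner.
#'
#' @param linear 3x3 numeric matrix, invertible.
#' @param translation numeric 3-vector, in voxel units per axis.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  if (abs(det(linear)) < 1e-12) stop("linear block is singular")
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform (voxel units, centre-pivoted):\n")
  print(cbind(x$linear, x$translation))
  invisible(x)
}

#' Invert an affine transform
#' @param x an [affine_transform()].
#' @return the inverse [affine_transform()].
#' @export
invert_affine <- function(x) {
  Ai <- solve(x$linear)
  affine_transform(Ai, -Ai %*% x$translation)
}

# trilinear interpolation of array `a` at fractional 1-based coordinates
# (n x 3 matrix); outside the field of view -> 0
interp3 <- function(a, xyz) {
  dm <- dim(a)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  ok <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
  out <- numeric(nrow(xyz))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), dm[1] - 1); y0 <- pmin(floor(y), dm[2] - 1)
  z0 <- pmin(floor(z), dm[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * dm[1] * dm[2] + (j - 1) * dm[1] + i
  v <- a[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       a[idx(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
       a[idx(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz) +
       a[idx(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz) +
       a[idx(x0, y0, z0 + 1)] * (1 - fx) * (1 - fy) * fz +
       a[idx(x0 + 1, y0, z0 + 1)] * fx * (1 - fy) * fz +
       a[idx(x0, y0 + 1, z0 + 1)] * (1 - fx) * fy * fz +
       a[idx(x0 + 1, y0 + 1, z0 + 1)] * fx * fy * fz
  out[ok] <- v
  out
}

#' Resample a volume through an affine transform
#'
#' Maps the moving volume onto the fixed grid by inverse mapping with
#' trilinear interpolation; voxels mapped from outside the field of view
#' are set to 0.
#'
#' @param vol a [volume3d()] (or plain 3D array).
#' @param transform an [affine_transform()].
#' @return object of the same kind as `vol`, resampled.
#' @export
apply_affine <- function(vol, transform) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  dm <- dim(a)
  Ti <- invert_affine(transform)
  ctr <- (dm + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                             z = seq_len(dm[3])))
  src <- sweep(g, 2, ctr) %*% t(Ti$linear)
  src <- sweep(src, 2, Ti$translation + ctr, `+`)
  res <- array(interp3(a, src), dm)
  if (inherits(vol, "volume3d"))
    volume3d(res, vol$voxel_size, vol$slice_thickness, vol$slice_gap)
  else res
}

#' Mutual information between two images
#'
#' Shannon mutual information `H(A) + H(B) - H(A,B)` (in bits) computed
#' from an equal-width joint histogram of the two images over the voxels
#' of an optional mask.
#'
#' @param fixed,moving [volume3d()] objects or arrays of equal shape.
#' @param mask optional logical array / [mask3d()]; default all voxels.
#' @param bins number of histogram bins per image (>= 2, default 32).
#' @return mutual information in bits.
#' @export
mutual_information <- function(fixed, moving, mask = NULL, bins = 32L) {
  stopifnot(bins >= 2)
  a <- if (inherits(fixed, "volume3d")) fixed$data else fixed
  b <- if (inherits(moving, "volume3d")) moving$data else moving
  if (!identical(dim(a), dim(b))) stop("images are on different grids")
  if (!is.null(mask)) {
    m <- if (inherits(mask, "mask3d")) mask$labels > 0 else mask > 0
    if (!any(m)) stop("empty mask overlap")
    a <- a[m]; b <- b[m]
  }
  bin_of <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-300) return(rep(1L, length(x)))
    pmin(1L + floor((x - r[1]) / diff(r) * bins), bins)
  }
  ia <- bin_of(as.vector(a)); ib <- bin_of(as.vector(b))
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  ent(pa) + ent(pb) - ent(p)
}

#' Registration parameters
#'
#' @param bins histogram bins for mutual information (default 32).
#' @param levels multiresolution levels (default 2: half in-plane
#'   resolution, then full).
#' @param maxit iterations per optimizer stage.
#' @param smooth_sigma in-plane Gaussian pre-smoothing SD in voxels
#'   (0 = none; smoothing can displace the MI optimum on
#'   piecewise-constant images, so the default is off).
#' @return list of class `mi_params`.
#' @export
mi_params <- function(bins = 32L, levels = 2L, maxit = 400L,
                      smooth_sigma = 0) {
  stopifnot(bins >= 2, levels >= 1)
  structure(list(bins = as.integer(bins), levels = as.integer(levels),
                 maxit = as.integer(maxit), smooth_sigma = smooth_sigma),
            class = "mi_params")
}

# bin an image into `bins` equal-width intensity bins
bin_image <- function(x, bins) {
  r <- range(x)
  if (diff(r) < 1e-300) return(array(1L, dim(x)))
  array(pmin(1L + as.integer(floor((x - r[1]) / diff(r) * bins)), bins),
        dim(x))
}

# Partial-volume-interpolated MI objective (Maes et al.): the joint
# histogram is built by distributing each fixed voxel's mass over the 8
# moving-image neighbours of its inverse-mapped position with trilinear
# weights. MI then varies smoothly with the transform, unlike
# resample-then-histogram MI, whose interpolation blur displaces the
# optimum on piecewise-constant images. Returns a function(transform) ->
# MI in bits over in-field voxels.
make_pv_mi <- function(fixed, moving, bins) {
  dm <- dim(fixed)
  bins <- as.integer(bins)
  fb <- as.integer(bin_image(fixed, bins))
  mb <- as.integer(bin_image(moving, bins))
  g0 <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                              z = seq_len(dm[3])))
  ctr <- (dm + 1) / 2
  g0 <- sweep(g0, 2, ctr)
  nxy <- dm[1] * dm[2]
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  function(transform) {
    Ti <- invert_affine(transform)
    src <- g0 %*% t(Ti$linear)
    off <- Ti$translation + ctr
    sx <- src[, 1] + off[1]; sy <- src[, 2] + off[2]; sz <- src[, 3] + off[3]
    ok <- sx >= 1 & sx <= dm[1] & sy >= 1 & sy <= dm[2] &
      sz >= 1 & sz <= dm[3]
    if (sum(ok) < 100) return(NA_real_)
    sx <- sx[ok]; sy <- sy[ok]; sz <- sz[ok]
    f <- fb[ok]
    n <- length(f)
    x0 <- pmin(floor(sx), dm[1] - 1); y0 <- pmin(floor(sy), dm[2] - 1)
    z0 <- pmin(floor(sz), dm[3] - 1)
    wx <- sx - x0; wy <- sy - y0; wz <- sz - z0
    base <- (z0 - 1) * nxy + (y0 - 1) * dm[1] + x0
    fcode <- (f - 1L) * bins
    idx8 <- integer(8L * n); w8 <- numeric(8L * n)
    pos <- 0L
    for (corner in 0:7) {
      dx <- corner %% 2L; dy <- (corner %/% 2L) %% 2L; dz <- corner %/% 4L
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
           (if (dz) wz else 1 - wz)
      idx8[pos + seq_len(n)] <- fcode + mb[base + dz * nxy + dy * dm[1] + dx]
      w8[pos + seq_len(n)] <- w
      pos <- pos + n
    }
    keep <- w8 > 0
    rs <- rowsum(w8[keep], idx8[keep], reorder = FALSE)
    jidx <- as.integer(rownames(rs))
    p <- rs[, 1] / sum(rs)
    pa <- rowsum(p, (jidx - 1L) %/% bins, reorder = FALSE)[, 1]
    pb <- rowsum(p, (jidx - 1L) %% bins, reorder = FALSE)[, 1]
    ent(pa) + ent(pb) - ent(p)
  }
}

gauss_smooth_slices <- function(a, sigma) {
  if (sigma <= 0) return(a)
  sz <- 2L * ceiling(2 * sigma) + 1L
  br <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma)
  for (k in seq_len(dim(a)[3]))
    a[, , k] <- EBImage::filter2(a[, , k], br)
  a
}

downsample2_inplane <- function(a) {
  dm <- dim(a)
  i <- seq(1, dm[1] - 1, by = 2); j <- seq(1, dm[2] - 1, by = 2)
  (a[i, j, , drop = FALSE] + a[i + 1, j, , drop = FALSE] +
   a[i, j + 1, , drop = FALSE] + a[i + 1, j + 1, , drop = FALSE]) / 4
}

theta_to_transform <- function(p) {
  affine_transform(diag(3) + matrix(p[1:9], 3, 3), p[10:12])
}

# centre of mass of nonzero intensities, voxel coordinates
com3 <- function(a) {
  w <- pmax(a, 0)
  s <- sum(w)
  if (s == 0) return((dim(a) + 1) / 2)
  g <- expand.grid(x = seq_len(dim(a)[1]), y = seq_len(dim(a)[2]),
                   z = seq_len(dim(a)[3]))
  c(sum(g$x * w) / s, sum(g$y * w) / s, sum(g$z * w) / s)
}

# Nelder-Mead on a parameter subset with restarts (the joint-histogram MI
# surface is stepped; restarting from the collapsed simplex escapes
# premature convergence)
nm_stage <- function(p, active, fn, maxit, scale, restarts = 3L) {
  bv <- fn(p)
  for (r in seq_len(restarts)) {
    o <- stats::optim(p[active], function(q) {
      pp <- p; pp[active] <- q; fn(pp)
    }, method = "Nelder-Mead",
       control = list(maxit = maxit, reltol = 1e-10,
                      parscale = scale[active]))
    if (o$value < bv) p[active] <- o$par
    if (bv - o$value < 1e-7) break
    bv <- min(bv, o$value)
  }
  p
}

#' Register a T2W gland ROI to the DWI gland ROI
#'
#' Finds the 12-parameter affine transform maximizing the mutual
#' information between the fixed (DWI) and transformed moving (T2W)
#' gland-ROI-masked volumes. Optimization is staged Nelder-Mead with
#' restarts: centre-of-mass initialization, coarse translation-only
#' search on a half-resolution grid, then translation + isotropic scale,
#' translation + per-axis scales, and a full 12-parameter refine at full
#' resolution. If the result does not improve on the identity's mutual
#' information the identity is returned with a warning.
#'
#' @param t2w_roi moving [volume3d()] (gland-ROI-masked intensities).
#' @param dwi_roi fixed [volume3d()] (gland-ROI-masked intensities).
#' @param params an [mi_params()].
#' @return an [affine_transform()] mapping the moving volume onto the
#'   fixed grid, with attributes `mi_initial` and `mi_final`.
#' @export
register_t2w_to_dwi <- function(t2w_roi, dwi_roi, params = mi_params()) {
  fx <- if (inherits(dwi_roi, "volume3d")) dwi_roi$data else dwi_roi
  mv <- if (inherits(t2w_roi, "volume3d")) t2w_roi$data else t2w_roi
  if (sum(abs(fx)) == 0 || sum(abs(mv)) == 0) stop("empty ROI volume")
  fx_s <- gauss_smooth_slices(fx, params$smooth_sigma)
  mv_s <- gauss_smooth_slices(mv, params$smooth_sigma)

  pv_mi <- make_pv_mi(fx_s, mv_s, params$bins)
  neg_mi <- function(p) {
    tr <- tryCatch(theta_to_transform(p), error = function(e) NULL)
    if (is.null(tr)) return(1e6)
    v <- pv_mi(tr)
    if (is.na(v)) 1e6 else -v
  }

  p0 <- c(rep(0, 9), com3(fx_s) - com3(mv_s))
  scale <- c(rep(0.05, 9), rep(0.5, 3))
  iso_vec <- function(q) c(q[1], 0, 0, 0, q[1], 0, 0, 0, q[1], q[2:4])

  # Candidate transforms are generated cheaply (half-resolution grid when
  # levels >= 2, multi-start over isotropic scale) and then compared only
  # AFTER a short full-resolution refine. The partial-volume histogram
  # has spurious sharp maxima wherever sampling is grid-commensurate
  # (notably at the identity), and these spikes can dominate the coarse
  # objective, so no winner is declared at coarse resolution.
  use_coarse <- params$levels >= 2
  if (use_coarse) {
    pv_mi_c <- make_pv_mi(downsample2_inplane(fx_s),
                          downsample2_inplane(mv_s), params$bins)
    neg_mi_c <- function(p) {
      tr <- tryCatch(theta_to_transform(p), error = function(e) NULL)
      if (is.null(tr)) return(1e6)
      v <- pv_mi_c(tr)
      if (is.na(v)) 1e6 else -v
    }
    to_full <- function(p) { p[10:11] <- p[10:11] * 2; p }
    p_c <- p0; p_c[10:11] <- p_c[10:11] / 2
  } else {
    neg_mi_c <- neg_mi
    to_full <- identity
    p_c <- p0
  }
  p_c <- nm_stage(p_c, 10:12, neg_mi_c, params$maxit, scale,
                  restarts = 2L)
  cands <- list(to_full(p_c),
                nm_stage(p0, 10:12, neg_mi, params$maxit, scale,
                         restarts = 1L))
  neg_mi_iso_c <- function(q) neg_mi_c(iso_vec(q))
  for (s0 in c(0, 0.1, -0.1)) {
    qi <- nm_stage(c(s0, p_c[10:12]), 1:4, neg_mi_iso_c, params$maxit,
                   c(0.05, 0.5, 0.5, 0.5), restarts = 2L)
    cands <- c(cands, list(to_full(iso_vec(qi))))
  }
  # short full-resolution refine (translation + per-axis scales) of each
  # candidate, then select by full-resolution MI
  best_v <- Inf; p <- cands[[1]]
  for (pc in cands) {
    pr <- nm_stage(pc, c(1, 5, 9, 10, 11, 12), neg_mi,
                   max(100L, params$maxit %/% 2), scale, restarts = 1L)
    v <- neg_mi(pr)
    if (v < best_v) { best_v <- v; p <- pr }
  }
  # full 12-parameter refine
  p <- nm_stage(p, 1:12, neg_mi, params$maxit, scale, restarts = 2L)
  best <- theta_to_transform(p)
  mi0 <- pv_mi(affine_transform())
  mi1 <- pv_mi(best)
  if (is.na(mi1) || mi1 < mi0) {
    warning("registration did not improve mutual information; ",
            "returning identity")
    best <- affine_transform()
    mi1 <- mi0
  }
  attr(best, "mi_initial") <- mi0
  attr(best, "mi_final") <- mi1
  best
}
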