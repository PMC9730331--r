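#' Specification of a synthetic prostate mpMRI phantom
#'
#' Describes an ellipsoidal gland on a dark background, split into a
#' posterior-crescent peripheral zone (PZ) and an anterior transition zone
#' (TZ), carrying elliptical lesions across one or more slices, imaged in
#' three channels (DWI, ADC, T2W) with optional additive noise. The
#' through-plane grid spacing is `slice_thickness + slice_gap` so the voxel
#' grid and the slice-profile volume formula are consistent.
#'
#' Channel contrasts are free parameters of the phantom (no
#' lesion-to-background contrast ratio is claimed to match any cohort);
#' defaults make lesions DWI-hyperintense and ADC-hypointense.
#'
#' @param grid_shape integer triple, voxels per axis (x, y, slice).
#' @param voxel_size in-plane voxel size in mm (length 2).
#' @param slice_thickness,slice_gap through-plane geometry, mm.
#' @param gland_semiaxes ellipsoid semi-axes in mm (x, y, z), centred in
#'   the grid.
#' @param zone_split fraction of each axial gland slice's posterior depth
#'   assigned to the PZ crescent, in (0, 1).
#' @param lesions list of [lesion_spec()] objects.
#' @param noise_sigma additive noise SD in intensity units (>= 0).
#' @param noise_model `"gaussian"` or `"rician"` (magnitude-MRI noise).
#' @param channel_contrasts named list (`dwi`, `adc`, `t2w`) of named
#'   numeric vectors with entries `background`, `tz`, `pz`.
#' @param supersample integer >= 1. With 1 (default) voxels are rendered
#'   binary from centre membership and noise-free phantoms are exactly
#'   piecewise constant per region. Larger values average membership
#'   over `supersample^3` sub-voxel offsets at the outer gland boundary,
#'   emulating the partial-volume appearance of real MRI (boundary
#'   voxels carry fractional intensities; sub-voxel geometry becomes
#'   recoverable, e.g. by registration). Truth masks always use centre
#'   membership.
#' @param seed integer RNG seed; the phantom is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 12),
                         voxel_size = c(0.8, 0.8),
                         slice_thickness = 3, slice_gap = 3,
                         gland_semiaxes = c(28, 23, 27),
                         zone_split = 0.4,
                         lesions = list(),
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician"),
                         channel_contrasts = list(
                           dwi = c(background = 20, tz = 100, pz = 120),
                           adc = c(background = 5, tz = 140, pz = 160),
                           t2w = c(background = 30, tz = 110, pz = 150)),
                         supersample = 1L,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            all(gland_semiaxes > 0), noise_sigma >= 0,
            zone_split > 0, zone_split < 1, supersample >= 1)
  for (ch in c("dwi", "adc", "t2w")) {
    cc <- channel_contrasts[[ch]]
    if (is.null(cc) || !all(c("background", "tz", "pz") %in% names(cc)))
      stop("channel_contrasts$", ch,
           " must name background, tz and pz intensities")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size[1:2]),
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 gland_semiaxes = as.numeric(gland_semiaxes),
                 zone_split = zone_split, lesions = lesions,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 channel_contrasts = channel_contrasts,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of one phantom lesion
#'
#' An elliptical lesion occupying `n_slices` consecutive slices. The
#' ground-truth maximum diameter is twice the largest in-plane semi-major
#' axis; the ground-truth volume is the slice profile (thickness + gap)
#' times the sum of per-slice analytic ellipse areas.
#'
#' @param center voxel coordinates (x, y, slice), 1-based; the lesion is
#'   centred through-plane on `center[3]`.
#' @param in_plane_semiaxes cm pair `(a, b)` with `a >= b`, or a list of
#'   one pair per slice.
#' @param orientation in-plane rotation of the major axis, radians.
#' @param n_slices number of slices the lesion spans (>= 1).
#' @param channel_offsets named numeric: intensity deltas added to the
#'   underlying zone intensity in each channel. Defaults make the lesion
#'   DWI-hyperintense and ADC-hypointense.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, in_plane_semiaxes, orientation = 0,
                        n_slices = 1L,
                        channel_offsets = c(dwi = 80, adc = -60, t2w = -40)) {
  n_slices <- as.integer(n_slices)
  stopifnot(length(center) == 3L, n_slices >= 1L)
  if (!is.list(in_plane_semiaxes))
    in_plane_semiaxes <- rep(list(as.numeric(in_plane_semiaxes)), n_slices)
  if (length(in_plane_semiaxes) != n_slices)
    stop("need one semiaxis pair per slice")
  for (ax in in_plane_semiaxes)
    if (length(ax) != 2L || any(ax <= 0) || ax[1] < ax[2])
      stop("in-plane semiaxes must be a positive (major, minor) cm pair")
  structure(list(center = as.numeric(center),
                 in_plane_semiaxes = in_plane_semiaxes,
                 orientation = orientation, n_slices = n_slices,
                 channel_offsets = channel_offsets),
            class = "lesion_spec")
}

# analytic truth for one lesion: diameter (cm) and slice-profile volume (cc)
lesion_truth_measurement <- function(lesion, slice_profile_cm) {
  a <- vapply(lesion$in_plane_semiaxes, `[`, numeric(1), 1L)
  b <- vapply(lesion$in_plane_semiaxes, `[`, numeric(1), 2L)
  list(diameter_cm = 2 * max(a),
       volume_cc = slice_profile_cm * sum(pi * a * b))
}

# slice indices a lesion occupies (centred on center[3])
lesion_slices <- function(lesion) {
  z0 <- round(lesion$center[3]) - floor((lesion$n_slices - 1) / 2)
  z0 + seq_len(lesion$n_slices) - 1L
}

#' Generate a synthetic prostate mpMRI phantom
#'
#' Renders the [phantom_spec()] into per-channel [volume3d()] images plus
#' ground-truth masks and analytic lesion measurements. Noise-free
#' phantoms are piecewise constant per region; PZ and TZ are disjoint and
#' together tile the gland exactly.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_output` with elements `volumes`
#'   (named list `dwi`, `adc`, `t2w`), `gland_truth`, `pz_truth`,
#'   `tz_truth` ([mask3d()]), `lesion_truth` (list of [mask3d()]),
#'   `truth_measurements` (data.frame `lesion`, `diameter_cm`,
#'   `volume_cc`) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vx <- spec$voxel_size
  dz <- spec$slice_thickness + spec$slice_gap
  # world coordinates (mm) of voxel centres, grid centred at 0
  xs <- (seq_len(gs[1]) - (gs[1] + 1) / 2) * vx[1]
  ys <- (seq_len(gs[2]) - (gs[2] + 1) / 2) * vx[2]
  zs <- (seq_len(gs[3]) - (gs[3] + 1) / 2) * dz

  sa <- spec$gland_semiaxes
  # membership of continuous points: gland ellipsoid, and the posterior
  # crescent (PZ) = gland points with y above the analytic per-height cut
  zone_cut <- function(z) {
    ymax <- sa[2] * sqrt(pmax(1 - (z / sa[3])^2, 0))
    ymax * (1 - 2 * spec$zone_split)
  }
  memberships <- function(ox, oy, oz) {
    X2 <- outer(((xs + ox) / sa[1])^2, ((ys + oy) / sa[2])^2, `+`)
    g <- array(FALSE, gs); p <- array(FALSE, gs)
    for (k in seq_len(gs[3])) {
      gk <- X2 + ((zs[k] + oz) / sa[3])^2 <= 1
      g[, , k] <- gk
      p[, , k] <- gk &
        outer(rep(TRUE, gs[1]), ys + oy > zone_cut(zs[k] + oz))
    }
    list(gland = g, pz = p)
  }
  truth_mem <- memberships(0, 0, 0)
  gland <- truth_mem$gland
  pz <- truth_mem$pz
  tz <- gland & !pz

  # class-coverage fractions for rendering (fractional at boundaries
  # when supersample > 1; identical to the truth masks when == 1)
  ss <- spec$supersample
  if (ss > 1) {
    cov_pz <- array(0, gs); cov_tz <- array(0, gs)
    offs <- (seq_len(ss) - (ss + 1) / 2) / ss
    for (ox in offs * vx[1]) for (oy in offs * vx[2])
      for (oz in offs * dz) {
        mem <- memberships(ox, oy, oz)
        cov_pz <- cov_pz + mem$pz
        cov_tz <- cov_tz + (mem$gland & !mem$pz)
      }
    cov_pz <- cov_pz / ss^3; cov_tz <- cov_tz / ss^3
  } else {
    cov_pz <- pz + 0; cov_tz <- tz + 0
  }

  mk <- function(x) mask3d(x, voxel_size = vx,
                           slice_thickness = spec$slice_thickness,
                           slice_gap = spec$slice_gap)

  # lesion masks and analytic truth
  les_masks <- list()
  truth <- data.frame(lesion = integer(), diameter_cm = numeric(),
                      volume_cc = numeric())
  xs_cm <- xs / 10; ys_cm <- ys / 10
  for (li in seq_along(spec$lesions)) {
    L <- spec$lesions[[li]]
    ci <- round(L$center)
    if (any(ci < 1) || any(ci > gs) || !gland[ci[1], ci[2], ci[3]])
      stop("lesion ", li, " center is outside the gland")
    m <- array(FALSE, gs)
    slc <- lesion_slices(L)
    if (any(slc < 1) || any(slc > gs[3]))
      stop("lesion ", li, " extends outside the slice range")
    cx <- xs_cm[ci[1]]; cy <- ys_cm[ci[2]]
    co <- cos(L$orientation); si <- sin(L$orientation)
    dx <- outer(xs_cm - cx, rep(1, gs[2]))
    dy <- outer(rep(1, gs[1]), ys_cm - cy)
    u <- dx * co + dy * si
    v <- -dx * si + dy * co
    for (s in seq_along(slc)) {
      ab <- L$in_plane_semiaxes[[s]]
      m[, , slc[s]] <- (u / ab[1])^2 + (v / ab[2])^2 <= 1
    }
    les_masks[[li]] <- mk(m)
    tm <- lesion_truth_measurement(L, dz / 10)
    truth <- rbind(truth, data.frame(lesion = li,
                                     diameter_cm = tm$diameter_cm,
                                     volume_cc = tm$volume_cc))
  }

  # render channels
  set.seed(spec$seed)
  vols <- list()
  for (ch in c("dwi", "adc", "t2w")) {
    cc <- spec$channel_contrasts[[ch]]
    img <- cc[["background"]] * (1 - cov_pz - cov_tz) +
      cc[["pz"]] * cov_pz + cc[["tz"]] * cov_tz
    for (li in seq_along(spec$lesions)) {
      off <- spec$lesions[[li]]$channel_offsets[[ch]]
      sel <- les_masks[[li]]$labels > 0
      img[sel] <- img[sel] + off
    }
    if (spec$noise_sigma > 0) {
      if (spec$noise_model == "gaussian") {
        img <- img + array(stats::rnorm(prod(gs), 0, spec$noise_sigma), gs)
      } else {
        n1 <- array(stats::rnorm(prod(gs), 0, spec$noise_sigma), gs)
        n2 <- array(stats::rnorm(prod(gs), 0, spec$noise_sigma), gs)
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }
    vols[[ch]] <- volume3d(img, voxel_size = vx,
                           slice_thickness = spec$slice_thickness,
                           slice_gap = spec$slice_gap)
  }

  structure(list(volumes = vols, gland_truth = mk(gland),
                 pz_truth = mk(pz), tz_truth = mk(tz),
                 lesion_truth = les_masks, truth_measurements = truth,
                 spec = spec),
            class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("phantom_output: %s grid, %d lesion(s), noise sigma %.3g\n",
              paste(x$spec$grid_shape, collapse = "x"),
              length(x$lesion_truth), x$spec$noise_sigma))
  if (nrow(x$truth_measurements)) print(x$truth_measurements)
  invisible(x)
}

# Table of class-conditional size distributions (ellipse-fit measurements):
# per-score mean/SD of maximum diameter (cm) and volume (cc).
default_class_params <- function() {
  data.frame(score = c(2L, 3L, 4L, 5L),
             diameter_mean = c(0.47, 0.67, 0.96, 1.45),
             diameter_sd   = c(0.06, 0.11, 0.18, 0.15),
             volume_mean   = c(0.13, 0.29, 0.66, 0.99),
             volume_sd     = c(0.03, 0.12, 0.28, 0.25))
}

# truncated-at-zero normal sampling (sizes are positive)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a labelled lesion-size feature table
#'
#' Draws per-class (diameter, volume) pairs from truncated-at-zero normal
#' distributions. Default class parameters are the per-score ellipse-fit
#' means and SDs of the study cohort's measurement table.
#'
#' @param n_per_class named integer vector, rows per score (names are
#'   score labels, e.g. `c("2" = 16, ...)`), or a single count recycled
#'   over all classes in `class_params`.
#' @param class_params data.frame with columns `score`, `diameter_mean`,
#'   `diameter_sd`, `volume_mean`, `volume_sd`; SDs must be >= 0.
#' @param seed integer RNG seed.
#' @return data.frame with columns `diameter_cm`, `volume_cc` and `score`
#'   (factor).
#' @export
generate_feature_table <- function(n_per_class,
                                   class_params = default_class_params(),
                                   seed = 1L) {
  stopifnot(all(class_params$diameter_sd >= 0),
            all(class_params$volume_sd >= 0))
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, nrow(class_params)),
                                   class_params$score)
  if (any(n_per_class < 1)) stop("counts must be >= 1")
  unknown <- setdiff(names(n_per_class), as.character(class_params$score))
  if (length(unknown))
    stop("unknown score label(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  out <- do.call(rbind, lapply(names(n_per_class), function(s) {
    p <- class_params[class_params$score == as.integer(s), ]
    n <- n_per_class[[s]]
    data.frame(diameter_cm = rtnorm0(n, p$diameter_mean, p$diameter_sd),
               volume_cc = rtnorm0(n, p$volume_mean, p$volume_sd),
               score = s)
  }))
  out$score <- factor(out$score, levels = sort(unique(names(n_per_class))))
  rownames(out) <- NULL
  out
}
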