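#' 3D scalar volume with acquisition geometry
#'
#' A `volume3d` wraps a 3D numeric array together with the voxel geometry
#' needed downstream: in-plane voxel size, slice thickness and slice gap.
#' The third array axis is always the slice (through-plane) axis. The
#' through-plane grid spacing is `slice_thickness + slice_gap` (the slice
#' profile), so voxel grids and the slice-profile volume formula agree.
#'
#' @param data numeric 3D array (x, y, slice).
#' @param voxel_size length-2 or length-3 numeric, mm. If length 2, the
#'   through-plane spacing is taken as `slice_thickness + slice_gap`.
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size = c(0.49, 0.49),
                     slice_thickness = 3, slice_gap = 3) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("`data` must be finite")
  if (slice_thickness <= 0) stop("`slice_thickness` must be > 0")
  if (slice_gap < 0) stop("`slice_gap` must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 2L)
    voxel_size <- c(voxel_size, slice_thickness + slice_gap)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 2 or 3 positive numbers (mm)")
  structure(list(data = data, voxel_size = voxel_size,
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "volume3d")
}

#' Label mask on a volume grid
#'
#' A `mask3d` is an integer label array sharing a `volume3d` grid, with an
#' optional label dictionary (e.g. gland / PZ / TZ / lesion-k).
#'
#' @param labels integer-valued 3D array, labels >= 0 (0 = background).
#' @param voxel_size,slice_thickness,slice_gap grid geometry as in
#'   [volume3d()].
#' @param label_names optional named integer vector mapping names to labels.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(labels, voxel_size = c(0.49, 0.49),
                   slice_thickness = 3, slice_gap = 3, label_names = NULL) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers")
  v <- volume3d(labels + 0, voxel_size, slice_thickness, slice_gap)
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 voxel_size = v$voxel_size,
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 label_names = label_names),
            class = "mask3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels, %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  slice thickness %.1f mm, gap %.1f mm; intensity range [%.3g, %.3g]\n",
              x$slice_thickness, x$slice_gap, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$labels)
  tb <- table(x$labels[x$labels > 0])
  cat(sprintf("mask3d: %d x %d x %d voxels, %d foreground (%s labels)\n",
              d[1], d[2], d[3], sum(x$labels > 0),
              length(tb)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
dim.mask3d <- function(x) dim(x$labels)

same_grid <- function(a, b) {
  da <- if (inherits(a, "mask3d")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "mask3d")) dim(b$labels) else dim(b$data)
  identical(da, db)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume3d()]. Voxel sizes come from
#' the NIfTI header (`pixdim`); slice thickness and gap are not stored in
#' NIfTI and must be supplied (defaults match a 3 mm thickness / 3 mm gap
#' acquisition whose through-plane spacing is 6 mm).
#'
#' @param path file path to a NIfTI volume.
#' @param slice_thickness,slice_gap through-plane geometry in mm; their sum
#'   must equal the header's third pixdim (checked when both are finite).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, slice_thickness = 3, slice_gap = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D volume: ", path)
  a <- array(as.numeric(a), dim(a))   # drop NIfTI header attributes
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("no usable voxel-size metadata in ", path,
         "; supply explicit voxel_size via volume3d()")
  if (abs(pd[3] - (slice_thickness + slice_gap)) > 1e-4)
    warning("through-plane pixdim (", pd[3], " mm) != slice_thickness + ",
            "slice_gap (", slice_thickness + slice_gap, " mm)")
  volume3d(a, voxel_size = pd[1:3], slice_thickness = slice_thickness,
           slice_gap = slice_gap)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a [volume3d()] or [mask3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  a <- if (inherits(vol, "mask3d")) vol$labels else vol$data
  img <- RNifti::asNifti(a)
  img <- RNifti::`pixdim<-`(img, vol$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask from NIfTI
#'
#' @inheritParams read_volume
#' @return A [mask3d()].
#' @export
read_mask <- function(path, slice_thickness = 3, slice_gap = 3) {
  v <- read_volume(path, slice_thickness, slice_gap)
  mask3d(array(as.integer(round(v$data)), dim(v$data)),
         voxel_size = v$voxel_size, slice_thickness = slice_thickness,
         slice_gap = slice_gap)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b `mask3d` objects or logical/integer arrays; nonzero =
#'   foreground.
#' @return Dice coefficient 2|A∩B| / (|A| + |B|) in `[0, 1]`.
#' @export
dice <- function(a, b) {
  A <- if (inherits(a, "mask3d")) a$labels > 0 else a > 0
  B <- if (inherits(b, "mask3d")) b$labels > 0 else b > 0
  if (!identical(dim(A), dim(B))) stop("masks are on different grids")
  2 * sum(A & B) / (sum(A) + sum(B))
}
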