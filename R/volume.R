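#' Scalar volume on an image grid
#'
#' The basic voxelized container: a CT surrogate (HU-like), a PET uptake image
#' (arbitrary units) or a dose distribution (Gy). Dose volumes must be
#' non-negative; pass `kind = "dose"` to enforce this.
#'
#' @param values 3D numeric array.
#' @param grid an [image_grid] with `dims == dim(values)`.
#' @param kind one of `"generic"`, `"ct"`, `"pet"`, `"dose"`.
#' @return An object of class `scalar_volume` (fields `values`, `grid`,
#'   `kind`).
#' @export
scalar_volume <- function(values, grid, kind = c("generic", "ct", "pet", "dose")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (!all(dim(values) == grid$dims)) {
    stop("values array shape does not match grid dims")
  }
  if (kind == "dose" && any(values < 0)) {
    stop("dose volumes must be non-negative")
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume (%s): %s, range [%.4g, %.4g]\n", x$kind,
              format(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask on an image grid
#'
#' Structure sets follow head-and-neck usage: gross tumor volumes (`GTV_T`,
#' `GTV_N*`), clinical/planning target volumes (`CTV_HR`, `PTV_HR`, `CTV_EN`,
#' `PTV_EN`), organs at risk and their planning volumes (`PRV_*`).
#'
#' @param name structure label.
#' @param mask 3D logical array.
#' @param grid an [image_grid] with `dims == dim(mask)`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, grid) {
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!all(dim(mask) == grid$dims)) {
    stop("mask array shape does not match grid dims")
  }
  structure(list(name = as.character(name), mask = mask, grid = grid),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels (%.2f cm^3) on %s\n", x$name,
              sum(x$mask), mask_volume_cm3(x), format(x$grid)))
  invisible(x)
}

#' Structure volume in cm^3
#' @param structure a [structure_mask].
#' @return volume of the structure in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(structure) {
  sum(structure$mask) * voxel_volume_cm3(structure$grid)
}

#' Deformation vector field on a reference grid
#'
#' Displacements are stored *pull-back* style: the vector at a reference voxel
#' points from that voxel center to the corresponding location in the phase
#' image, which is the direction needed to warp phase dose onto the reference
#' (pretreatment) grid.
#'
#' @param displacement 4D numeric array `c(grid$dims, 3)` of mm displacement
#'   components.
#' @param grid the reference [image_grid].
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacement, grid) {
  displacement <- as.array(displacement)
  if (length(dim(displacement)) != 4L || dim(displacement)[4] != 3L ||
      !all(dim(displacement)[1:3] == grid$dims)) {
    stop("displacement must be an array of shape c(grid$dims, 3)")
  }
  if (!all(is.finite(displacement))) stop("displacements must be finite")
  structure(list(displacement = displacement, grid = grid),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$displacement[, , , 1]^2 + x$displacement[, , , 2]^2 +
                x$displacement[, , , 3]^2)
  cat(sprintf("deformation_field on %s, |u| max %.2f mm, mean %.2f mm\n",
              format(x$grid), max(mag), mean(mag)))
  invisible(x)
}

## ---- NIfTI round-trip -------------------------------------------------

grid_from_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  dims <- dim(img)[1:3]
  spacing <- hdr$pixdim[2:4]
  # we store volumes with a plain translation-only xform; the origin is the
  # world position of the first voxel center
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # RNifti xforms are RAS with possible sign flips; volumes written by this
  # package use a positive diagonal, so recover origin from the affine action
  # on index (0,0,0) and spacing from the column norms
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (all(sp > 0)) spacing <- sp
  image_grid(dims, spacing, origin)
}

#' Write a scalar volume or mask to NIfTI
#'
#' Grid spacing and origin are stored in the NIfTI header (translation-only
#' affine, voxel-center origin). Masks are written as 0/1 volumes.
#'
#' @param x a [scalar_volume], [structure_mask] or [deformation_field].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "structure_mask")) {
    arr <- array(as.numeric(x$mask), dim = x$grid$dims)
    grid <- x$grid
  } else if (inherits(x, "deformation_field")) {
    arr <- x$displacement
    grid <- x$grid
  } else {
    arr <- x$values
    grid <- x$grid
  }
  img <- RNifti::asNifti(arr)
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::pixdim(img) <- grid$spacing
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar volume from NIfTI
#'
#' @param path NIfTI file written by [write_volume()] (or any axis-aligned
#'   NIfTI with a translation-only affine).
#' @param kind passed to [scalar_volume()].
#' @return a [scalar_volume] (3D input), or a [deformation_field] when the
#'   file holds a 4D 3-component field.
#' @export
read_volume <- function(path, kind = "generic") {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 3L) {
    return(deformation_field(arr, grid))
  }
  scalar_volume(arr, grid, kind = kind)
}

#' Read a 0/1 NIfTI volume as a structure mask
#'
#' @param path NIfTI file path.
#' @param name structure label to attach.
#' @return a [structure_mask].
#' @export
read_mask <- function(path, name) {
  v <- read_volume(path)
  structure_mask(name, v$values > 0.5, v$grid)
}

## ---- small helpers used across modules --------------------------------

get_structure <- function(structures, name) {
  for (s in structures) if (s$name == name) return(s)
  NULL
}

structure_names <- function(structures) {
  vapply(structures, function(s) s$name, character(1))
}
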