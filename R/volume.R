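#' 3D image volume
#'
#' Lightweight carrier for a 3D scalar lattice plus the two pieces of
#' metadata the asymmetry pipeline needs: the voxel spacing in millimetres
#' and a flag stating that the lattice x-midplane is the midsagittal plane
#' (so a left-right flip is meaningful).
#'
#' @param values 3D numeric array.
#' @param voxel_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param symmetric_space logical; `TRUE` means the volume is aligned in a
#'   left-right symmetric space with the midsagittal plane at the x-midplane
#'   (between columns `Nx/2` and `Nx/2 + 1` in 1-based indexing).
#' @return An object of class `pnms_volume`.
#' @export
volume <- function(values, voxel_mm = c(2, 2, 2), symmetric_space = TRUE) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("volume requires a 3D array")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel_mm must be 3 positive numbers")
  structure(
    list(values = values, voxel_mm = voxel_mm,
         symmetric_space = isTRUE(symmetric_space)),
    class = "pnms_volume"
  )
}

#' @export
dim.pnms_volume <- function(x) dim(x$values)

#' @export
print.pnms_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pnms_volume %dx%dx%d, voxel %s mm, symmetric_space=%s>\n",
              d[1], d[2], d[3], paste(format(x$voxel_mm), collapse = "x"),
              x$symmetric_space))
  invisible(x)
}

#' @export
as.array.pnms_volume <- function(x, ...) x$values

is_volume <- function(x) inherits(x, "pnms_volume")

# shared-lattice check used by every voxelwise combination of volumes
check_same_lattice <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("volumes differ in grid shape")
  if (max(abs(a$voxel_mm - b$voxel_mm)) > 1e-9)
    stop("volumes differ in voxel size")
  invisible(TRUE)
}

# rebuild a volume with new values, keeping metadata
with_values <- function(vol, values) {
  volume(array(values, dim(vol$values)), vol$voxel_mm, vol$symmetric_space)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param symmetric_space logical flag to attach (the file format cannot
#'   carry it); default `TRUE`.
#' @return A [volume()].
#' @export
read_volume <- function(path, symmetric_space = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  volume(arr, vox, symmetric_space)
}

#' Write a volume as NIfTI-1
#'
#' Values are stored as float32; voxel sizes go to the header.
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Flip a volume across the midsagittal plane
#'
#' Voxel `(i, j, k)` maps to `(Nx + 1 - i, j, k)` (1-based), i.e. the image
#' is mirrored about the lattice x-midplane. The operation is an involution.
#'
#' @param vol a [volume()] with `symmetric_space = TRUE`.
#' @return The flipped [volume()].
#' @export
midsagittal_flip <- function(vol) {
  stopifnot(is_volume(vol))
  if (!vol$symmetric_space) stop("volume not in symmetric space")
  nx <- dim(vol$values)[1]
  with_values(vol, vol$values[nx:1, , , drop = FALSE])
}

#' Hemisphere masks in a symmetric-space lattice
#'
#' Left hemisphere = x indices `1..Nx/2`, right = `Nx/2+1..Nx`; requires an
#' even x dimension so the midplane falls between voxels.
#'
#' @param vol a [volume()] (only the grid is used).
#' @param side `"left"` or `"right"`.
#' @return A logical 3D array.
#' @export
hemisphere_mask <- function(vol, side = c("left", "right")) {
  side <- match.arg(side)
  d <- dim(vol$values)
  if (d[1] %% 2L != 0L) stop("asymmetric grid")
  m <- array(FALSE, d)
  if (side == "left") m[seq_len(d[1] / 2L), , ] <- TRUE
  else m[(d[1] / 2L + 1L):d[1], , ] <- TRUE
  m
}
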