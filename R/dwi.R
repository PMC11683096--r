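#' Construct a diffusion-weighted imaging volume
#'
#' Bundles a 4-D signal array with its gradient table and voxel geometry.
#' b-values below `b0_threshold` (default 50 s/mm^2) are treated as b = 0;
#' non-b0 gradient vectors must be unit length within `1e-3` and are
#' renormalised exactly.
#'
#' @param signal 4-D numeric array, dimensions x, y, z, gradient.
#' @param bvals numeric vector of b-values (s/mm^2), one per gradient.
#' @param bvecs 3-row (or 3-column) numeric matrix of gradient directions.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param affine 4x4 voxel-to-world transform (RAS+); default scaled identity.
#' @param b0_threshold b-values at or below this are treated as b = 0.
#'
#' @return An object of class `dwi_volume`: a list with elements `signal`,
#'   `bvals`, `bvecs` (3 x n, unit columns for non-b0), `voxel_size_mm`,
#'   `affine`.
#' @export
dwi_volume <- function(signal, bvals, bvecs, voxel_size_mm = 2,
                       affine = NULL, b0_threshold = 50) {
  signal <- unclass(signal)
  assert_that(length(dim(signal)) == 4L,
              "signal must be a 4-D array (x, y, z, gradient)")
  n <- dim(signal)[4]
  assert_that(length(bvals) == n, sprintf(
    "gradient count mismatch: %d b-values but %d volumes", length(bvals), n))
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  assert_that(nrow(bvecs) == 3 && ncol(bvecs) == n, sprintf(
    "gradient count mismatch: bvecs has %d columns but %d volumes",
    ncol(bvecs), n))
  assert_that(all(is.finite(signal)), "non-finite values in signal")
  assert_that(all(is.finite(bvals)) && all(is.finite(bvecs)),
              "non-finite values in gradient table")
  assert_that(min(signal) >= 0, "signal must be non-negative")

  bvals <- as.numeric(bvals)
  bvals[bvals <= b0_threshold] <- 0
  assert_that(any(bvals == 0), "at least one b=0 volume is required")

  nz <- which(bvals > 0)
  nrm <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  bad <- which(abs(nrm - 1) > 1e-3)
  if (length(bad)) {
    stop_glue("non-unit b-vectors beyond tolerance at gradient index(es) ",
              paste(nz[bad], collapse = ", "))
  }
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm, "/")

  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
  }
  structure(
    list(signal = signal, bvals = bvals, bvecs = bvecs,
         voxel_size_mm = voxel_size_mm, affine = affine),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d gradients (%d b=0), voxel %g mm\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0), x$voxel_size_mm))
  invisible(x)
}

#' Read a DWI volume from NIfTI plus FSL-style gradient files
#'
#' @param path_nifti path to a 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param path_bvals path to a whitespace-separated b-value text file.
#' @param path_bvecs path to a 3-row whitespace-separated b-vector file.
#' @param ... passed to [dwi_volume()] (e.g. `b0_threshold`).
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(path_nifti, path_bvals, path_bvecs, ...) {
  for (p in c(path_nifti, path_bvals, path_bvecs)) {
    assert_that(file.exists(p), paste0("file not found: ", p))
  }
  img <- RNifti::readNifti(path_nifti)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bvals <- scan(path_bvals, quiet = TRUE)
  bvecs <- as.matrix(read.table(path_bvecs))
  vox <- RNifti::pixdim(img)[1]
  aff <- tryCatch(structure(RNifti::xform(img), class = NULL),
                  error = function(e) NULL)
  dwi_volume(arr, bvals, bvecs, voxel_size_mm = vox, affine = aff, ...)
}

#' Write a DWI volume as NIfTI plus FSL-style gradient files
#'
#' @param dwi a [dwi_volume()].
#' @param path_nifti,path_bvals,path_bvecs output paths.
#' @return `path_nifti`, invisibly.
#' @export
write_dwi <- function(dwi, path_nifti, path_bvals, path_bvecs) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(rep(dwi$voxel_size_mm, 3), 1)
  RNifti::writeNifti(img, path_nifti)
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), path_bvals)
  write.table(format(dwi$bvecs, digits = 17), path_bvecs,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path_nifti)
}

#' Write a 3-D map as NIfTI-1, preserving voxel size
#' @param map 3-D numeric array.
#' @param path output path.
#' @param voxel_size_mm isotropic voxel size.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- rep(voxel_size_mm, length(dim(map)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @importFrom utils read.table write.table
NULL
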