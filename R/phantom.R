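#' Specification for a synthetic periventricular diffusion phantom
#'
#' The phantom emulates the anatomy the ALPS method relies on at the level
#' of the lateral-ventricle body: projection fibres running
#' superior-inferior (z), association fibres running anterior-posterior (y),
#' and perivascular water movement along the left-right (x) medullary-vein
#' axis. On one mid-axial slice, two bilateral "projection" slabs carry a
#' diagonal tensor (d_pv * glymphatic_factor, d_perp, d_parallel) and two
#' "association" slabs lateral to them carry
#' (d_pv * glymphatic_factor, d_parallel, d_perp); everywhere else diffusion
#' is isotropic. `glymphatic_factor` scales the perivascular (x) diffusivity
#' only, so the ground-truth ALPS index is
#' `glymphatic_factor * d_pv / d_perp`, strictly increasing in the factor.
#'
#' @param grid_shape integer vector of 3 voxel counts (default 40 x 40 x 20).
#' @param voxel_size_mm isotropic voxel edge, mm (default 2).
#' @param d_parallel axial diffusivity of fibre bundles, mm^2/s.
#' @param d_perp radial diffusivity of fibre bundles, mm^2/s.
#' @param d_pv perivascular (x-axis) diffusivity inside the slabs, mm^2/s.
#' @param glymphatic_factor scalar in (0, 1] multiplying `d_pv`; 1 = healthy.
#' @param snr signal-to-noise ratio at b = 0; `Inf` = noiseless.
#' @param bvals b-shell values, s/mm^2 (default c(0, 1000)).
#' @param n_directions number of diffusion gradient directions (default 32).
#' @param seed RNG seed used when noise is added.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 20L),
                         voxel_size_mm = 2,
                         d_parallel = 1.4e-3,
                         d_perp = 0.5e-3,
                         d_pv = 1.1e-3,
                         glymphatic_factor = 1,
                         snr = Inf,
                         bvals = c(0, 1000),
                         n_directions = 32L,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               d_parallel = d_parallel, d_perp = d_perp, d_pv = d_pv,
               glymphatic_factor = glymphatic_factor, snr = snr,
               bvals = bvals, n_directions = as.integer(n_directions),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    assert_that(length(grid_shape) == 3 && all(grid_shape >= 8),
                "grid_shape must be 3 dimensions of at least 8 voxels")
    assert_that(d_parallel >= d_perp && d_perp > 0,
                "need d_parallel >= d_perp > 0")
    assert_that(d_pv > 0, "d_pv must be positive")
    assert_that(glymphatic_factor > 0 && glymphatic_factor <= 1,
                "glymphatic_factor must lie in (0, 1]")
    assert_that(max(d_parallel, d_perp, d_pv) < 3.5e-3,
                "diffusivities must stay below the free-water bound 3.5e-3 mm^2/s")
    assert_that(snr > 0, "snr must be positive")
    assert_that(any(bvals == 0), "bvals must include 0")
    assert_that(n_directions >= 6,
                "at least 6 gradient directions are required for a tensor fit")
  })
  invisible(spec)
}

# slab geometry on the mid-axial slice: bilateral projection slabs flanking
# the midline, association slabs lateral to them; each extends over a few
# slices in z so the fitted tensors at the ALPS slice are interior voxels
phantom_geometry <- function(spec) {
  g <- spec$grid_shape
  cx <- ceiling(g[1] / 2); cy <- ceiling(g[2] / 2); cz <- ceiling(g[3] / 2)
  half_y <- 3L; half_z <- 1L
  yr <- (cy - half_y):(cy + half_y)
  zr <- (cz - half_z):(cz + half_z)
  proj_off <- 4L; assoc_off <- 9L; half_x <- 1L
  slab <- function(xc) list(x = (xc - half_x):(xc + half_x), y = yr, z = zr)
  list(
    slice_index = cz,
    proj_left   = slab(cx - proj_off),
    proj_right  = slab(cx + proj_off),
    assoc_left  = slab(cx - assoc_off),
    assoc_right = slab(cx + assoc_off),
    seeds = list(
      proj_left   = c(cx - proj_off,  cy, cz),
      proj_right  = c(cx + proj_off,  cy, cz),
      assoc_left  = c(cx - assoc_off, cy, cz),
      assoc_right = c(cx + assoc_off, cy, cz)
    )
  )
}

slab_mask <- function(grid_shape, slab) {
  m <- array(FALSE, grid_shape)
  m[slab$x, slab$y, slab$z] <- TRUE
  m
}

#' Generate a synthetic diffusion phantom with known ALPS ground truth
#'
#' Synthesises the diffusion signal voxelwise as
#' `S(g, b) = S0 * exp(-b * g' D g)` from the phantom's piecewise-constant
#' tensor field, optionally corrupted by Rician noise calibrated to the
#' b = 0 signal. Gradient directions come from a deterministic Fibonacci
#' sphere scheme.
#'
#' @param spec a [phantom_spec()].
#' @param s0 b = 0 signal intensity (arbitrary units).
#' @return A list with elements
#'   \describe{
#'     \item{dwi}{a [dwi_volume()] with the synthesised signal,}
#'     \item{ground_truth}{a list carrying the exact diagonal tensor field
#'       (`d_x`, `d_y`, `d_z` arrays), logical slab `masks`, per-ROI `seeds`
#'       voxel coordinates, `slice_index`, and `alps` — the closed-form
#'       ALPS index implied by the slab diffusivities.}
#'   }
#' @export
make_phantom <- function(spec = phantom_spec(), s0 = 1000) {
  validate_phantom_spec(spec)
  g <- spec$grid_shape
  geom <- phantom_geometry(spec)
  iso <- 0.7e-3
  d_x <- array(iso, g); d_y <- array(iso, g); d_z <- array(iso, g)
  dx_slab <- spec$d_pv * spec$glymphatic_factor

  masks <- list(
    proj_left   = slab_mask(g, geom$proj_left),
    proj_right  = slab_mask(g, geom$proj_right),
    assoc_left  = slab_mask(g, geom$assoc_left),
    assoc_right = slab_mask(g, geom$assoc_right)
  )
  proj <- masks$proj_left | masks$proj_right
  assoc <- masks$assoc_left | masks$assoc_right
  d_x[proj] <- dx_slab; d_y[proj] <- spec$d_perp;    d_z[proj] <- spec$d_parallel
  d_x[assoc] <- dx_slab; d_y[assoc] <- spec$d_parallel; d_z[assoc] <- spec$d_perp

  dirs <- fibonacci_sphere(spec$n_directions)        # n x 3, unit rows
  shells <- spec$bvals[spec$bvals > 0]
  bvals <- c(0, rep(shells, each = spec$n_directions))
  bvecs <- cbind(c(0, 0, 0),
                 t(dirs[rep(seq_len(spec$n_directions), length(shells)), ,
                        drop = FALSE]))

  nvox <- prod(g)
  D <- cbind(as.vector(d_x), as.vector(d_y), as.vector(d_z))  # nvox x 3
  # diagonal tensors: g' D g = sum_k d_k g_k^2
  gsq <- bvecs^2                                      # 3 x ngrad
  att <- exp(-(D %*% gsq) * rep(bvals, each = nvox))  # nvox x ngrad
  signal <- array(s0 * att, dim = c(g, length(bvals)))

  if (is.finite(spec$snr)) {
    set.seed(spec$seed)
    sigma <- s0 / spec$snr
    n1 <- array(rnorm(length(signal), 0, sigma), dim = dim(signal))
    n2 <- array(rnorm(length(signal), 0, sigma), dim = dim(signal))
    signal <- sqrt((signal + n1)^2 + n2^2)
  }

  gt_alps <- mean(c(dx_slab, dx_slab)) / mean(c(spec$d_perp, spec$d_perp))
  list(
    dwi = dwi_volume(signal, bvals, bvecs,
                     voxel_size_mm = spec$voxel_size_mm),
    ground_truth = list(
      d_x = d_x, d_y = d_y, d_z = d_z,
      masks = masks, seeds = geom$seeds,
      slice_index = geom$slice_index,
      alps = gt_alps,
      spec = spec
    )
  )
}

#' Write a phantom to disk (NIfTI + bvals/bvecs + JSON ground truth)
#'
#' @param phantom result of [make_phantom()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dwi(phantom$dwi,
            file.path(dir, "dwi.nii.gz"),
            file.path(dir, "bvals"),
            file.path(dir, "bvecs"))
  gt <- phantom$ground_truth
  side <- list(
    alps = gt$alps,
    slice_index = gt$slice_index,
    seeds = gt$seeds,
    spec = unclass(gt$spec)
  )
  jsonlite::write_json(side, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
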