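#' Place the four periventricular ALPS ROIs by colour-channel peak search
#'
#' Starting from seed voxel coordinates on one axial slice, each projection
#' ROI centre moves to the voxel maximising the blue channel (z-dominant
#' projection fibres) within an in-plane search disc, and each association
#' ROI centre to the green-channel (y-dominant association fibres) maximum.
#' Ties are broken by smallest Euclidean distance to the seed, then by
#' lexicographic voxel order. If the search disc is empty or the channel is
#' identically zero inside it, the centre falls back to the seed with a
#' warning. ROI membership is all voxels on the slice whose centre lies
#' within `radius_mm` of the adjusted centre.
#'
#' @param cfa a `color_fa` object from [color_fa()].
#' @param seeds named list of integer voxel coordinates `c(x, y, z)` (1-based)
#'   with names `proj_left`, `proj_right`, `assoc_left`, `assoc_right`; all
#'   must share the same z (axial slice).
#' @param search_radius_mm in-plane peak-search radius (default 10).
#' @param radius_mm ROI radius (default 3, the standard ALPS ROI size).
#' @return An `alps_roi_set`: per-ROI adjusted `center`, `members`
#'   (n x 3 voxel matrix), plus `slice_index`, `radius_mm`.
#' @export
place_rois <- function(cfa, seeds, search_radius_mm = 10, radius_mm = 3) {
  stopifnot(inherits(cfa, "color_fa"))
  need <- c("proj_left", "proj_right", "assoc_left", "assoc_right")
  assert_that(all(need %in% names(seeds)),
              paste("seeds must be named:", paste(need, collapse = ", ")))
  assert_that(search_radius_mm >= 0, "search_radius_mm must be >= 0")
  assert_that(radius_mm > 0, "radius_mm must be positive")
  zs <- vapply(seeds[need], `[`, numeric(1), 3)
  assert_that(length(unique(zs)) == 1, "all seeds must lie on one axial slice")
  slice <- as.integer(zs[1])
  dm <- dim(cfa$red)
  assert_that(slice >= 1 && slice <= dm[3], "seed slice outside image")
  vox <- cfa$voxel_size_mm

  channel_for <- function(name) {
    if (grepl("^proj", name)) cfa$blue[, , slice] else cfa$green[, , slice]
  }

  adjust_center <- function(seed, chan) {
    r_vox <- search_radius_mm / vox
    xr <- max(1, ceiling(seed[1] - r_vox)):min(dm[1], floor(seed[1] + r_vox))
    yr <- max(1, ceiling(seed[2] - r_vox)):min(dm[2], floor(seed[2] + r_vox))
    cand <- expand.grid(x = xr, y = yr)              # lexicographic in (y, x)
    cand <- cand[order(cand$x, cand$y), ]
    d2 <- (cand$x - seed[1])^2 + (cand$y - seed[2])^2
    keep <- d2 <= r_vox^2 + 1e-9
    cand <- cand[keep, ]; d2 <- d2[keep]
    vals <- chan[cbind(cand$x, cand$y)]
    vals[is.na(vals)] <- -Inf
    if (!nrow(cand) || all(vals <= 0)) {
      warning("peak search found no positive channel value; using seed")
      return(c(seed[1], seed[2]))
    }
    best <- vals == max(vals)
    pick <- which(best)[order(d2[best])][1]          # nearest tie first,
    c(cand$x[pick], cand$y[pick])                    # then lexicographic
  }

  disc_members <- function(center) {
    r_vox <- radius_mm / vox
    xr <- max(1, ceiling(center[1] - r_vox)):min(dm[1], floor(center[1] + r_vox))
    yr <- max(1, ceiling(center[2] - r_vox)):min(dm[2], floor(center[2] + r_vox))
    cand <- expand.grid(x = xr, y = yr)
    keep <- (cand$x - center[1])^2 + (cand$y - center[2])^2 <= r_vox^2 + 1e-9
    cbind(x = cand$x[keep], y = cand$y[keep], z = slice)
  }

  rois <- lapply(need, function(nm) {
    ctr <- adjust_center(seeds[[nm]], channel_for(nm))
    list(center = c(ctr, slice), members = disc_members(ctr))
  })
  names(rois) <- need

  # projection/association ROIs must not overlap within a hemisphere
  for (side in c("left", "right")) {
    a <- rois[[paste0("proj_", side)]]$members
    b <- rois[[paste0("assoc_", side)]]$members
    overlap <- intersect(paste(a[, 1], a[, 2]), paste(b[, 1], b[, 2]))
    if (length(overlap)) {
      warning(sprintf("projection and association ROIs overlap (%s side)",
                      side))
    }
  }

  structure(list(rois = rois, slice_index = slice, radius_mm = radius_mm,
                 search_radius_mm = search_radius_mm),
            class = "alps_roi_set")
}

#' @export
print.alps_roi_set <- function(x, ...) {
  cat(sprintf("<alps_roi_set> slice %d, radius %g mm\n",
              x$slice_index, x$radius_mm))
  for (nm in names(x$rois)) {
    r <- x$rois[[nm]]
    cat(sprintf("  %-12s center (%d, %d), %d voxels\n", nm,
                r$center[1], r$center[2], nrow(r$members)))
  }
  invisible(x)
}

roi_mean_diag <- function(field, members, axis) {
  # axis 1 = Dxx, 2 = Dyy, 3 = Dzz (tensor diagonal in subject axes)
  vals <- field$tensor[cbind(members[, 1], members[, 2], members[, 3], axis)]
  fitted <- field$mask[cbind(members[, 1], members[, 2], members[, 3])]
  if (!any(fitted)) return(NA_real_)
  mean(vals[fitted])
}

#' Compute the ALPS index from a fitted tensor field and ROI set
#'
#' For each hemisphere the six directional diffusivities are the ROI means
#' of the tensor diagonal elements (Dxx, Dyy, Dzz), and
#' `alps = mean(Dx_assoc, Dx_proj) / mean(Dz_assoc, Dy_proj)`.
#' The reported index follows the clinical convention: the left/right mean
#' when `lesion_side = "none"` (controls), otherwise the lesion-side index.
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @param rois an `alps_roi_set` from [place_rois()].
#' @param lesion_side "left", "right" or "none".
#' @return An `alps_result`: tibble of per-hemisphere diffusivities plus
#'   attributes, with fields `alps_left`, `alps_right`, `alps_mean`,
#'   `alps_reported`, `lesion_side`.
#' @export
compute_alps <- function(field, rois, lesion_side = c("none", "left", "right")) {
  stopifnot(inherits(field, "tensor_field"), inherits(rois, "alps_roi_set"))
  lesion_side <- match.arg(lesion_side)

  side_vals <- function(side) {
    p <- rois$rois[[paste0("proj_", side)]]$members
    a <- rois$rois[[paste0("assoc_", side)]]$members
    v <- c(
      Dxproj = roi_mean_diag(field, p, 1),
      Dyproj = roi_mean_diag(field, p, 2),
      Dzproj = roi_mean_diag(field, p, 3),
      Dxassoc = roi_mean_diag(field, a, 1),
      Dyassoc = roi_mean_diag(field, a, 2),
      Dzassoc = roi_mean_diag(field, a, 3)
    )
    if (anyNA(v)) {
      stop_glue("ROI with zero fitted voxels on the ", side, " side")
    }
    v
  }
  L <- side_vals("left"); R <- side_vals("right")
  alps_one <- function(v) {
    num <- mean(c(v["Dxassoc"], v["Dxproj"]))
    den <- mean(c(v["Dzassoc"], v["Dyproj"]))
    if (den <= 0) stop_glue("non-physical fit: ALPS denominator <= 0")
    unname(num / den)
  }
  alps_left <- alps_one(L); alps_right <- alps_one(R)
  alps_mean <- (alps_left + alps_right) / 2
  alps_reported <- switch(lesion_side,
                          none = alps_mean,
                          left = alps_left,
                          right = alps_right)

  out <- tibble::tibble(
    hemisphere = c("left", "right"),
    Dxproj = c(L["Dxproj"], R["Dxproj"]),
    Dyproj = c(L["Dyproj"], R["Dyproj"]),
    Dzproj = c(L["Dzproj"], R["Dzproj"]),
    Dxassoc = c(L["Dxassoc"], R["Dxassoc"]),
    Dyassoc = c(L["Dyassoc"], R["Dyassoc"]),
    Dzassoc = c(L["Dzassoc"], R["Dzassoc"]),
    alps = c(alps_left, alps_right)
  )
  structure(list(
    diffusivities = out,
    alps_left = alps_left, alps_right = alps_right,
    alps_mean = alps_mean, alps_reported = alps_reported,
    lesion_side = lesion_side
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf(
    "<alps_result> left %.4f, right %.4f, mean %.4f, reported %.4f (%s)\n",
    x$alps_left, x$alps_right, x$alps_mean, x$alps_reported, x$lesion_side))
  invisible(x)
}

#' Run fit -> ROI placement -> ALPS on a DWI volume
#'
#' Convenience wrapper chaining [fit_tensor()], [color_fa()],
#' [place_rois()] and [compute_alps()].
#'
#' @inheritParams fit_tensor
#' @inheritParams place_rois
#' @inheritParams compute_alps
#' @return An `alps_result`.
#' @export
alps_pipeline <- function(dwi, seeds, lesion_side = "none",
                          method = "wls", search_radius_mm = 10,
                          radius_mm = 3) {
  field <- fit_tensor(dwi, method = method)
  cfa <- color_fa(field)
  rois <- place_rois(cfa, seeds, search_radius_mm = search_radius_mm,
                     radius_mm = radius_mm)
  compute_alps(field, rois, lesion_side = lesion_side)
}
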