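#' Fit the diffusion tensor voxelwise
#'
#' Log-linear least-squares estimation of the symmetric diffusion tensor
#' from a multi-directional DWI acquisition: for each voxel,
#' `ln(S/S0) = -b g' D g` is solved for the six unique tensor elements.
#' `method = "wls"` (default) performs the standard two-pass weighted fit
#' with weights equal to the squared signals predicted by the first-pass
#' OLS solution; `method = "ols"` stops after the first pass.
#'
#' S0 is estimated as the mean of all b = 0 volumes. Voxels with S0 <= 0
#' (or any non-positive diffusion-weighted signal) are masked out.
#' Negative eigenvalues are clamped to zero; the affected voxel count is
#' reported via a warning and stored in the result.
#'
#' @param dwi a [dwi_volume()].
#' @param method "wls" (two-pass weighted) or "ols".
#' @param mask_threshold S0 values at or below this are excluded from the
#'   fit (0 suits noiseless phantoms; raise it for real data).
#' @return A `tensor_field` object: list with
#'   \describe{
#'     \item{tensor}{4-D array (x, y, z, 6) of unique elements in order
#'       Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s);}
#'     \item{eigenvalues}{4-D array (x, y, z, 3), descending, clamped >= 0;}
#'     \item{principal_direction}{4-D array (x, y, z, 3), unit vectors;}
#'     \item{fa}{3-D fractional anisotropy map in \[0, 1\];}
#'     \item{mask}{3-D logical array of fitted voxels;}
#'     \item{n_clamped}{number of voxels with clamped negative eigenvalues.}
#'   }
#' @export
fit_tensor <- function(dwi, method = c("wls", "ols"), mask_threshold = 0) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  g <- dim(dwi$signal)[1:3]
  nvox <- prod(g)
  b0_idx <- which(dwi$bvals == 0)
  dw_idx <- which(dwi$bvals > 0)

  dirs <- t(dwi$bvecs[, dw_idx, drop = FALSE])   # ndw x 3
  ud <- unique(round(dirs, 6))
  ud <- rbind(ud, -ud)
  assert_that(nrow(unique(ud)) / 2 >= 6,
              "at least 6 unique non-b0 gradient directions are required")

  b <- dwi$bvals[dw_idx]
  # design for the 6 unique elements: Dxx Dyy Dzz Dxy Dxz Dyz
  X <- -b * cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
                  2 * dirs[, 1] * dirs[, 2],
                  2 * dirs[, 1] * dirs[, 3],
                  2 * dirs[, 2] * dirs[, 3])
  if (qr(X)$rank < 6) {
    stop_glue("gradient scheme is rank-deficient: ",
              "directions do not span the 6 tensor degrees of freedom")
  }

  sig <- matrix(dwi$signal, nrow = nvox)          # nvox x ngrad
  s0 <- rowMeans(sig[, b0_idx, drop = FALSE])
  sdw <- sig[, dw_idx, drop = FALSE]
  mask <- s0 > mask_threshold & apply(sdw > 0, 1, all)

  Dmat <- matrix(NA_real_, nvox, 6)
  if (any(mask)) {
    y <- log(sdw[mask, , drop = FALSE] / s0[mask]) # nfit x ndw
    # OLS pass, all voxels at once
    beta <- t(qr.solve(X, t(y)))                   # nfit x 6
    if (method == "wls") {
      pred <- beta %*% t(X)                        # predicted log-signal
      w <- exp(2 * pred)                           # squared predicted signal
      # per-voxel weighted normal equations
      beta <- t(vapply(seq_len(nrow(y)), function(i) {
        Xw <- X * w[i, ]
        solve(crossprod(X, Xw), crossprod(Xw, y[i, ]))[, 1]
      }, numeric(6)))
    }
    Dmat[mask, ] <- beta
  }

  ev <- matrix(NA_real_, nvox, 3)
  v1 <- matrix(NA_real_, nvox, 3)
  n_clamped <- 0L
  idx <- which(mask)
  for (i in idx) {
    d <- Dmat[i, ]
    Tm <- matrix(c(d[1], d[4], d[5],
                   d[4], d[2], d[6],
                   d[5], d[6], d[3]), 3, 3)
    e <- eigen(Tm, symmetric = TRUE)
    if (e$values[3] < 0) n_clamped <- n_clamped + 1L
    ev[i, ] <- pmax(e$values, 0)
    v1[i, ] <- e$vectors[, 1]
  }
  if (n_clamped > 0) {
    warning(sprintf("clamped negative eigenvalues in %d voxel(s)", n_clamped))
  }

  fa <- rep(NA_real_, nvox)
  fa[idx] <- fa_from_eigenvalues(ev[idx, 1], ev[idx, 2], ev[idx, 3])

  structure(list(
    tensor = array(Dmat, c(g, 6)),
    eigenvalues = array(ev, c(g, 3)),
    principal_direction = array(v1, c(g, 3)),
    fa = array(fa, g),
    mask = array(mask, g),
    n_clamped = n_clamped,
    voxel_size_mm = dwi$voxel_size_mm,
    method = method
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s fit, %d/%d voxels, %d clamped\n",
              toupper(x$method), sum(x$mask), length(x$mask), x$n_clamped))
  invisible(x)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `fa = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`. Vectorised;
#' all-zero triples return 0 (with a warning flag, since the tensor is
#' degenerate there).
#'
#' @param l1,l2,l3 eigenvalues, `l1 >= l2 >= l3 >= 0` elementwise.
#' @return FA values in \[0, 1\].
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  stopifnot(length(l1) == length(l2), length(l2) == length(l3))
  bad <- !is.na(l1) & (l3 < 0 | l1 < l2 | l2 < l3)
  if (any(bad)) stop_glue("eigenvalues must satisfy l1 >= l2 >= l3 >= 0")
  m <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  zero <- !is.na(den) & den == 0
  if (any(zero)) warning(sprintf(
    "FA undefined for %d all-zero eigenvalue set(s); returning 0", sum(zero)))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

#' Colour-encoded FA maps
#'
#' Standard directional colour encoding of the principal eigenvector:
#' red = |x| (left-right), green = |y| (anterior-posterior),
#' blue = |z| (superior-inferior), each modulated by FA. By construction
#' the squared channels sum to FA^2.
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @return A `color_fa` object: list of 3-D arrays `red`, `green`, `blue`
#'   plus the fit `mask`.
#' @export
color_fa <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  v <- field$principal_direction
  structure(list(
    red   = field$fa * abs(v[, , , 1]),
    green = field$fa * abs(v[, , , 2]),
    blue  = field$fa * abs(v[, , , 3]),
    mask  = field$mask,
    voxel_size_mm = field$voxel_size_mm
  ), class = "color_fa")
}
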