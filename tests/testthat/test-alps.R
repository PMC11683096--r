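# ROI placement and the ALPS index

make_cfa_fixture <- function(dim3 = c(20L, 20L, 5L), slice = 3L) {
  z <- array(0, dim3)
  structure(list(red = z, green = z, blue = z,
                 mask = array(TRUE, dim3), voxel_size_mm = 2),
            class = "color_fa")
}

test_that("zero search radius keeps the centers at the seeds", {
  cfa <- make_cfa_fixture()
  cfa$blue[, , 3] <- 0.5; cfa$green[, , 3] <- 0.5
  seeds <- list(proj_left = c(6, 10, 3), proj_right = c(14, 10, 3),
                assoc_left = c(4, 10, 3), assoc_right = c(16, 10, 3))
  rois <- place_rois(cfa, seeds, search_radius_mm = 0)
  for (nm in names(seeds)) {
    expect_equal(rois$rois[[nm]]$center, seeds[[nm]], ignore_attr = TRUE)
  }
})

test_that("peak search finds channel maxima offset from the seeds", {
  cfa <- make_cfa_fixture()
  cfa$blue[, , 3] <- 0.1; cfa$green[, , 3] <- 0.1
  cfa$blue[8, 12, 3] <- 0.9     # true projection peak, offset (2, 2)
  cfa$green[2, 10, 3] <- 0.9    # true association peak, offset (-2, 0)
  seeds <- list(proj_left = c(6, 10, 3), proj_right = c(14, 10, 3),
                assoc_left = c(4, 10, 3), assoc_right = c(16, 10, 3))
  rois <- place_rois(cfa, seeds, search_radius_mm = 10)
  expect_equal(rois$rois$proj_left$center[1:2], c(8, 12))
  expect_equal(rois$rois$assoc_left$center[1:2], c(2, 10))
  # seeds with no better voxel stay put
  expect_equal(rois$rois$proj_right$center[1:2], c(14, 10))
})

test_that("uniform channels resolve ties to the seed; empty discs fall back", {
  cfa <- make_cfa_fixture()
  cfa$blue[, , 3] <- 0.4; cfa$green[, , 3] <- 0.4
  seeds <- list(proj_left = c(6, 10, 3), proj_right = c(14, 10, 3),
                assoc_left = c(4, 10, 3), assoc_right = c(16, 10, 3))
  rois <- place_rois(cfa, seeds, search_radius_mm = 8)
  expect_equal(rois$rois$proj_left$center[1:2], c(6, 10))

  cfa0 <- make_cfa_fixture()   # all-zero channels
  expect_warning(r0 <- place_rois(cfa0, seeds, search_radius_mm = 8),
                 "using seed")
  expect_equal(r0$rois$assoc_right$center[1:2], c(16, 10))
})

test_that("ALPS index reproduces direct formula arithmetic", {
  # uniform diagonal tensor field -> alps = 1 by isotropy of the ratio
  g <- c(20L, 20L, 5L)
  tens <- array(0, c(g, 6))
  tens[, , , 1:3] <- 0.7e-3
  field <- structure(list(tensor = tens, mask = array(TRUE, g),
                          voxel_size_mm = 2), class = "tensor_field")
  seeds <- list(proj_left = c(6, 10, 3), proj_right = c(14, 10, 3),
                assoc_left = c(3, 10, 3), assoc_right = c(17, 10, 3))
  cfa <- make_cfa_fixture()
  suppressWarnings(rois <- place_rois(cfa, seeds, search_radius_mm = 0))
  res <- compute_alps(field, rois)
  expect_equal(res$alps_left, 1.0)
  expect_equal(res$alps_mean, (res$alps_left + res$alps_right) / 2)

  # Dxassoc = 1.2e-3, Dxproj = 1.0e-3, Dzassoc = 0.6e-3, Dyproj = 0.5e-3
  tens2 <- tens
  for (s in list(c(6, 10), c(14, 10))) {       # projection ROIs
    tens2[(s[1] - 1):(s[1] + 1), (s[2] - 1):(s[2] + 1), 3, 1] <- 1.0e-3
    tens2[(s[1] - 1):(s[1] + 1), (s[2] - 1):(s[2] + 1), 3, 2] <- 0.5e-3
  }
  for (s in list(c(3, 10), c(17, 10))) {       # association ROIs
    tens2[(s[1] - 1):(s[1] + 1), (s[2] - 1):(s[2] + 1), 3, 1] <- 1.2e-3
    tens2[(s[1] - 1):(s[1] + 1), (s[2] - 1):(s[2] + 1), 3, 3] <- 0.6e-3
  }
  field2 <- structure(list(tensor = tens2, mask = array(TRUE, g),
                           voxel_size_mm = 2), class = "tensor_field")
  res2 <- compute_alps(field2, rois)
  expect_equal(res2$alps_left, 2.0, tolerance = 1e-12)
  expect_equal(res2$alps_right, 2.0, tolerance = 1e-12)
})

test_that("ALPS is invariant to a global tensor scaling", {
  ph <- make_phantom(tiny_phantom_spec())
  field <- fit_tensor(ph$dwi)
  cfa <- color_fa(field)
  rois <- place_rois(cfa, ph$ground_truth$seeds)
  r1 <- compute_alps(field, rois)
  field2 <- field
  field2$tensor <- field$tensor * 1.7
  r2 <- compute_alps(field2, rois)
  expect_equal(r2$alps_left, r1$alps_left, tolerance = 1e-12)
  expect_equal(r2$alps_right, r1$alps_right, tolerance = 1e-12)
})

test_that("mirroring the volume swaps left and right indices", {
  ph <- make_phantom(tiny_phantom_spec(glymphatic_factor = 0.9, snr = 40,
                                       seed = 21L))
  field <- fit_tensor(ph$dwi)
  rois <- place_rois(color_fa(field), ph$ground_truth$seeds)
  r1 <- compute_alps(field, rois)

  nx <- dim(ph$dwi$signal)[1]
  flip <- function(a) a[nx:1, , , , drop = FALSE]
  dwi2 <- ph$dwi
  dwi2$signal <- flip(ph$dwi$signal)
  seeds2 <- lapply(ph$ground_truth$seeds, function(s)
    c(nx + 1 - s[1], s[2], s[3]))
  names(seeds2) <- c("proj_right", "proj_left", "assoc_right", "assoc_left")
  field2 <- fit_tensor(dwi2)
  rois2 <- place_rois(color_fa(field2), seeds2)
  r2 <- compute_alps(field2, rois2)
  expect_equal(r2$alps_left, r1$alps_right, tolerance = 1e-10)
  expect_equal(r2$alps_right, r1$alps_left, tolerance = 1e-10)
})

test_that("reported index follows the lesion-side convention", {
  ph <- make_phantom(tiny_phantom_spec(snr = 35, seed = 9L))
  field <- fit_tensor(ph$dwi)
  rois <- place_rois(color_fa(field), ph$ground_truth$seeds)
  none <- compute_alps(field, rois, "none")
  left <- compute_alps(field, rois, "left")
  right <- compute_alps(field, rois, "right")
  expect_equal(none$alps_reported, none$alps_mean)
  expect_equal(left$alps_reported, left$alps_left)
  expect_equal(right$alps_reported, right$alps_right)
  expect_equal(none$alps_mean, (none$alps_left + none$alps_right) / 2)
})

test_that("noiseless pipeline recovers ground truth and tracks the factor", {
  alps <- vapply(c(1.0, 0.75, 0.5), function(f) {
    ph <- make_phantom(tiny_phantom_spec(glymphatic_factor = f))
    res <- alps_pipeline(ph$dwi, ph$ground_truth$seeds)
    expect_equal(res$alps_mean, ph$ground_truth$alps, tolerance = 1e-3)
    res$alps_mean
  }, numeric(1))
  expect_true(all(diff(alps) < 0))
})

test_that("tidy and glance expose the ALPS result as tibbles", {
  ph <- make_phantom(tiny_phantom_spec())
  res <- alps_pipeline(ph$dwi, ph$ground_truth$seeds, lesion_side = "left")
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$hemisphere, c("left", "right"))
  gl <- generics::glance(res)
  expect_identical(gl$lesion_side, "left")
  expect_equal(gl$alps_reported, res$alps_left)
})
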