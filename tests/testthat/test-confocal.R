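test_that("maximum-intensity projection collapses the declared axis", {
  arr <- array(7, dim = c(8, 8, 4))
  st <- image_stack(arr)
  roi <- membrane_roi("r", cbind(c(0, 0, 0), c(8, 8, 4)), "z")
  pl <- project_membrane(st, roi)
  expect_true(all(pl$intensities == 7))
  expect_equal(dim(pl$intensities), c(8, 8))
  expect_equal(pl$pixel_size, c(0.089, 0.089))

  arr2 <- array(0, dim = c(8, 8, 4))
  arr2[3, 5, 2] <- 9
  pl2 <- project_membrane(image_stack(arr2), roi)
  expect_equal(pl2$intensities[3, 5], 9)
  expect_equal(sum(pl2$intensities), 9)

  # exhaustive loop oracle on a random sub-volume, all three axes
  set.seed(11)
  arr3 <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  st3 <- image_stack(arr3)
  for (ax in c("x", "y", "z")) {
    roi3 <- membrane_roi("r", cbind(c(0, 0, 0), c(8, 8, 4)), ax)
    pl3 <- project_membrane(st3, roi3)
    k <- match(ax, c("x", "y", "z"))
    oracle <- apply(arr3, setdiff(1:3, k), max)
    expect_equal(pl3$intensities, oracle)
    expect_equal(pl3$pixel_size, st3$voxel_size[setdiff(1:3, k)])
  }
})

test_that("projection rejects degenerate and out-of-bounds ROIs", {
  st <- image_stack(array(1, dim = c(8, 8, 4)))
  expect_error(membrane_roi("r", cbind(c(0, 0, 2), c(8, 8, 2)), "z"),
               "end > start")
  expect_error(
    project_membrane(st, membrane_roi("r", cbind(c(0, 0, 0), c(8, 8, 9)), "z")),
    "exceeds")
})

test_that("local maxima are exactly the strict 3x3 interior maxima", {
  expect_equal(nrow(find_local_maxima(matrix(5, 6, 6))), 0)  # ties never peak

  m <- matrix(0, 7, 7); m[3, 3] <- 1
  expect_equal(find_local_maxima(m), cbind(i = 3L, j = 3L))

  # border peak candidates are excluded even when brightest
  mb <- matrix(0, 5, 5); mb[1, 3] <- 9
  expect_equal(nrow(find_local_maxima(mb)), 0)

  for (seed in 1:25) {
    m <- random_plane(16, 16, seed)
    got <- find_local_maxima(m)
    exp <- bf_local_maxima(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 cbind(i = as.integer(exp[, 1]), j = as.integer(exp[, 2])))
  }
})

test_that("no two maxima are within Chebyshev distance 1", {
  for (seed in 1:10) {
    pk <- find_local_maxima(random_plane(24, 24, seed))
    if (nrow(pk) > 1) {
      d <- pmax(abs(outer(pk[, 1], pk[, 1], "-")), abs(outer(pk[, 2], pk[, 2], "-")))
      expect_true(all(d[upper.tri(d)] >= 2))
    }
  }
})

test_that("growing-window size matches the nearest-brighter-pixel oracle", {
  # brighter pixel at Chebyshev distance 5: clean 9x9, dirty 11x11
  m <- matrix(0, 21, 21)
  m[11, 11] <- 10
  m[11, 16] <- 11
  call <- estimate_cluster_size(m, c(11, 11), n_cap = 6, low_contrast_k = NULL)
  expect_equal(call$n_max, 4L)
  expect_equal(call$side_px, 9L)
  expect_false(call$capped)
  # the alternative even-diameter convention reports 2n = 8
  call2n <- estimate_cluster_size(m, c(11, 11), n_cap = 6,
                                  size_convention = "diameter2n",
                                  low_contrast_k = NULL)
  expect_equal(call2n$side_px, 8L)

  # nothing brighter anywhere: growth runs to the cap
  m2 <- matrix(0, 21, 21); m2[11, 11] <- 1
  call2 <- estimate_cluster_size(m2, c(11, 11), n_cap = 6, low_contrast_k = NULL)
  expect_equal(call2$n_max, 6L)
  expect_true(call2$capped)

  expect_error(estimate_cluster_size(matrix(1, 5, 5), c(3, 3)), "strict local maximum")

  for (seed in 1:25) {
    m <- random_plane(20, 20, seed)
    for (k in seq_len(nrow(pk <- find_local_maxima(m)))) {
      got <- estimate_cluster_size(m, pk[k, ], n_cap = 6, low_contrast_k = NULL)
      ora <- bf_window_size(m, pk[k, 1], pk[k, 2], 6L)
      expect_equal(got$n_max, ora$n_max)
      expect_equal(got$capped, ora$capped)
    }
  }
})

test_that("size consistency: a brighter pixel inside the side-s window forces side < s", {
  for (seed in 1:10) {
    m <- random_plane(24, 24, seed)
    pl <- plane_image(m, 0.089)
    calls <- call_clusters(pl, n_cap = 6, low_contrast_k = NULL)
    for (k in seq_len(nrow(calls))) {
      n <- calls$n_max[k]; i <- calls$i[k]; j <- calls$j[k]
      if (!calls$capped[k]) {
        w <- m[max(1, i - n - 1):min(24, i + n + 1), max(1, j - n - 1):min(24, j + n + 1)]
        expect_true(any(w > m[i, j]))  # growth stopped for a reason
      }
      w_in <- m[(i - n):(i + n), (j - n):(j + n)]
      expect_true(all(w_in <= m[i, j]))
    }
  }
})

test_that("detection is invariant under affine intensity rescaling", {
  m <- random_plane(32, 32, 99)
  pl <- plane_image(m, 0.089)
  base <- call_clusters(pl)
  for (tf in list(function(x) x * 7.3, function(x) x + 11, function(x) 0.2 * x + 5)) {
    tr <- call_clusters(plane_image(tf(m), 0.089))
    expect_equal(tr$i, base$i)
    expect_equal(tr$j, base$j)
    expect_equal(tr$n_max, base$n_max)
    expect_equal(tr$capped, base$capped)
    expect_equal(tr$low_contrast, base$low_contrast)
  }
})

test_that("size gating keeps the configured classes and drops capped calls", {
  calls <- data.frame(i = c(5L, 20L, 40L, 60L, 80L), j = 5L, peak_value = 5:1,
                      n_max = c(1L, 2L, 3L, 4L, 5L),
                      side_px = c(3L, 5L, 7L, 9L, 11L),
                      capped = FALSE, low_contrast = FALSE)
  expect_equal(filter_size_classes(calls)$side_px, c(5L, 7L, 9L))
  expect_equal(nrow(filter_size_classes(calls[0, , drop = FALSE])), 0)
  calls$capped <- TRUE
  expect_equal(nrow(filter_size_classes(calls)), 0)
  expect_error(filter_size_classes(calls, 9, 5), "must not exceed")
})

test_that("overlap suppression keeps one call per blob", {
  calls <- data.frame(i = c(10L, 13L, 30L), j = c(10L, 10L, 30L),
                      peak_value = c(9, 5, 7),
                      n_max = c(2L, 2L, 3L), side_px = c(5L, 5L, 7L),
                      capped = FALSE, low_contrast = FALSE)
  kept <- filter_size_classes(calls)
  expect_equal(kept$i, c(10L, 30L))  # dimmer overlapping call suppressed
  kept_all <- filter_size_classes(calls, suppress_overlaps = FALSE)
  expect_equal(nrow(kept_all), 3)
})

test_that("pixel size classes convert to printed physical diameters", {
  expect_equal(to_physical_diameter(9, 0.089), 0.801)
  expect_equal(round(to_physical_diameter(9, 0.089), 2), 0.80)
  expect_equal(to_physical_diameter(5, 0.089), 0.445)
  # the conventional printed lower bound truncates rather than rounds
  expect_equal(floor(to_physical_diameter(5, 0.089) * 100) / 100, 0.44)
  expect_equal(to_physical_diameter(1, 0.3), 0.3)
  expect_error(to_physical_diameter(0, 0.089), ">= 1")
})

test_that("membrane area counts thresholded pixels times pixel area", {
  pl <- plane_image(matrix(10, 100, 100), 0.089)
  expect_equal(as.numeric(estimate_membrane_area(pl, threshold = 5)),
               100 * 100 * 0.089^2)
  half <- plane_image(cbind(matrix(0, 50, 50), matrix(10, 50, 50)), 0.1)
  expect_equal(as.numeric(estimate_membrane_area(half, threshold = 5)),
               50 * 50 * 0.1^2)
  expect_error(estimate_membrane_area(pl, threshold = 99), "no pixels")
})

test_that("Otsu area recovers a synthetic membrane strip", {
  p <- stack_sim_params(grid_shape = c(96L, 96L, 16L),
        membrane_faces = list(list(axis = "z", position = 7L, thickness_vox = 2L,
                                   extent_um = rbind(c(1, 7.5), c(0.5, 8)))),
        cluster_density_per_face = 0.1, seed = 5)
  sim <- simulate_membrane_stack(p)
  roi <- membrane_roi("m", cbind(c(0L, 0L, 0L), dim(sim$stack$data)), "z")
  area <- estimate_membrane_area(project_membrane(sim$stack, roi))
  truth <- sim$truth$faces[[1]]$face_area_um2
  expect_lt(abs(as.numeric(area) - truth) / truth, 0.15)
})

test_that("cluster density is count over area", {
  d <- cluster_density(19, 100, "roi1")
  expect_equal(d$density_per_um2, 0.19)
  expect_equal(cluster_density(0, 50)$density_per_um2, 0)
  expect_error(cluster_density(3, 0), "positive")
})
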