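make_points <- function(n, seed, side_nm = 1000) {
  set.seed(seed)
  cbind(runif(n, 0, side_nm), runif(n, 0, side_nm))
}

test_that("linkage groups are connected components at the inclusive threshold", {
  # exactly 55 nm apart: inclusive boundary makes a doublet
  memb <- link_particles(rbind(c(0, 0), c(55, 0)), 55)
  expect_equal(memb$group, c(1L, 1L))
  # 55 + epsilon: two singletons
  memb2 <- link_particles(rbind(c(0, 0), c(55.001, 0)), 55)
  expect_equal(length(unique(memb2$group)), 2L)
  # chaining: pairwise 50/50/100 merges all three
  memb3 <- link_particles(rbind(c(0, 0), c(50, 0), c(100, 0)), 55)
  expect_equal(memb3$group, c(1L, 1L, 1L))
})

test_that("linkage matches the single-linkage dendrogram oracle", {
  for (seed in 1:30) {
    n <- sample(20:300, 1)
    pts <- make_points(n, seed)
    got <- link_particles(pts, 55)$group
    expect_same_partition(got, bf_linkage(pts, 55))
  }
  # denser field exercising the grid pathway
  pts <- make_points(400, 999, side_nm = 600)
  expect_same_partition(link_particles(pts, 55)$group, bf_linkage(pts, 55))
})

test_that("linkage partition is invariant under rigid motion and joint rescaling", {
  pts <- make_points(150, 7)
  base <- link_particles(pts, 55)$group
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_same_partition(link_particles(pts %*% Rm, 55)$group, base)
  expect_same_partition(link_particles(pts + 1e5, 55)$group, base)
  expect_same_partition(link_particles(pts * 3.7, 55 * 3.7)$group, base)
})

test_that("raising dmax never splits groups nor increases their number", {
  pts <- make_points(200, 13)
  prev <- link_particles(pts, 30)$group
  for (dmax in c(45, 55, 70, 90, 120)) {
    cur <- link_particles(pts, dmax)$group
    expect_lte(length(unique(cur)), length(unique(prev)))
    # coarsening: points together at the smaller threshold stay together
    expect_true(all(tapply(cur, prev, function(g) length(unique(g))) == 1))
    prev <- cur
  }
})

test_that("group summary partitions all particles and classifies by size", {
  pts <- rbind(c(0, 0), c(40, 0),            # doublet
               c(500, 500), c(530, 500), c(515, 540),  # triplet
               c(2000, 2000))                # singleton
  ps <- particle_set(pts[, 1], pts[, 2])
  grp <- summarize_groups(ps, link_particles(ps))
  expect_equal(sort(grp$size), c(1L, 2L, 3L))
  expect_setequal(grp$class, c("scattered", "doublet", "cluster"))
  expect_equal(sum(grp$size), 6L)

  cls <- classify_particle_groups(grp)
  expect_equal(unname(cls$particle_counts), c(1L, 2L, 3L))
  expect_equal(cls$n_particles, 6L)
})

test_that("class fractions are percentages of particles, not groups", {
  grp <- data.frame(
    group = 1:14,
    size = c(rep(1L, 10), 2L, 2L, 3L, 3L),
    class = c(rep("scattered", 10), "doublet", "doublet", "cluster", "cluster"))
  cls <- classify_particle_groups(grp)
  expect_equal(unname(cls$particle_fractions), c(50, 20, 30))
  expect_equal(sum(cls$particle_fractions), 100)

  all_single <- data.frame(group = 1:4, size = 1L, class = "scattered")
  expect_equal(unname(classify_particle_groups(all_single)$particle_fractions),
               c(100, 0, 0))
  empty <- classify_particle_groups(grp[0, , drop = FALSE])
  expect_true(empty$empty)
  expect_true(all(is.nan(empty$particle_fractions)))
})

test_that("group diameter is the Feret diameter plus optional label size", {
  expect_equal(group_diameter(rbind(c(0, 0), c(40, 0))), 40)
  s <- 50
  tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  expect_equal(group_diameter(tri), 50)
  expect_equal(group_diameter(rbind(c(0, 0), c(40, 0)), gold_diameter_nm = 10), 50)
  expect_equal(group_diameter(rbind(c(5, 5)), gold_diameter_nm = 10), 10)
  set.seed(3)
  g6 <- make_points(6, 3, 200)
  expect_equal(group_diameter(g6),
               max(sqrt(outer(g6[, 1], g6[, 1], "-")^2 +
                        outer(g6[, 2], g6[, 2], "-")^2)))
})

test_that("polar bands assign apical, central and basal labels per the 2 um rule", {
  # 10 um cell along x, full-width region
  ps <- particle_set(x_nm = c(1500, 5000, 8500, 3000),
                     y_nm = c(500, 500, 500, 500),
                     analyzed_region = cbind(c(0, 10000, 10000, 0), c(0, 0, 1000, 1000)),
                     apical_edge = c(0, 500), basal_edge = c(10000, 500))
  dom <- assign_membrane_domains(ps, band_um = 2)
  expect_equal(as.character(dom$labels), c("apical", "central", "basal", "unassigned"))
  # band areas: each band is 2 um x 1 um of the region
  q <- dom$quant
  expect_equal(q$band_area_um2, rep(2, 3))
  expect_equal(q$particle_density_per_um2, c(0.5, 0.5, 0.5))
})

test_that("band density is count over band area", {
  # 50 particles in a 2 x 5 um apical band
  set.seed(21)
  ps <- particle_set(x_nm = runif(50, 0, 2000), y_nm = runif(50, 0, 5000),
                     analyzed_region = cbind(c(0, 20000, 20000, 0), c(0, 0, 5000, 5000)),
                     apical_edge = c(0, 2500), basal_edge = c(20000, 2500))
  dom <- assign_membrane_domains(ps, band_um = 2)
  q <- dom$quant
  expect_equal(q$particle_density_per_um2[q$domain == "apical"], 50 / 10)
  expect_error(assign_membrane_domains(
    particle_set(1, 1, apical_edge = c(0, 0), basal_edge = c(3000, 0)), band_um = 2),
    "overlap")
})

test_that("particles-per-cluster profile bins clusters by apical distance", {
  ps <- particle_set(numeric(), numeric(),
                     apical_edge = c(0, 0), basal_edge = c(10000, 0))
  groups <- data.frame(group = 1:3, size = 3L, class = "cluster",
                       diameter_nm = 50,
                       centroid_x_nm = c(500, 1500, 8500), centroid_y_nm = 0)
  prof <- particles_per_cluster_gradient(groups, ps, bin_um = 1)
  occupied <- prof[prof$n_clusters > 0, ]
  expect_equal(occupied$mean_particles_per_cluster, rep(3, 3))
  expect_true(all(is.na(prof$mean_particles_per_cluster[prof$n_clusters == 0])))
  empty <- particles_per_cluster_gradient(groups[0, , drop = FALSE], ps, 1)
  expect_equal(nrow(empty), 0)
})

test_that("thin-section profile summary reports per-image and per-length counts", {
  s <- iem_profile_summary(c(9, 9, 9))
  expect_equal(s$mean_per_image, 9)
  expect_equal(s$sd_per_image, 0)
  one <- iem_profile_summary(4)
  expect_equal(one$mean_per_image, 4)
  expect_equal(one$sd_per_image, 0)
  withlen <- iem_profile_summary(c(4, 6), profile_lengths_um = c(2, 3))
  expect_equal(withlen$per_um, c(2, 2))
  counts <- c(3, 7, 1, 5, 9, 2, 8, 4, 6, 0)
  s10 <- iem_profile_summary(counts)
  expect_equal(s10$mean_per_image, mean(counts))
  expect_equal(s10$sd_per_image, sd(counts))
})

test_that("gold-particle detection finds centroids of thresholded components", {
  img <- matrix(0, 20, 20)
  expect_warning(ps0 <- detect_gold_particles(img, 10, 0.5), "no foreground")
  expect_equal(length(ps0), 0)

  img[5:7, 9:11] <- 1  # uniform 3x3 square, centre pixel (6, 10)
  ps1 <- detect_gold_particles(img, 10, 0.5)
  expect_equal(length(ps1), 1)
  expect_equal(ps1$x_nm, (6 - 0.5) * 10)
  expect_equal(ps1$y_nm, (10 - 0.5) * 10)

  # diagonal contact is one component (8-connectivity)
  img2 <- matrix(0, 10, 10); img2[2, 2] <- 1; img2[3, 3] <- 1
  expect_equal(length(detect_gold_particles(img2, 10, 0.5)), 1)

  # planted discs recovered one-to-one with sub-pixel centroid accuracy
  set.seed(17)
  img3 <- matrix(0, 120, 120)
  centers <- cbind(sample(10:110, 12), sample(10:110, 12))
  keep <- rep(TRUE, 12)
  for (k in 1:12) if (k > 1 && any(sqrt(colSums((t(centers[seq_len(k - 1), , drop = FALSE]) - centers[k, ])^2)) < 8)) keep[k] <- FALSE
  centers <- centers[keep, , drop = FALSE]
  for (k in seq_len(nrow(centers))) {
    di <- -2:2
    for (a in di) for (b in di) if (a^2 + b^2 <= 4)
      img3[centers[k, 1] + a, centers[k, 2] + b] <- 1
  }
  ps3 <- detect_gold_particles(img3, 5, 0.5, area_range_px = c(3, 50))
  expect_equal(length(ps3), nrow(centers))
  d <- sqrt(outer(ps3$x_nm / 5 + 0.5, centers[, 1], "-")^2 +
            outer(ps3$y_nm / 5 + 0.5, centers[, 2], "-")^2)
  expect_true(all(apply(d, 2, min) <= 1))
})

test_that("partition bookkeeping conserves the particle count", {
  for (seed in 1:5) {
    pts <- make_points(250, seed + 50)
    ps <- particle_set(pts[, 1], pts[, 2])
    grp <- summarize_groups(ps, link_particles(ps))
    cls <- classify_particle_groups(grp)
    expect_equal(1L * cls$group_counts[["scattered"]] +
                 2L * cls$group_counts[["doublet"]] +
                 sum(grp$size[grp$class == "cluster"]), 250L)
  }
})
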