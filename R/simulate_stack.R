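# Seeded generator of synthetic confocal stacks: membrane sheets carrying
# diffraction-limited Gaussian spots, anisotropic PSF blur (axial wider than
# lateral, emulating z-elongation) and additive/Poisson noise, with the
# planted ground truth exported alongside.

#' Parameters for the synthetic membrane-stack generator
#'
#' Describes a 3D acquisition of one or more planar membrane sheets bearing
#' diffraction-limited protein clusters. Each face is a slab perpendicular
#' to one principal axis; clusters are planted on it as a Poisson process
#' with the given surface density and rendered as isotropic in-plane
#' Gaussian spots of the stated full width at half maximum, extruded through
#' the membrane thickness. The whole volume is then blurred with an
#' anisotropic Gaussian point-spread function and corrupted by noise.
#'
#' @param grid_shape voxels per axis (x, y, z), each >= 16.
#' @param voxel_size µm per voxel (x, y, z); default 0.089/0.089/0.313.
#' @param membrane_faces list of faces; each a list with `axis` ("x", "y" or
#'   "z": the membrane normal), `position` (0-based voxel index of the slab
#'   centre along that axis), `thickness_vox` (slab thickness, voxels) and
#'   optionally `extent_um`, a 2x2 matrix of in-plane ranges (µm; rows are
#'   the two non-normal axes in x, y, z order) restricting the sheet to a
#'   strip or patch instead of the full plane.
#' @param cluster_density_per_face clusters per µm², one value per face.
#' @param cluster_diameter_um spot full width at half maximum (µm); must be
#'   at least one lateral voxel, otherwise spots would be undetectable.
#' @param spot_amplitude peak intensity of a planted spot above the membrane
#'   baseline (arbitrary units).
#' @param membrane_background baseline intensity of the membrane slab.
#' @param psf_sigma_lateral_um,psf_sigma_axial_um Gaussian blur sigmas (µm);
#'   the axial sigma is typically about three times the lateral one.
#' @param noise_gaussian_sd additive Gaussian noise sigma (0 disables).
#' @param noise_poisson_scale if > 0, intensities are replaced by
#'   `rpois(x * scale) / scale` (photon-counting noise; 0 disables).
#' @param seed mandatory RNG seed for reproducible stacks.
#' @return Validated parameter list of class `stack_sim_params`.
#' @export
stack_sim_params <- function(grid_shape = c(128L, 128L, 16L),
                             voxel_size = c(0.089, 0.089, 0.313),
                             membrane_faces = list(list(axis = "z", position = 7L,
                                                        thickness_vox = 2L)),
                             cluster_density_per_face = 0.19,
                             cluster_diameter_um = 0.75,
                             spot_amplitude = 1000,
                             membrane_background = 1500,
                             psf_sigma_lateral_um = 0.1,
                             psf_sigma_axial_um = 0.35,
                             noise_gaussian_sd = 160,
                             noise_poisson_scale = 0,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            all(cluster_density_per_face >= 0),
            length(cluster_density_per_face) == length(membrane_faces),
            cluster_diameter_um > 0, spot_amplitude >= 0,
            membrane_background >= 0,
            psf_sigma_lateral_um >= 0, psf_sigma_axial_um >= 0,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  if (cluster_diameter_um < min(voxel_size[1:2]))
    stop("cluster_diameter_um is below one lateral voxel: spots would be undetectable")
  for (f in membrane_faces) {
    ax <- .axis_index(f$axis)
    if (is.na(ax)) stop("face axis must be 'x', 'y' or 'z'")
    if (f$position < 0L || f$position >= grid_shape[ax])
      stop("face position outside the grid")
    if (f$thickness_vox < 1L) stop("face thickness must be >= 1 voxel")
  }
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 membrane_faces = membrane_faces,
                 cluster_density_per_face = as.numeric(cluster_density_per_face),
                 cluster_diameter_um = cluster_diameter_um,
                 spot_amplitude = spot_amplitude,
                 membrane_background = membrane_background,
                 psf_sigma_lateral_um = psf_sigma_lateral_um,
                 psf_sigma_axial_um = psf_sigma_axial_um,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson_scale = noise_poisson_scale,
                 seed = as.integer(seed)),
            class = "stack_sim_params")
}

# Row-normalised banded Gaussian convolution matrix (truncated at 4 sigma).
.gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  G <- outer(idx, idx, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= half, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  sweep(G, 1, rowSums(G), "/")
}

#' Simulate a synthetic confocal membrane stack with ground truth
#'
#' See [stack_sim_params()] for the generative model. Identical parameters
#' and seed produce bit-identical output.
#'
#' @param params a [stack_sim_params()] object.
#' @return List with `stack` (an [image_stack]) and `truth`: per face, the
#'   planted count, in-plane centre coordinates (µm) and face area (µm²),
#'   plus a parameter echo.
#' @export
simulate_membrane_stack <- function(params) {
  stopifnot(inherits(params, "stack_sim_params"))
  set.seed(params$seed)
  d <- params$grid_shape
  vs <- params$voxel_size
  vol <- array(0, dim = d)
  sigma_spot_um <- params$cluster_diameter_um / (2 * sqrt(2 * log(2)))

  truth_faces <- vector("list", length(params$membrane_faces))
  for (fi in seq_along(params$membrane_faces)) {
    f <- params$membrane_faces[[fi]]
    ax <- .axis_index(f$axis)
    inplane <- setdiff(1:3, ax)
    n1 <- d[inplane[1]]; n2 <- d[inplane[2]]
    s1 <- vs[inplane[1]]; s2 <- vs[inplane[2]]
    ext <- if (is.null(f$extent_um)) rbind(c(0, n1 * s1), c(0, n2 * s2))
           else matrix(as.numeric(f$extent_um), 2L, 2L)
    ext[1, ] <- pmin(pmax(ext[1, ], 0), n1 * s1)
    ext[2, ] <- pmin(pmax(ext[2, ], 0), n2 * s2)
    area <- diff(ext[1, ]) * diff(ext[2, ])
    if (area <= 0) stop("face extent has zero area")
    n_spots <- stats::rpois(1, params$cluster_density_per_face[fi] * area)
    centers <- cbind(stats::runif(n_spots, ext[1, 1], ext[1, 2]),
                     stats::runif(n_spots, ext[2, 1], ext[2, 2]))

    face_img <- matrix(0, n1, n2)
    e1 <- max(1L, floor(ext[1, 1] / s1) + 1L):min(n1, ceiling(ext[1, 2] / s1))
    e2 <- max(1L, floor(ext[2, 1] / s2) + 1L):min(n2, ceiling(ext[2, 2] / s2))
    face_img[e1, e2] <- params$membrane_background
    if (n_spots > 0 && params$spot_amplitude > 0) {
      halfw <- ceiling(4 * sigma_spot_um / min(s1, s2))
      px1 <- (seq_len(n1) - 0.5) * s1
      px2 <- (seq_len(n2) - 0.5) * s2
      for (k in seq_len(n_spots)) {
        c1 <- centers[k, 1]; c2 <- centers[k, 2]
        i1 <- max(1L, floor(c1 / s1) - halfw):min(n1, ceiling(c1 / s1) + halfw)
        i2 <- max(1L, floor(c2 / s2) - halfw):min(n2, ceiling(c2 / s2) + halfw)
        g1 <- exp(-(px1[i1] - c1)^2 / (2 * sigma_spot_um^2))
        g2 <- exp(-(px2[i2] - c2)^2 / (2 * sigma_spot_um^2))
        face_img[i1, i2] <- face_img[i1, i2] + params$spot_amplitude * outer(g1, g2)
      }
    }
    slab <- (f$position - floor((f$thickness_vox - 1) / 2)):
      (f$position + ceiling((f$thickness_vox - 1) / 2))
    slab <- slab[slab >= 0L & slab < d[ax]] + 1L
    for (s in slab) {
      if (ax == 1L) vol[s, , ] <- vol[s, , ] + face_img
      else if (ax == 2L) vol[, s, ] <- vol[, s, ] + face_img
      else vol[, , s] <- vol[, , s] + face_img
    }
    truth_faces[[fi]] <- list(axis = f$axis, n_planted = n_spots,
                              centers_um = centers, face_area_um2 = area)
  }

  # separable anisotropic Gaussian blur via banded matrices
  sig_vox <- c(params$psf_sigma_lateral_um / vs[1],
               params$psf_sigma_lateral_um / vs[2],
               params$psf_sigma_axial_um / vs[3])
  if (sig_vox[1] > 0 || sig_vox[2] > 0) {
    Gx <- .gauss_band(d[1], sig_vox[1])
    Gy <- t(.gauss_band(d[2], sig_vox[2]))
    for (z in seq_len(d[3])) vol[, , z] <- Gx %*% vol[, , z] %*% Gy
  }
  if (sig_vox[3] > 0) {
    Gz <- t(.gauss_band(d[3], sig_vox[3]))
    dim(vol) <- c(d[1] * d[2], d[3])
    vol <- vol %*% Gz
    dim(vol) <- d
  }

  if (params$noise_poisson_scale > 0) {
    sc <- params$noise_poisson_scale
    vol[] <- stats::rpois(length(vol), pmax(vol, 0) * sc) / sc
  }
  if (params$noise_gaussian_sd > 0)
    vol[] <- vol + stats::rnorm(length(vol), 0, params$noise_gaussian_sd)
  vol[vol < 0] <- 0  # detector floor

  list(stack = image_stack(vol, vs),
       truth = list(faces = truth_faces, params = params))
}
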