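# Thresholding-free confocal cluster detection: maximum-intensity projection,
# strict local maxima, growing-window size classification, size gating and
# cluster densities per membrane area.

#' Maximum-intensity projection of a membrane ROI
#'
#' Collapses the ROI sub-volume along its declared projection axis (the
#' membrane-normal direction), so that a membrane sheet lying roughly
#' perpendicular to that axis becomes a 2D image of its in-plane intensity
#' pattern. Each output pixel is the maximum intensity along the projection
#' axis within the ROI.
#'
#' @param stack an [image_stack].
#' @param roi a [membrane_roi] fully contained in the stack, with thickness
#'   of at least 1 voxel along the projection axis.
#' @return A [plane_image]; its `pixel_size` is taken from the two
#'   non-projected axes (in their x, y, z order).
#' @export
project_membrane <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "membrane_roi"))
  .check_roi_in_stack(stack, roi)
  b <- roi$bounds
  sub <- stack$data[(b[1, 1] + 1L):b[1, 2],
                    (b[2, 1] + 1L):b[2, 2],
                    (b[3, 1] + 1L):b[3, 2], drop = FALSE]
  ax <- .axis_index(roi$projection_axis)
  if (dim(sub)[ax] < 1L) stop("degenerate ROI: zero thickness along projection axis")
  keep <- setdiff(1:3, ax)
  if (any(dim(sub)[keep] < 3L))
    stop("projected plane must be at least 3 x 3 pixels")
  mip <- apply(sub, keep, max)
  plane_image(mip, stack$voxel_size[keep])
}

#' Find strict local intensity maxima in a plane
#'
#' A pixel is a peak when it is the absolute maximum of its 3 x 3
#' neighbourhood: all eight nearest neighbours are strictly dimmer. No
#' intensity threshold is applied -- detection compares intensity differences
#' between neighbours, never absolute intensity values, so the result is
#' invariant under any increasing affine rescaling of the image. Border
#' pixels have incomplete neighbourhoods and are never peaks; intensity
#' plateaus (ties) yield no peak.
#'
#' @param plane a [plane_image] of at least 3 x 3 pixels, or a plain matrix.
#' @return Integer matrix with columns `i`, `j`: 1-based row/column indices
#'   of the peaks (zero rows when there is none).
#' @export
find_local_maxima <- function(plane) {
  m <- if (inherits(plane, "plane_image")) plane$intensities else plane
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 3L)
    stop("plane must be at least 3 x 3 pixels")
  nr <- nrow(m); nc <- ncol(m)
  core <- m[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  strict <- matrix(TRUE, nr - 2L, nc - 2L)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- m[(2L + di):(nr - 1L + di), (2L + dj):(nc - 1L + dj), drop = FALSE]
    strict <- strict & (core > nb)
  }
  idx <- which(strict, arr.ind = TRUE)
  cbind(i = as.integer(idx[, 1] + 1L), j = as.integer(idx[, 2] + 1L))
}

#' Classify the size of a cluster by growing windows around its peak
#'
#' Starting from a strict local maximum, square windows of side
#' `2n + 1` (n = 1, 2, ...) centred on the peak are examined; the size class
#' is the largest `n` for which no pixel inside the window is strictly
#' brighter than the peak. Growth stops as soon as a brighter pixel enters
#' the window, when the window would cross the image border, or at the cap
#' `n_cap`; in the latter two cases the call is marked `capped` (size was not
#' resolved, only bounded). Like peak detection this uses intensity
#' comparisons only, never absolute values.
#'
#' @param plane a [plane_image] or matrix.
#' @param peak length-2 integer (row, column) of a strict local maximum, as
#'   returned by [find_local_maxima()].
#' @param n_cap maximum window radius in pixels (default 6, i.e. side 13).
#' @param size_convention `"side"` (default) reports the full odd window side
#'   `2n + 1` as the pixel size class; `"diameter2n"` reports `2n`, an
#'   alternative even-diameter convention.
#' @param low_contrast_k prominence threshold in robust noise units: a call
#'   is flagged low-contrast when the mean of its 3 x 3 core exceeds the
#'   median of the membrane-classified pixels (at or above an Otsu
#'   brightness threshold) of a surrounding annulus (Chebyshev radius
#'   `n_cap + 2` to `3 * n_cap`, wide enough to exclude the largest
#'   admissible cluster footprint) by less than `low_contrast_k` estimated
#'   noise standard deviations. Restricting the reference to membrane-bright
#'   pixels means calls at a membrane border or in empty background are
#'   compared against membrane brightness, not against the dark surround, so
#'   bright pixels popping out of noise or dim areas are flagged. This is a
#'   reproducible surrogate for the manual curation of false positives
#'   (bright pixels popping out of noise); calls are flagged, never dropped,
#'   here. `NULL` disables flagging.
#' @param noise_sd optional pre-computed robust noise scale of the plane
#'   (see [plane_noise_sd()]); estimated from the plane when `NULL`.
#' @param membrane_threshold optional pre-computed brightness threshold
#'   separating membrane from background (Otsu of the plane when `NULL`);
#'   used only by the low-contrast flag.
#' @return A one-row data.frame (a "cluster call") with columns `i`, `j`,
#'   `peak_value`, `n_max`, `side_px`, `capped`, `low_contrast`.
#' @export
estimate_cluster_size <- function(plane, peak, n_cap = 6L,
                                  size_convention = c("side", "diameter2n"),
                                  low_contrast_k = 2, noise_sd = NULL,
                                  membrane_threshold = NULL) {
  size_convention <- match.arg(size_convention)
  m <- if (inherits(plane, "plane_image")) plane$intensities else plane
  i <- as.integer(peak[1]); j <- as.integer(peak[2])
  nr <- nrow(m); nc <- ncol(m)
  if (i < 2L || j < 2L || i > nr - 1L || j > nc - 1L)
    stop("peak must be an interior pixel")
  v <- m[i, j]
  nb <- m[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
  if (any(nb[-5L] >= v))
    stop("peak is not a strict local maximum (contract violation)")
  n_cap <- as.integer(n_cap)
  stopifnot(n_cap >= 1L)
  n_max <- 0L
  capped <- FALSE
  for (n in seq_len(n_cap)) {
    i0 <- i - n; i1 <- i + n; j0 <- j - n; j1 <- j + n
    clipped <- i0 < 1L || j0 < 1L || i1 > nr || j1 > nc
    # a brighter pixel stops growth even in a border-clipped window: clipping
    # only ever hides out-of-image area, never an in-image brighter pixel
    if (any(m[max(i0, 1L):min(i1, nr), max(j0, 1L):min(j1, nc)] > v)) break
    if (clipped) {
      capped <- TRUE  # window truncated by the border: size bounded, not resolved
      break
    }
    n_max <- n
    if (n == n_cap) capped <- TRUE
  }
  lc <- FALSE
  if (!is.null(low_contrast_k) && is.finite(low_contrast_k)) {
    if (is.null(noise_sd)) noise_sd <- plane_noise_sd(m)
    if (is.null(membrane_threshold)) membrane_threshold <- .otsu_threshold(m)
    r_in <- n_cap + 2L; r_out <- 3L * n_cap
    ri <- max(1L, i - r_out):min(nr, i + r_out)
    rj <- max(1L, j - r_out):min(nc, j + r_out)
    w <- m[ri, rj]
    ann <- w[abs(ri - i) > r_in | rep(abs(rj - j) > r_in, each = length(ri))]
    bright <- ann[ann >= membrane_threshold]
    ref <- if (length(bright) >= 10L) stats::median(bright) else stats::median(ann)
    prominence <- mean(nb) - ref
    lc <- prominence < low_contrast_k * noise_sd
  }
  side <- if (size_convention == "side") 2L * n_max + 1L else 2L * n_max
  data.frame(i = i, j = j, peak_value = v, n_max = n_max, side_px = side,
             capped = capped, low_contrast = lc)
}

#' Detect and size all clusters in a projected membrane plane
#'
#' Convenience wrapper: runs [find_local_maxima()] then
#' [estimate_cluster_size()] for every peak and appends the physical
#' diameter from the lateral pixel size.
#'
#' @inheritParams estimate_cluster_size
#' @param plane a [plane_image] (pixel size needed for diameters).
#' @return data.frame of cluster calls with additional column `diameter_um`.
#' @export
call_clusters <- function(plane, n_cap = 6L,
                          size_convention = c("side", "diameter2n"),
                          low_contrast_k = 2) {
  stopifnot(inherits(plane, "plane_image"))
  size_convention <- match.arg(size_convention)
  noise_sd <- plane_noise_sd(plane$intensities)
  mthr <- if (is.null(low_contrast_k)) NULL else .otsu_threshold(plane$intensities)
  pk <- find_local_maxima(plane)
  calls <- if (nrow(pk) == 0L) {
    data.frame(i = integer(), j = integer(), peak_value = numeric(),
               n_max = integer(), side_px = integer(), capped = logical(),
               low_contrast = logical())
  } else {
    do.call(rbind, lapply(seq_len(nrow(pk)), function(k)
      estimate_cluster_size(plane, pk[k, ], n_cap = n_cap,
                            size_convention = size_convention,
                            low_contrast_k = low_contrast_k,
                            noise_sd = noise_sd, membrane_threshold = mthr)))
  }
  calls$diameter_um <- to_physical_diameter(calls$side_px, plane$pixel_size[1])
  calls
}

#' Gate cluster calls by pixel size class
#'
#' Retains calls whose size class lies in the configured pixel range and
#' whose window growth terminated inside the image (uncapped). The default
#' 5-9 pixel gate corresponds to physical diameters of about 0.45-0.80 µm at
#' 0.089 µm/px; smaller classes are single bright pixels, larger ones are
#' typically overlapping membrane sections rather than single clusters.
#'
#' @param calls data.frame of cluster calls.
#' @param min_side_px,max_side_px inclusive gates on `side_px`.
#' @param drop_low_contrast if `TRUE`, also drop calls flagged low-contrast
#'   (surrogate for the manual discarding of dim false positives); default
#'   `FALSE`.
#' @param suppress_overlaps if `TRUE` (default), a retained call whose
#'   size window overlaps the window of a brighter retained call is
#'   suppressed (non-maximum suppression): one cluster contributes one
#'   call even when a secondary maximum on its flank also passes the gate.
#' @return The retained subset of `calls`.
#' @export
filter_size_classes <- function(calls, min_side_px = 5L, max_side_px = 9L,
                                drop_low_contrast = FALSE,
                                suppress_overlaps = TRUE) {
  if (min_side_px > max_side_px) stop("min_side_px must not exceed max_side_px")
  keep <- calls$side_px >= min_side_px & calls$side_px <= max_side_px & !calls$capped
  if (drop_low_contrast) keep <- keep & !calls$low_contrast
  out <- calls[keep, , drop = FALSE]
  if (suppress_overlaps && nrow(out) > 1L && !is.null(out$peak_value)) {
    ord <- order(-out$peak_value)
    taken <- integer()
    for (k in ord) {
      di <- abs(out$i[taken] - out$i[k])
      dj <- abs(out$j[taken] - out$j[k])
      if (!any(pmax(di, dj) <= out$n_max[taken] + out$n_max[k])) taken <- c(taken, k)
    }
    out <- out[sort(taken), , drop = FALSE]
  }
  out
}

# Otsu threshold on an arbitrary-range intensity matrix.
.otsu_threshold <- function(m) {
  rng <- range(m)
  if (rng[2] <= rng[1]) stop("constant plane: Otsu threshold undefined")
  scaled <- (m - rng[1]) / (rng[2] - rng[1])
  EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * (rng[2] - rng[1]) + rng[1]
}

#' Robust noise scale of a plane
#'
#' Estimates the pixel-noise standard deviation from the median absolute
#' lag-1 horizontal intensity difference; structure (spots, edges) occupies
#' too few pixel pairs to move the median, so this tracks the noise floor.
#'
#' @param m intensity matrix (or [plane_image]).
#' @return Estimated noise standard deviation.
#' @export
plane_noise_sd <- function(m) {
  if (inherits(m, "plane_image")) m <- m$intensities
  dif <- abs(m[-1, ] - m[-nrow(m), ])
  stats::median(dif) * 1.4826 / sqrt(2)
}

#' Convert a pixel size class to a physical diameter
#'
#' @param side_px size class in pixels (>= 1).
#' @param lateral_pixel_size_um lateral pixel size in µm.
#' @return Diameter in µm at full precision (display rounding is left to the
#'   caller).
#' @export
to_physical_diameter <- function(side_px, lateral_pixel_size_um) {
  if (any(side_px < 1L)) stop("side_px must be >= 1")
  if (lateral_pixel_size_um <= 0) stop("pixel size must be positive")
  side_px * lateral_pixel_size_um
}

#' Estimate the membrane area of a projected plane by brightness thresholding
#'
#' The denominator for cluster densities: pixels at or above a brightness
#' threshold are counted as membrane and multiplied by the pixel area.
#' By default the threshold is chosen by Otsu's method on the plane
#' histogram; a user-supplied absolute threshold overrides it.
#'
#' @param plane a [plane_image].
#' @param threshold `"otsu"` (default) or an absolute intensity value.
#' @return Area in µm², with attribute `threshold` (the value used).
#' @export
estimate_membrane_area <- function(plane, threshold = "otsu") {
  stopifnot(inherits(plane, "plane_image"))
  m <- plane$intensities
  if (identical(threshold, "otsu")) {
    thr <- .otsu_threshold(m)
  } else {
    thr <- as.numeric(threshold)
    stopifnot(is.finite(thr))
  }
  n_above <- sum(m >= thr)
  if (n_above == 0L)
    stop("no pixels at or above threshold: membrane area (and density) undefined")
  area <- n_above * plane$pixel_size[1] * plane$pixel_size[2]
  attr(area, "threshold") <- thr
  area
}

#' Cluster density per membrane area
#'
#' @param n_retained number of size-gated cluster calls.
#' @param membrane_area_um2 membrane area in µm² (> 0).
#' @param roi_id optional ROI label.
#' @return One-row data.frame: `roi`, `n_retained`, `membrane_area_um2`,
#'   `density_per_um2`.
#' @export
cluster_density <- function(n_retained, membrane_area_um2, roi_id = NA_character_) {
  if (!is.finite(membrane_area_um2) || membrane_area_um2 <= 0)
    stop("membrane area must be positive")
  if (n_retained < 0) stop("n_retained must be non-negative")
  data.frame(roi = as.character(roi_id), n_retained = as.integer(n_retained),
             membrane_area_um2 = as.numeric(membrane_area_um2),
             density_per_um2 = n_retained / membrane_area_um2)
}

#' Quantify one membrane ROI end to end
#'
#' Projects the ROI, detects and sizes clusters, gates them by pixel size
#' class and reports the density over the thresholded membrane area.
#'
#' @inheritParams project_membrane
#' @inheritParams filter_size_classes
#' @inheritParams estimate_cluster_size
#' @param area_threshold threshold for [estimate_membrane_area()].
#' @return List with `calls` (all calls), `retained`, and `density` (one-row
#'   data.frame as from [cluster_density()], plus `n_peaks`).
#' @export
quantify_membrane_roi <- function(stack, roi, min_side_px = 5L, max_side_px = 9L,
                                  n_cap = 6L, drop_low_contrast = FALSE,
                                  low_contrast_k = 2,
                                  area_threshold = "otsu") {
  plane <- project_membrane(stack, roi)
  calls <- call_clusters(plane, n_cap = n_cap, low_contrast_k = low_contrast_k)
  retained <- filter_size_classes(calls, min_side_px, max_side_px,
                                  drop_low_contrast = drop_low_contrast)
  area <- estimate_membrane_area(plane, area_threshold)
  dens <- cluster_density(nrow(retained), as.numeric(area), roi_id = roi$id)
  dens$n_peaks <- nrow(calls)
  list(plane = plane, calls = calls, retained = retained, density = dens)
}
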