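# Immunogold particle analysis: 55 nm single-linkage grouping,
# scattered/doublet/cluster classification, Feret diameters, polar-domain
# band statistics and the particles-per-cluster gradient.

#' Construct a planar gold-particle set
#'
#' Coordinates are stored in nanometres. The cell geometry carries the
#' apical and basal edge positions along the cell axis; the axial coordinate
#' of a particle is its signed projection onto the unit vector pointing from
#' the apical towards the basal edge, with 0 at the apical edge.
#'
#' @param x_nm,y_nm numeric particle coordinates in nm.
#' @param analyzed_region optional polygon (matrix with columns x, y in nm,
#'   vertices in order, not closed) delimiting the analysed membrane area.
#' @param apical_edge,basal_edge length-2 points (nm) on the apical and
#'   basal cell edges, defining the polarity axis. May be `NULL` when no
#'   domain assignment is needed.
#' @param id optional particle identifiers (default 1..n).
#' @param source `"frl"` (freeze-fracture replica labeling, en-face views) or
#'   `"iem"` (thin-section immunogold, membrane profiles).
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(x_nm, y_nm, analyzed_region = NULL,
                         apical_edge = NULL, basal_edge = NULL,
                         id = NULL, source = c("frl", "iem")) {
  source <- match.arg(source)
  x_nm <- as.numeric(x_nm); y_nm <- as.numeric(y_nm)
  if (length(x_nm) != length(y_nm)) stop("x_nm and y_nm lengths differ")
  if (anyNA(x_nm) || anyNA(y_nm)) stop("coordinates must be finite")
  if (is.null(id)) id <- seq_along(x_nm)
  if (!is.null(analyzed_region)) {
    analyzed_region <- as.matrix(analyzed_region)
    if (ncol(analyzed_region) != 2L || nrow(analyzed_region) < 3L)
      stop("analyzed_region must be a polygon matrix with columns x, y")
  }
  if (!is.null(apical_edge) || !is.null(basal_edge)) {
    apical_edge <- as.numeric(apical_edge); basal_edge <- as.numeric(basal_edge)
    if (length(apical_edge) != 2L || length(basal_edge) != 2L)
      stop("edges must be length-2 points (nm)")
    if (isTRUE(all.equal(apical_edge, basal_edge)))
      stop("apical and basal edges must differ")
  }
  structure(list(id = id, x_nm = x_nm, y_nm = y_nm,
                 analyzed_region = analyzed_region,
                 apical_edge = apical_edge, basal_edge = basal_edge,
                 source = source),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles (%s)%s\n", length(x$x_nm),
              toupper(x$source),
              if (is.null(x$analyzed_region)) "" else
                sprintf(", analysed region %.1f um^2", polygon_area(x$analyzed_region) / 1e6)))
  invisible(x)
}

#' @export
length.particle_set <- function(x) length(x$x_nm)

#' Axial position of particles along the apical-basal axis
#'
#' @param particles a [particle_set] with defined cell edges.
#' @return Numeric vector: signed distance (nm) from the apical edge along
#'   the apical-to-basal unit vector.
#' @export
axial_position <- function(particles) {
  if (is.null(particles$apical_edge))
    stop("particle_set has no cell axis (apical/basal edges undefined)")
  u <- particles$basal_edge - particles$apical_edge
  u <- u / sqrt(sum(u^2))
  (particles$x_nm - particles$apical_edge[1]) * u[1] +
    (particles$y_nm - particles$apical_edge[2]) * u[2]
}

# Union-find with path halving; roots returned for each element.
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Single-linkage partition of planar points at Euclidean threshold dmax,
# using a grid of dmax-sized cells so only 3x3 neighbourhoods are scanned.
.link_points <- function(x, y, dmax) {
  n <- length(x)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  parent <- seq_len(n)
  cx <- floor((x - min(x)) / dmax); cy <- floor((y - min(y)) / dmax)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_of <- function(a, b) cells[[paste(a, b)]]
  d2max <- dmax * dmax
  for (nm in names(cells)) {
    ab <- as.numeric(strsplit(nm, " ", fixed = TRUE)[[1]])
    here <- cells[[nm]]
    # neighbours: same cell plus the 8 surrounding cells (scan half to avoid
    # duplicating pairs; same-cell pairs handled by i<j)
    cand <- here
    for (off in list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))) {
      nb <- cells[[paste(ab[1] + off[1], ab[2] + off[2])]]
      if (!is.null(nb)) cand <- c(cand, nb)
    }
    nh <- length(here)
    for (ii in seq_len(nh)) {
      i <- here[ii]
      js <- if (ii < nh) c(here[(ii + 1L):nh], cand[-seq_len(nh)]) else cand[-seq_len(nh)]
      if (length(js) == 0L) next
      d2 <- (x[js] - x[i])^2 + (y[js] - y[i])^2
      for (j in js[d2 <= d2max]) {
        ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
        # path compression writes are local; refresh parent via find below
        parent[i] <- ri; parent[j] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Group particles by single-linkage distance clustering
#'
#' Two particles are linked when their centre-to-centre distance is at most
#' `dmax_nm` (inclusive at the threshold); groups are the connected
#' components of the resulting graph, so chains of sub-threshold steps merge
#' into one group regardless of overall extent. The default 55 nm reflects
#' label geometry: with the epitope-to-gold displacement of up to about
#' 20 nm on each label, two labels of one molecular assembly can sit up to
#' roughly this far apart (the construction equivalent to overlapping
#' 27.5 nm-radius circles around particle centres).
#'
#' @param particles a [particle_set] (or a 2-column matrix of nm coordinates).
#' @param dmax_nm linkage threshold in nm (> 0), default 55.
#' @return data.frame with one row per particle: `particle` (index), `group`
#'   (group id, 1-based, in order of first member).
#' @export
link_particles <- function(particles, dmax_nm = 55) {
  stopifnot(dmax_nm > 0)
  if (inherits(particles, "particle_set")) {
    x <- particles$x_nm; y <- particles$y_nm
  } else {
    m <- as.matrix(particles); x <- m[, 1]; y <- m[, 2]
  }
  grp <- .link_points(x, y, dmax_nm)
  data.frame(particle = seq_along(x), group = grp)
}

#' Summarise linkage groups
#'
#' @param particles the [particle_set] that was linked.
#' @param membership data.frame from [link_particles()].
#' @param gold_diameter_nm optional physical label diameter added to the
#'   centre-to-centre Feret diameter (default 0; singletons then have
#'   diameter `gold_diameter_nm`).
#' @return data.frame with one row per group: `group`, `size`, `class`
#'   (`scattered`/`doublet`/`cluster` for 1/2/>=3 members), `diameter_nm`,
#'   `centroid_x_nm`, `centroid_y_nm`.
#' @export
summarize_groups <- function(particles, membership, gold_diameter_nm = 0) {
  x <- particles$x_nm; y <- particles$y_nm
  gs <- split(membership$particle, membership$group)
  out <- lapply(names(gs), function(g) {
    idx <- gs[[g]]
    data.frame(group = as.integer(g), size = length(idx),
               class = group_class(length(idx)),
               diameter_nm = group_diameter(cbind(x[idx], y[idx]), gold_diameter_nm),
               centroid_x_nm = mean(x[idx]), centroid_y_nm = mean(y[idx]))
  })
  if (length(out) == 0L)
    return(data.frame(group = integer(), size = integer(), class = character(),
                      diameter_nm = numeric(), centroid_x_nm = numeric(),
                      centroid_y_nm = numeric()))
  do.call(rbind, out)
}

group_class <- function(size) {
  ifelse(size >= 3L, "cluster", ifelse(size == 2L, "doublet", "scattered"))
}

#' Feret diameter of a particle group
#'
#' Maximum pairwise centre-to-centre distance, optionally inflated by the
#' physical gold-label diameter; a singleton has centre-to-centre extent 0.
#'
#' @param coords matrix of member coordinates (nm, columns x, y).
#' @param gold_diameter_nm label diameter added to the result (default 0).
#' @return Diameter in nm.
#' @export
group_diameter <- function(coords, gold_diameter_nm = 0) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty group")
  if (nrow(coords) == 1L) return(gold_diameter_nm)
  max(stats::dist(coords)) + gold_diameter_nm
}

#' Classify particles into scattered / doublet / cluster fractions
#'
#' Fractions are percentages of particles (not of groups): a cluster of five
#' contributes five particles to the clustered fraction. The three fractions
#' sum to 100%.
#'
#' @param groups data.frame from [summarize_groups()] (needs `size`, `class`).
#' @return List with `group_counts` (named integer: groups per class),
#'   `particle_counts` (particles per class), `particle_fractions`
#'   (percentages), `n_particles`. For empty input the fractions are `NaN`
#'   and `empty` is `TRUE`.
#' @export
classify_particle_groups <- function(groups) {
  classes <- c("scattered", "doublet", "cluster")
  gc <- vapply(classes, function(cl) sum(groups$class == cl), integer(1))
  pc <- vapply(classes, function(cl) sum(groups$size[groups$class == cl]), integer(1))
  n <- sum(pc)
  list(group_counts = gc, particle_counts = pc,
       particle_fractions = if (n > 0) 100 * pc / n else rep(NaN, 3L),
       n_particles = n, empty = n == 0L)
}

#' Area of a polygon (shoelace formula)
#'
#' @param poly matrix of vertices (columns x, y), in order, not closed.
#' @return Absolute area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Clip a polygon with the half-plane {p : a . p <= b} (Sutherland-Hodgman).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(), 0L, 2L)
  val <- poly %*% a - b
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- poly[k, ]; p2 <- poly[k2, ]
    in1 <- val[k] <= 0; in2 <- val[k2] <= 0
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      t <- val[k] / (val[k] - val[k2])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

# Area (nm^2) of the part of `poly` whose axial coordinate (projection onto
# unit vector u with origin at `origin`) lies in [lo, hi].
band_area <- function(poly, origin, u, lo, hi) {
  shifted <- sweep(poly, 2, origin)
  clipped <- clip_halfplane(shifted, u, hi)
  clipped <- clip_halfplane(clipped, -u, -lo)
  if (nrow(clipped) < 3L) return(0)
  polygon_area(clipped)
}

#' Assign particles to apical, central and basal membrane domains
#'
#' Bands of width `band_um` along the apical-basal axis: particles within
#' `band_um` of the apical edge are apical, within `band_um` of the basal
#' edge basal, and within a `band_um`-wide band centred on the midline
#' central; everything else is unassigned. Per-domain particle and cluster
#' densities use the area of the analysed-region polygon intersected with
#' each band.
#'
#' @param particles a [particle_set] with cell edges (and, for densities, an
#'   analysed-region polygon).
#' @param groups optional group table from [summarize_groups()] (for
#'   cluster densities and per-domain fractions); groups are assigned by
#'   their centroid.
#' @param band_um band width in µm (default 2).
#' @return List with `labels` (per-particle domain factor), `quant`
#'   (data.frame per domain: counts, band area µm², particle density,
#'   cluster count/density, mean particles per cluster), and `bands`
#'   (axial intervals used, nm).
#' @export
assign_membrane_domains <- function(particles, groups = NULL, band_um = 2) {
  stopifnot(band_um > 0)
  ax <- axial_position(particles)
  L <- sqrt(sum((particles$basal_edge - particles$apical_edge)^2))
  band_nm <- band_um * 1000
  if (L <= 2 * band_nm)
    stop("cell length must exceed twice the band width (apical/basal bands overlap)")
  mid <- L / 2
  bands <- list(apical = c(0, band_nm),
                central = c(mid - band_nm / 2, mid + band_nm / 2),
                basal = c(L - band_nm, L))
  lab <- rep("unassigned", length(ax))
  lab[ax >= bands$central[1] & ax <= bands$central[2]] <- "central"
  lab[ax <= band_nm] <- "apical"              # apical/basal take precedence
  lab[ax >= L - band_nm] <- "basal"
  lab <- factor(lab, levels = c("apical", "central", "basal", "unassigned"))

  quant <- NULL
  if (!is.null(particles$analyzed_region)) {
    u <- (particles$basal_edge - particles$apical_edge) / L
    rows <- lapply(names(bands), function(dn) {
      b <- bands[[dn]]
      a_um2 <- band_area(particles$analyzed_region, particles$apical_edge, u,
                         b[1], b[2]) / 1e6
      n_p <- sum(lab == dn)
      row <- data.frame(domain = dn, n_particles = n_p, band_area_um2 = a_um2,
                        particle_density_per_um2 = if (a_um2 > 0) n_p / a_um2 else NA_real_,
                        n_clusters = NA_integer_, cluster_density_per_um2 = NA_real_,
                        mean_particles_per_cluster = NA_real_)
      if (!is.null(groups)) {
        gax <- .axial_of_points(groups$centroid_x_nm, groups$centroid_y_nm, particles)
        inb <- gax >= b[1] & gax <= b[2] & groups$class == "cluster"
        row$n_clusters <- sum(inb)
        row$cluster_density_per_um2 <- if (a_um2 > 0) sum(inb) / a_um2 else NA_real_
        row$mean_particles_per_cluster <- if (any(inb)) mean(groups$size[inb]) else NA_real_
      }
      row
    })
    quant <- do.call(rbind, rows)
  }
  list(labels = lab, quant = quant, bands = bands)
}

.axial_of_points <- function(px, py, particles) {
  u <- particles$basal_edge - particles$apical_edge
  u <- u / sqrt(sum(u^2))
  (px - particles$apical_edge[1]) * u[1] + (py - particles$apical_edge[2]) * u[2]
}

#' Particles-per-cluster profile along the polarity axis
#'
#' Bins clusters (groups of three or more) by the axial distance of their
#' centroid from the apical edge and reports, per bin, the number of
#' clusters and the mean number of particles per cluster. Bins with no
#' cluster are reported with `NA`, not zero, for the mean.
#'
#' @param groups group table from [summarize_groups()].
#' @param particles the [particle_set] (for the cell axis).
#' @param bin_um bin width in µm (> 0).
#' @return data.frame: `bin_start_um`, `bin_end_um`, `n_clusters`,
#'   `mean_particles_per_cluster`.
#' @export
particles_per_cluster_gradient <- function(groups, particles, bin_um = 1) {
  stopifnot(bin_um > 0)
  cl <- groups[groups$class == "cluster", , drop = FALSE]
  if (nrow(cl) == 0L)
    return(data.frame(bin_start_um = numeric(), bin_end_um = numeric(),
                      n_clusters = integer(), mean_particles_per_cluster = numeric()))
  ax_um <- .axial_of_points(cl$centroid_x_nm, cl$centroid_y_nm, particles) / 1000
  L_um <- sqrt(sum((particles$basal_edge - particles$apical_edge)^2)) / 1000
  breaks <- seq(0, ceiling(L_um / bin_um) * bin_um, by = bin_um)
  bin <- cut(pmin(pmax(ax_um, 0), max(breaks) - 1e-9), breaks, right = FALSE)
  n <- as.integer(table(bin))
  mn <- tapply(cl$size, bin, mean)
  data.frame(bin_start_um = breaks[-length(breaks)], bin_end_um = breaks[-1],
             n_clusters = n,
             mean_particles_per_cluster = as.numeric(mn))
}

#' Per-image cluster-count summary for thin-section immunogold data
#'
#' Thin sections show membranes as profiles; each image contributes one
#' cluster count (groups of three or more particles). Reports mean and SD of
#' counts per image and, when membrane profile lengths are supplied, counts
#' per µm of profile.
#'
#' @param counts integer vector of cluster counts, one per image.
#' @param profile_lengths_um optional membrane profile length per image (µm).
#' @return List with `n_images`, `mean_per_image`, `sd_per_image` and, when
#'   lengths are given, `per_um` (vector), `mean_per_um`, `sd_per_um`.
#' @export
iem_profile_summary <- function(counts, profile_lengths_um = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("need at least one image")
  out <- list(n_images = length(counts),
              mean_per_image = mean(counts),
              sd_per_image = if (length(counts) > 1L) stats::sd(counts) else 0)
  if (!is.null(profile_lengths_um)) {
    stopifnot(length(profile_lengths_um) == length(counts), all(profile_lengths_um > 0))
    pu <- counts / profile_lengths_um
    out$per_um <- pu
    out$mean_per_um <- mean(pu)
    out$sd_per_um <- if (length(pu) > 1L) stats::sd(pu) else 0
  }
  out
}

#' Detect gold particles in a calibrated electron micrograph
#'
#' Connected components (8-connectivity) of the thresholded image, filtered
#' by component pixel area, are reported as centroids in nm. This mirrors
#' the usual manual-threshold + particle-analysis workflow on replica
#' images, where gold labels are small high-contrast blobs.
#'
#' @param image numeric matrix of intensities.
#' @param scale_nm_per_px physical calibration (> 0).
#' @param intensity_threshold pixels at or above this value are foreground.
#' @param area_range_px inclusive component-size range in pixels kept as
#'   particles (default `c(1, Inf)`).
#' @param ... passed to [particle_set()] (geometry, source).
#' @return A [particle_set] of component centroids (nm). Empty, with a
#'   warning, when no component passes the area filter.
#' @export
detect_gold_particles <- function(image, scale_nm_per_px, intensity_threshold,
                                  area_range_px = c(1, Inf), ...) {
  stopifnot(is.matrix(image), scale_nm_per_px > 0)
  fg <- which(image >= intensity_threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    warning("no foreground pixels at threshold")
    return(particle_set(numeric(), numeric(), ...))
  }
  # 8-connectivity = single linkage of pixel centres at Euclidean 1.5
  comp <- .link_points(as.numeric(fg[, 1]), as.numeric(fg[, 2]), 1.5)
  keep_centroids <- lapply(split(seq_len(nrow(fg)), comp), function(idx) {
    if (length(idx) < area_range_px[1] || length(idx) > area_range_px[2]) return(NULL)
    c(mean(fg[idx, 1]), mean(fg[idx, 2]))
  })
  keep_centroids <- do.call(rbind, keep_centroids)
  if (is.null(keep_centroids)) {
    warning("no connected component within the area range")
    return(particle_set(numeric(), numeric(), ...))
  }
  # centre-of-pixel convention: pixel (i, j) sits at ((i - 0.5), (j - 0.5)) px
  particle_set((keep_centroids[, 1] - 0.5) * scale_nm_per_px,
               (keep_centroids[, 2] - 0.5) * scale_nm_per_px, ...)
}
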