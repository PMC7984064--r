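# File formats: single-channel TIFF stacks (pages = z-slices, rows = y,
# columns = x) with a JSON sidecar for voxel sizes, particle CSVs (id, x_nm,
# y_nm) with a JSON geometry file, and ROI JSON.

#' Write an image stack to a single-channel TIFF with a JSON sidecar
#'
#' Pages are z-slices (rows = y, columns = x); 32-bit float samples.
#' Voxel sizes and the intensity scale are written to `<path>.json`.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(d[3]), function(z) t(stack$data[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size,
                            intensity_scale = scale,
                            axes = "ZYX"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-channel TIFF stack
#'
#' Accepts the layout written by [write_stack()] (pages = z, rows = y,
#' columns = x). Voxel sizes are taken from the `<path>.json` sidecar unless
#' overridden; RGB/multi-sample TIFFs are rejected.
#'
#' @param path TIFF path.
#' @param voxel_size optional length-3 override (µm per voxel, x/y/z).
#' @return An [image_stack].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    stop("multi-sample (e.g. RGB) TIFF: the stack must be single-channel")
  sidecar <- paste0(path, ".json")
  scale <- 1
  if (is.null(voxel_size)) {
    if (!file.exists(sidecar))
      stop(sprintf(paste("no voxel calibration: provide `voxel_size` or a sidecar",
                         "'%s' with field voxel_size_um"), sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$voxel_size_um))
      stop(sprintf("sidecar '%s' lacks voxel_size_um", sidecar))
    voxel_size <- as.numeric(meta$voxel_size_um)
    if (!is.null(meta$intensity_scale)) scale <- as.numeric(meta$intensity_scale)
  } else if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_scale)) scale <- as.numeric(meta$intensity_scale)
  }
  vol <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]]) * scale
  image_stack(vol, voxel_size)
}

#' Write a particle set to CSV plus a geometry JSON
#'
#' @param particles a [particle_set].
#' @param csv_path output CSV (columns id, x_nm, y_nm).
#' @param geometry_path output JSON (analysed region polygon, cell edges,
#'   source).
#' @return `csv_path`, invisibly.
#' @export
write_particles <- function(particles, csv_path, geometry_path) {
  stopifnot(inherits(particles, "particle_set"))
  utils::write.csv(data.frame(id = particles$id, x_nm = particles$x_nm,
                              y_nm = particles$y_nm),
                   csv_path, row.names = FALSE)
  geo <- list(source = particles$source)
  if (!is.null(particles$analyzed_region))
    geo$analyzed_region_nm <- apply(particles$analyzed_region, 1, as.numeric,
                                    simplify = FALSE)
  if (!is.null(particles$apical_edge)) {
    geo$apical_edge_nm <- particles$apical_edge
    geo$basal_edge_nm <- particles$basal_edge
  }
  jsonlite::write_json(geo, geometry_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

# Ray-casting point-in-polygon (boundary-tolerant towards inclusion).
.in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  # accept points within eps of the bounding box edges (common after clipping)
  inside | (px >= min(poly[, 1]) - eps & px <= max(poly[, 1]) + eps &
              py >= min(poly[, 2]) - eps & py <= max(poly[, 2]) + eps &
              .on_boundary(px, py, poly, eps))
}

.on_boundary <- function(px, py, poly, eps) {
  n <- nrow(poly)
  on <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
      max((bx - ax)^2 + (by - ay)^2, eps)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (ax + t * (bx - ax) - px)^2 + (ay + t * (by - ay) - py)^2
    on <- on | d2 <= eps^2
    j <- i
  }
  on
}

#' Read a particle CSV and geometry JSON into a particle set
#'
#' The CSV must have columns `id`, `x_nm`, `y_nm`; malformed (non-numeric or
#' missing) rows are rejected with their line numbers. When the geometry
#' declares an analysed region, particles outside it are rejected with their
#' ids listed.
#'
#' @param csv_path particle CSV.
#' @param geometry_path geometry JSON (as written by [write_particles()]);
#'   optional.
#' @return A [particle_set].
#' @export
read_particles <- function(csv_path, geometry_path = NULL) {
  df <- utils::read.csv(csv_path, colClasses = "character")
  need <- c("id", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("particle CSV must have columns id, x_nm, y_nm")
  x <- suppressWarnings(as.numeric(df$x_nm))
  y <- suppressWarnings(as.numeric(df$y_nm))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0)
    stop(sprintf("malformed particle rows (CSV lines %s)",
                 paste(bad + 1L, collapse = ", ")))
  region <- apical <- basal <- NULL
  source <- "frl"
  if (!is.null(geometry_path)) {
    geo <- jsonlite::read_json(geometry_path, simplifyVector = TRUE)
    if (!is.null(geo$source)) source <- geo$source
    if (!is.null(geo$analyzed_region_nm)) {
      region <- geo$analyzed_region_nm
      if (is.list(region)) region <- do.call(rbind, region)
      region <- matrix(as.numeric(region), ncol = 2L)
    }
    if (!is.null(geo$apical_edge_nm)) {
      apical <- as.numeric(geo$apical_edge_nm)
      basal <- as.numeric(geo$basal_edge_nm)
    }
  }
  if (!is.null(region)) {
    out <- !.in_polygon(x, y, region)
    if (any(out))
      stop(sprintf("particles outside the analysed region: %s",
                   paste(df$id[out], collapse = ", ")))
  }
  particle_set(x, y, analyzed_region = region, apical_edge = apical,
               basal_edge = basal, id = df$id, source = source)
}

#' Read membrane ROIs from a JSON file
#'
#' Expected layout: an array of objects with fields `id`, `bounds` (object
#' with `x`, `y`, `z`, each a 0-based half-open `[start, end]` pair),
#' `projection_axis`, `polarity_label`, `cell_id`.
#'
#' @param path JSON file.
#' @return List of [membrane_roi]s.
#' @export
read_rois <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(spec, function(r) {
    b <- rbind(unlist(r$bounds$x), unlist(r$bounds$y), unlist(r$bounds$z))
    membrane_roi(id = r$id, bounds = b,
                 projection_axis = r$projection_axis %||% "z",
                 polarity_label = r$polarity_label %||% "unspecified",
                 cell_id = r$cell_id %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a string, reported as 8 hex digits; used to tie
# output files to the configuration that produced them.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    hx <- bitwXor(as.integer(h %% 2147483648), b)
    h <- hx + (h >= 2147483648) * 2147483648
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves to stay within exact double arithmetic
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
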