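# Apical-to-lateral polarity index from confocal stacks.

#' Apical-to-lateral membrane signal ratio for one cell
#'
#' The polarity index: mean voxel intensity over the apical membrane ROI
#' divided by the mean over the lateral membrane ROI, optionally after
#' subtracting the mean of a background ROI from both. The ratio is
#' invariant under multiplying all intensities by a positive constant, and
#' the background-subtracted ratio additionally under adding a constant.
#'
#' @param stack an [image_stack].
#' @param apical_roi,lateral_roi [membrane_roi]s within the stack.
#' @param background_roi optional [membrane_roi] for background estimation.
#' @return One-row data.frame: `cell_id`, `apical_mean`, `lateral_mean`,
#'   `background_mean` (`NA` when not used), `ratio`.
#' @export
apical_lateral_ratio <- function(stack, apical_roi, lateral_roi,
                                 background_roi = NULL) {
  roi_mean <- function(roi) {
    .check_roi_in_stack(stack, roi)
    b <- roi$bounds
    mean(stack$data[(b[1, 1] + 1L):b[1, 2],
                    (b[2, 1] + 1L):b[2, 2],
                    (b[3, 1] + 1L):b[3, 2]])
  }
  a <- roi_mean(apical_roi)
  l <- roi_mean(lateral_roi)
  bg <- if (is.null(background_roi)) NA_real_ else roi_mean(background_roi)
  denom <- if (is.na(bg)) l else l - bg
  if (denom <= 0)
    stop("lateral mean (after background subtraction) must be positive")
  num <- if (is.na(bg)) a else a - bg
  data.frame(cell_id = apical_roi$cell_id, apical_mean = a, lateral_mean = l,
             background_mean = bg, ratio = num / denom)
}

#' Aggregate per-cell polarity ratios
#'
#' Ratios are computed per cell and then averaged across cells, so every
#' cell carries equal weight regardless of membrane size.
#'
#' @param per_cell data.frame of rows from [apical_lateral_ratio()].
#' @return List with `n_cells`, `mean_ratio`, `sd_ratio`, `per_cell`.
#' @export
aggregate_polarity <- function(per_cell) {
  stopifnot(nrow(per_cell) >= 1L)
  list(n_cells = nrow(per_cell),
       mean_ratio = mean(per_cell$ratio),
       sd_ratio = if (nrow(per_cell) > 1L) stats::sd(per_cell$ratio) else 0,
       per_cell = per_cell)
}
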