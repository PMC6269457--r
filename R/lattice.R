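# Regular-lattice comparator: square windows on a regular grid, unweighted,
# sharing the texture code path with the polar sampler so downstream
# differences are attributable to sampling/weighting only.

#' Build a regular lattice of square windows inside the breast
#'
#' Lattice centers are spaced `spacing_mm` apart in both directions; each
#' window is a square of side `window_mm` clipped to the breast. Windows whose
#' breast coverage falls below `region_min_coverage` (or below the minimum
#' pixel count) are dropped.
#'
#' @param breast_mask logical breast mask (pectoralis excluded).
#' @param spacing_mm,window_mm lattice geometry in mm.
#' @param pixel_spacing_mm pixel spacing (mm).
#' @param region_min_coverage,region_min_pixels retention thresholds.
#' @return `lattice_grid`: `points` (data.frame row, col, coverage),
#'   `pixel_idx` (list of in-breast window pixel indices), geometry fields.
#' @export
build_lattice_grid <- function(breast_mask, spacing_mm, window_mm, pixel_spacing_mm,
                               region_min_coverage = 0.5, region_min_pixels = 25L) {
  nr <- nrow(breast_mask); nc <- ncol(breast_mask)
  s_px <- max(1, round(spacing_mm / pixel_spacing_mm))
  w_px <- max(2, round(window_mm / pixel_spacing_mm))
  h <- w_px %/% 2
  rows <- seq(1 + h, nr - h, by = s_px)
  cols <- seq(1 + h, nc - h, by = s_px)
  pts <- expand.grid(row = rows, col = cols)
  keep <- logical(nrow(pts)); cov <- numeric(nrow(pts))
  idx_list <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    r <- pts$row[i]; c <- pts$col[i]
    sub <- breast_mask[(r - h):(r - h + w_px - 1), (c - h):(c - h + w_px - 1)]
    n_in <- sum(sub)
    cov[i] <- n_in / (w_px * w_px)
    if (cov[i] >= region_min_coverage && n_in >= region_min_pixels) {
      keep[i] <- TRUE
      w <- which(sub)
      rr <- (w - 1) %% w_px + (r - h)
      cc <- (w - 1) %/% w_px + (c - h)
      idx_list[[i]] <- (cc - 1) * nr + rr
    }
  }
  structure(list(points = cbind(pts, coverage = cov)[keep, , drop = FALSE],
                 pixel_idx = idx_list[keep],
                 spacing_mm = spacing_mm, window_mm = window_mm,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "lattice_grid")
}

#' Lattice-based texture signature (comparator)
#'
#' Computes the same 34 texture descriptors on square windows centered on
#' regular lattice points within the breast (axis-aligned co-occurrence and
#' horizontal run-length directions), with all windows contributing equally;
#' the signature is the mean and standard deviation of each feature over
#' windows — 68 elements with the same labels as the anatomy signature.
#'
#' @param image a [mammogram] (used as-is; the lattice sampler needs no
#'   orientation standardization).
#' @param breast_mask logical breast mask with pectoralis excluded.
#' @param config a [run_config] (lattice geometry, gray levels, coverage).
#' @return a `texture_signature` (length 68) with attribute `sampler = "lattice"`.
#' @export
lattice_signature <- function(image, breast_mask, config = run_config()) {
  grid <- build_lattice_grid(breast_mask, config$lattice_spacing_mm,
                             config$lattice_window_mm, image$pixel_spacing_mm,
                             config$region_min_coverage, config$region_min_pixels)
  if (length(grid$pixel_idx) < 2)
    stop_mammotex("fewer than 2 retained lattice windows", "mammotex_grid_error")
  px <- image$pixels
  breast_range <- range(px[breast_mask])
  feats <- region_feature_matrix(px, grid$pixel_idx, NULL,
                                 config$gray_levels, breast_range)
  sig <- summarize_signature(list(features = feats),
                             subject_id = image$subject_id,
                             side_label = image$side_label)
  attr(sig, "sampler") <- "lattice"
  sig
}
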