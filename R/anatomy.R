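# Orientation standardization and the nipple-centered polar grid.
#
# Coordinate conventions: matrices are row-major, 1-based, origin top-left.
# Angles around the nipple are measured from the leftward direction (nipple
# toward chest wall), counterclockwise in the y-up sense, in (-180, 180].

# Forward-transform a (row, col) point: horizontal flip (if any), then
# rotation by `angle_deg` (counterclockwise, y-up) about the image center.
transform_point <- function(pt, transform) {
  nr <- transform$dims[1]; nc <- transform$dims[2]
  r <- pt[1]; c <- pt[2]
  if (transform$flip) c <- nc + 1 - c
  th <- transform$rotation_deg * pi / 180
  cr <- (nr + 1) / 2; ccen <- (nc + 1) / 2
  x <- c - ccen; y <- -(r - cr)
  c(cr - (sin(th) * x + cos(th) * y), ccen + (cos(th) * x - sin(th) * y))
}

# Apply / invert the standardization transform on a matrix.
apply_transform <- function(m, transform, fill = 0) {
  if (transform$flip) m <- flop(m)
  rotate_nn(m, transform$rotation_deg, fill = fill)
}

invert_transform <- function(m, transform, fill = 0) {
  m <- rotate_nn(m, -transform$rotation_deg, fill = fill)
  if (transform$flip) m <- flop(m)
  m
}

#' Standardize the orientation of a segmented mammogram
#'
#' Rotates the image so the pectoral boundary is vertical and mirrors right
#' breasts, so that in every standardized image the chest wall / pectoralis is
#' vertically aligned on the left. All masks are transformed identically
#' (nearest neighbour) and the transform is recorded. When no pectoral line
#' was found, only the laterality flip is applied and the result is flagged.
#'
#' @param image a [mammogram].
#' @param segmentation a `breast_segmentation` from [segment_all()].
#' @return list: `image` (standardized [mammogram]), `breast_mask`,
#'   `pectoralis_mask`, `cluster_labels`, `dense_mask`, `pect_col`
#'   (column of the vertical pectoral line, `NA` if absent), `transform`
#'   (`flip`, `rotation_deg`, `dims`), `flagged`.
#' @export
standardize_orientation <- function(image, segmentation) {
  line <- segmentation$pect_line
  flip <- image$laterality == "right"
  angle <- if (is.null(line)) 0 else line$angle_deg
  transform <- list(flip = flip, rotation_deg = angle, dims = dim(image$pixels))
  if (is.null(line)) warning("no pectoral line: identity rotation, flip by laterality")

  px <- apply_transform(image$pixels, transform, fill = 0)
  out <- list(
    image = mammogram(px, image$pixel_spacing_mm, "left", image$view,
                      image$subject_id, image$side_label),
    breast_mask = apply_transform(segmentation$breast_mask, transform, FALSE),
    pectoralis_mask = apply_transform(segmentation$pectoralis_mask, transform, FALSE),
    cluster_labels = apply_transform(segmentation$cluster_labels, transform, 0L),
    dense_mask = apply_transform(segmentation$dense_mask, transform, FALSE),
    transform = transform,
    flagged = is.null(line))
  out$pect_col <- if (is.null(line)) NA_real_ else transform_point(line$point, transform)[2]
  out
}

#' Locate the nipple on a standardized breast mask
#'
#' The nipple is approximated as the centroid of the rightmost breast region
#' bounded by an axis-aligned box of 1.5 cm side whose right edge sits at the
#' most anterior (rightmost) breast column, vertically centered on the breast
#' rows at that column.
#'
#' @param breast_mask logical matrix in standardized (chest-wall-left)
#'   orientation.
#' @param pixel_spacing_mm pixel spacing in mm.
#' @return numeric `(row, col)` of the nipple.
#' @export
locate_nipple <- function(breast_mask, pixel_spacing_mm) {
  if (!any(breast_mask))
    stop_mammotex("breast mask is empty", "mammotex_segmentation_error")
  nr <- nrow(breast_mask); nc <- ncol(breast_mask)
  cols_any <- which(colSums(breast_mask) > 0)
  c_max <- max(cols_any)
  box <- max(1, round(15 / pixel_spacing_mm))
  rows_at_cmax <- which(breast_mask[, c_max])
  r_mid <- mean(range(rows_at_cmax))
  r_lo <- max(1, ceiling(r_mid - box / 2)); r_hi <- min(nr, floor(r_mid + box / 2))
  c_lo <- max(1, c_max - box + 1)
  sub <- breast_mask[r_lo:r_hi, c_lo:c_max, drop = FALSE]
  rs <- row_grid(nrow(sub), ncol(sub))[sub] + r_lo - 1
  cs <- col_grid(nrow(sub), ncol(sub))[sub] + c_lo - 1
  c(mean(rs), mean(cs))
}

#' Define the CBA and UOA breast quadrants
#'
#' With `r_P` the perpendicular distance from the (vertical, standardized)
#' pectoral line to the nipple, the central breast area (CBA) is the breast at
#' radial distance `< f * r_P` from the nipple and the upper-outer area (UOA)
#' the breast above the nipple row at distance `> f * r_P`. Both exclude the
#' pectoralis. Without a pectoral line, `r_P` falls back to the distance from
#' the left image edge (flagged).
#'
#' @param nipple `(row, col)` from [locate_nipple()].
#' @param breast_mask standardized breast mask with pectoralis excluded.
#' @param pect_col column of the vertical pectoral line (or `NA`).
#' @param f CBA fraction, in `[0.5, 1]`.
#' @param pixel_spacing_mm pixel spacing (mm).
#' @return list: `cba_mask`, `uoa_mask`, `r_P_mm`, `flagged`.
#' @export
define_quadrants <- function(nipple, breast_mask, pect_col, f, pixel_spacing_mm) {
  if (f < 0.5 || f > 1)
    stop_mammotex("f must lie in [0.5, 1]", "mammotex_parameter_error")
  flagged <- is.na(pect_col)
  r_P_mm <- if (flagged) nipple[2] * pixel_spacing_mm
            else (nipple[2] - pect_col) * pixel_spacing_mm
  nr <- nrow(breast_mask); nc <- ncol(breast_mask)
  d_mm <- sqrt((row_grid(nr, nc) - nipple[1])^2 +
               (col_grid(nr, nc) - nipple[2])^2) * pixel_spacing_mm
  cba <- breast_mask & d_mm < f * r_P_mm
  uoa <- breast_mask & row_grid(nr, nc) < nipple[1] & d_mm > f * r_P_mm
  list(cba_mask = cba, uoa_mask = uoa, r_P_mm = r_P_mm, flagged = flagged)
}

#' Build the nipple-centered polar grid
#'
#' Rings are annuli `[i*D, (i+1)*D)` of nipple distance; sectors split the
#' angular span of the breast around the nipple into `N_s` equal wedges, with
#' `N_s = max(8, round(pi * r_P / D))` so that the arc length at radius `r_P`
#' is approximately `D`. Near-nipple regions are therefore smaller, giving the
#' retro-areolar region denser sampling. Every breast pixel belongs to exactly
#' one candidate region; regions with breast coverage below
#' `region_min_coverage` (relative to the analytic ring-sector area) or fewer
#' than `region_min_pixels` pixels are dropped from the retained set.
#'
#' @param nipple `(row, col)`.
#' @param breast_mask standardized breast mask with pectoralis excluded.
#' @param D_mm radius unit (mm).
#' @param r_P_mm nipple-pectoralis distance (mm).
#' @param pixel_spacing_mm pixel spacing (mm).
#' @param region_min_coverage,region_min_pixels retention thresholds.
#' @return `polar_grid` object: `regions` (data.frame with region_id, ring,
#'   sector, n_pixels, coverage, centroid_row, centroid_col, azimuth_deg,
#'   retained), `pixel_idx` (list of linear pixel indices per region, same
#'   order), `nipple`, `D_mm`, `n_sectors`, `span_rad`, `pixel_spacing_mm`.
#' @export
build_polar_grid <- function(nipple, breast_mask, D_mm, r_P_mm, pixel_spacing_mm,
                             region_min_coverage = 0.5, region_min_pixels = 25L) {
  if (D_mm <= 0) stop_mammotex("D_mm must be positive", "mammotex_parameter_error")
  nr <- nrow(breast_mask); nc <- ncol(breast_mask)
  idx <- which(breast_mask)
  if (length(idx) == 0)
    stop_mammotex("breast mask is empty", "mammotex_segmentation_error")
  r <- (idx - 1) %% nr + 1
  c <- (idx - 1) %/% nr + 1
  x <- c - nipple[2]; y <- -(r - nipple[1])
  d_mm <- sqrt(x^2 + y^2) * pixel_spacing_mm
  alpha <- atan2(y, x) - pi                      # 0 = leftward (toward chest wall)
  alpha <- ifelse(alpha <= -pi, alpha + 2 * pi, alpha)
  alpha[d_mm == 0] <- 0

  ring <- floor(d_mm / D_mm)
  pos <- d_mm > 0
  a_min <- min(alpha[pos]); a_max <- max(alpha[pos])
  n_sectors <- max(8L, round(pi * r_P_mm / D_mm))
  width <- max(a_max - a_min, 1e-9) / n_sectors
  sector <- pmin(n_sectors, pmax(1, floor((alpha - a_min) / width) + 1))

  key <- ring * (n_sectors + 1L) + sector
  groups <- split(seq_along(idx), key)
  n_reg <- length(groups)
  ring_g <- integer(n_reg); sector_g <- integer(n_reg)
  n_px <- integer(n_reg); cr <- numeric(n_reg); ccol <- numeric(n_reg)
  for (g in seq_len(n_reg)) {
    sel <- groups[[g]]
    ring_g[g] <- ring[sel[1]]; sector_g[g] <- sector[sel[1]]
    n_px[g] <- length(sel)
    cr[g] <- mean(r[sel]); ccol[g] <- mean(c[sel])
  }
  full_area_px <- width / 2 * ((ring_g + 1)^2 - ring_g^2) * D_mm^2 / pixel_spacing_mm^2
  coverage <- pmin(1, n_px / full_area_px)
  azimuth <- (a_min + (sector_g - 0.5) * width) * 180 / pi
  retained <- coverage >= region_min_coverage & n_px >= region_min_pixels
  if (!any(retained))
    stop_mammotex("polar grid retained zero regions", "mammotex_grid_error")

  regions <- data.frame(region_id = seq_len(n_reg), ring = ring_g,
                        sector = sector_g, n_pixels = n_px, coverage = coverage,
                        centroid_row = cr, centroid_col = ccol,
                        azimuth_deg = azimuth, retained = retained)
  pixel_idx <- unname(lapply(groups, function(sel) idx[sel]))
  structure(list(regions = regions, pixel_idx = pixel_idx, nipple = nipple,
                 D_mm = D_mm, n_sectors = n_sectors,
                 span_rad = c(a_min, a_max), pixel_spacing_mm = pixel_spacing_mm),
            class = "polar_grid")
}

#' @method print polar_grid
#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid> D = %.3g mm, %d sectors, %d/%d regions retained\n",
              x$D_mm, x$n_sectors, sum(x$regions$retained), nrow(x$regions)))
  invisible(x)
}

#' Run the full anatomy stage on a segmented image
#'
#' Standardizes orientation, locates the nipple, defines the CBA/UOA quadrants
#' and builds the polar grid.
#'
#' @param image a [mammogram].
#' @param segmentation from [segment_all()].
#' @param config a [run_config].
#' @return `breast_anatomy` object with the standardized image and masks,
#'   `nipple`, `r_P_mm`, `cba_mask`, `uoa_mask`, `grid` and the transform.
#' @export
analyze_anatomy <- function(image, segmentation, config = run_config()) {
  std <- standardize_orientation(image, segmentation)
  nipple <- locate_nipple(std$breast_mask, image$pixel_spacing_mm)
  quad <- define_quadrants(nipple, std$breast_mask, std$pect_col,
                           config$f, image$pixel_spacing_mm)
  grid <- build_polar_grid(nipple, std$breast_mask, config$D_mm, quad$r_P_mm,
                           image$pixel_spacing_mm,
                           config$region_min_coverage, config$region_min_pixels)
  structure(c(std, list(nipple = nipple, r_P_mm = quad$r_P_mm,
                        cba_mask = quad$cba_mask, uoa_mask = quad$uoa_mask,
                        f = config$f, grid = grid)),
            class = "breast_anatomy")
}
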