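# The 34 parenchymal texture descriptors (TF1..TF34), computed per region.
#
# TF1-13  gray-level histogram; TF14-20 co-occurrence (GLCM); TF21-31
# run-length; TF32-34 structural. Directional features (GLCM, run-length) use
# offsets aligned with the region's radial orientation on the polar grid, or
# the image axes for the lattice comparator.

#' Names of the 34 texture features
#'
#' @param descriptive if `TRUE`, return the human-readable feature names
#'   instead of the TF1..TF34 codes.
#' @return character vector of length 34 in the fixed pipeline order.
#' @export
tf_names <- function(descriptive = FALSE) {
  if (!descriptive) return(paste0("TF", 1:34))
  c("5th Percentile", "5th Mean", "95th Percentile", "95th Mean", "Entropy",
    "Kurtosis", "Max", "Mean", "Min", "Sigma", "Skewness", "Sum", "Median",
    "Contrast", "Correlation", "Homogeneity", "Energy", "Entropy (GLCM)",
    "Inverse Difference Moment", "Cluster Shade",
    "Short Run Emphasis", "Long Run Emphasis", "Gray Level Non-uniformity",
    "Run Length Non-uniformity", "Run Percentage", "Low Gray Level Run Emphasis",
    "High Gray Level Run Emphasis", "Short Run Low Gray Level Emphasis",
    "Short Run High Gray Level Emphasis", "Long Run Low Gray Level Emphasis",
    "Long Run High Gray Level Emphasis",
    "Edge-enhancing index", "Box-Counting Fractal Dimension",
    "Local Binary Pattern")
}

#' Quantize intensities into G gray levels
#'
#' Uniform binning of the interval `range` (normally the whole-breast
#' intensity range, so levels are comparable across regions) into `G` levels
#' 1..G. A zero-width range maps every pixel to level 1.
#'
#' @param x numeric vector or matrix of intensities.
#' @param range length-2 numeric, the quantization bounds.
#' @param G number of gray levels (>= 2).
#' @return integer vector/matrix of levels in 1..G.
#' @export
quantize <- function(x, range, G) {
  if (G < 2) stop_mammotex("G must be >= 2", "mammotex_parameter_error")
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    lv <- x * 0 + 1L
  } else {
    lv <- pmin(G, floor((x - lo) / (hi - lo) * G) + 1L)
    lv <- pmax(1L, lv)
  }
  storage.mode(lv) <- "integer"
  lv
}

#' Gray-level histogram features (TF1-TF13)
#'
#' First-order statistics of the region's intensity distribution: 5th/95th
#' percentiles and tail means, Shannon entropy of the G-bin histogram (bits),
#' excess kurtosis, max, mean, min, standard deviation, skewness, sum, median.
#' Skewness/kurtosis of a zero-variance region are 0 by convention.
#'
#' @param x numeric vector of region pixel intensities (>= 1 value).
#' @param levels optional integer vector of quantized levels matching `x`
#'   (used for the entropy bin counts); if omitted, `x` is quantized over its
#'   own range.
#' @param G gray levels for the entropy histogram.
#' @return named numeric vector TF1..TF13.
#' @export
histogram_features <- function(x, levels = NULL, G = 128L) {
  if (length(x) == 0) stop_mammotex("empty region", "mammotex_parameter_error")
  if (is.null(levels)) levels <- quantize(x, range(x), G)
  q <- quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  p <- tabulate(levels, nbins = G) / length(x)
  p <- p[p > 0]
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 1e-24 * max(1, m^2)) {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  out <- c(q[1], mean(x[x <= q[1]]), q[2], mean(x[x >= q[2]]),
           -sum(p * log2(p)), kurt, max(x), m, min(x),
           if (length(x) > 1) sd(x) else 0, skew, sum(x), median(x))
  names(out) <- tf_names()[1:13]
  out
}

#' Co-occurrence features (TF14-TF20)
#'
#' A single symmetric, normalized G x G co-occurrence matrix is accumulated
#' over all given distance-1 offsets; returns contrast, correlation,
#' homogeneity, energy, entropy (bits), inverse difference moment and cluster
#' shade (classical Haralick/Conners formulations, see the compiled kernel).
#' A region with no valid pixel pair gets the degenerate single-entry values
#' (contrast 0, correlation 0, homogeneity 1, energy 1, entropy 0, IDM 1,
#' shade 0).
#'
#' @param lv integer matrix of quantized levels 1..G, 0 outside the region.
#' @param G gray levels.
#' @param offsets integer matrix (k x 2) of `(dr, dc)` displacements.
#' @return named numeric vector TF14..TF20.
#' @export
glcm_features <- function(lv, G, offsets = rbind(c(0L, 1L), c(1L, 0L))) {
  offsets <- matrix(as.integer(offsets), ncol = 2)
  out <- cpp_glcm_features(lv, as.integer(G), offsets)
  names(out) <- tf_names()[14:20]
  out
}

#' Run-length features (TF21-TF31)
#'
#' Maximal constant-level runs of in-region pixels along one direction (runs
#' break at the region boundary); returns the 11 classical Galloway/Chu
#' statistics in Table-order: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
#' SRHGE, LRLGE, LRHGE.
#'
#' @param lv integer matrix of quantized levels 1..G, 0 outside the region.
#' @param G gray levels.
#' @param direction integer `(dr, dc)` run direction.
#' @return named numeric vector TF21..TF31.
#' @export
runlength_features <- function(lv, G, direction = c(0L, 1L)) {
  out <- cpp_rlm_features(lv, as.integer(G),
                          as.integer(direction[1]), as.integer(direction[2]))
  names(out) <- tf_names()[21:31]
  out
}

# Rotation-uniform 8-neighbour LBP indicator for interior pixels of `m`:
# TRUE where the circular binary code (neighbour >= center) has at most two
# 0/1 transitions. Border pixels are NA (no full neighbourhood).
lbp_uniform_mask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  ctr <- m[2:(nr - 1), 2:(nc - 1)]
  # 8 neighbours in circular order
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  s <- lapply(off, function(o)
    m[(2 + o[1]):(nr - 1 + o[1]), (2 + o[2]):(nc - 1 + o[2]), drop = FALSE] >= ctr)
  trans <- matrix(0L, nr - 2, nc - 2)
  for (k in 1:8) trans <- trans + (s[[k]] != s[[if (k == 8) 1 else k + 1]])
  out[2:(nr - 1), 2:(nc - 1)] <- trans <= 2
  out
}

# Box-counting fractal dimension of a binary pattern over dyadic box sizes.
box_counting_dimension <- function(bin) {
  rc <- which(bin, arr.ind = TRUE)
  if (nrow(rc) == 0) return(0)
  n <- min(nrow(bin), ncol(bin))
  sizes <- 2^(0:floor(log2(n / 2)))
  sizes <- sizes[sizes >= 1]
  if (length(sizes) < 3) return(0)
  big <- nrow(bin) + 1
  counts <- vapply(sizes, function(s) {
    length(unique(((rc[, 1] - 1) %/% s) * big + (rc[, 2] - 1) %/% s))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  unname(fit$coefficients[2])
}

# Fast first-order statistics from a pre-extracted pixel vector (same
# definitions as histogram_features; avoids repeated generic dispatch).
hist_features_fast <- function(x, lv, G) {
  n <- length(x)
  xs <- sort.int(x, method = "quick")
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  q05 <- q7(0.05); q95 <- q7(0.95)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  i_lo <- sum(xs <= q05); i_hi <- n - sum(xs >= q95) + 1
  m <- mean(x)
  d <- x - m
  v <- mean(d * d)
  if (v > 1e-24 * max(1, m^2)) {
    skew <- mean(d^3) / v^1.5
    kurt <- mean(d^4) / v^2 - 3
    sdev <- sqrt(v * n / (n - 1))
  } else {
    skew <- 0; kurt <- 0; sdev <- 0
  }
  p <- tabulate(lv, nbins = G) / n
  p <- p[p > 0]
  c(q05, mean(xs[seq_len(i_lo)]), q95, mean(xs[i_hi:n]),
    -sum(p * log2(p)), kurt, xs[n], m, xs[1],
    if (n > 1) sdev else 0, skew, sum(x), med)
}

#' Structural features (TF32-TF34)
#'
#' TF32: edge-enhancing index = mean 3x3 Sobel gradient magnitude over the
#' region, normalized by the region's mean intensity. TF33: box-counting
#' fractal dimension of the region binarized above its median, via the
#' least-squares slope of log N(s) vs log(1/s) over dyadic box sizes (regions
#' whose bounding box is smaller than 8x8 get 0, flagged by convention).
#' TF34: fraction of rotation-uniform 8-neighbour local binary pattern codes
#' among region pixels with a full neighbourhood.
#'
#' @param m numeric matrix: intensity crop covering the region (ideally with
#'   a 1-pixel margin so Sobel/LBP neighbourhoods are genuine).
#' @param mask logical matrix like `m`, TRUE on region pixels.
#' @return named numeric vector TF32..TF34.
#' @export
structural_features <- function(m, mask) {
  x <- m[mask]
  grad <- sobel_mag(m)
  # only pixels whose 3x3 neighbourhood lies inside the crop have genuine
  # gradients (the border is zero-padded)
  interior <- mask
  interior[c(1, nrow(m)), ] <- FALSE
  interior[, c(1, ncol(m))] <- FALSE
  mu <- mean(x)
  tf32 <- if (mu > 1e-12 && any(interior)) mean(grad[interior]) / mu else 0
  bb <- which(mask, arr.ind = TRUE)
  rr <- range(bb[, 1]); cr <- range(bb[, 2])
  tf33 <- 0
  if (diff(rr) + 1 >= 8 && diff(cr) + 1 >= 8) {
    sub <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    vals <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    bin <- sub & vals > median(m[mask])
    tf33 <- box_counting_dimension(bin)
  }
  u <- lbp_uniform_mask(m)
  uu <- u[mask]
  tf34 <- if (all(is.na(uu))) 1 else mean(uu, na.rm = TRUE)
  out <- c(tf32, tf33, tf34)
  names(out) <- tf_names()[32:34]
  out
}

# Integer (dr, dc) offsets for the radial and tangential unit vectors of a
# region at azimuth `deg` (degrees from the leftward direction, CCW y-up).
orientation_offsets <- function(deg) {
  a <- deg * pi / 180
  radial <- c(round(sin(a)), round(-cos(a)))
  tangential <- c(round(cos(a)), round(sin(a)))
  if (all(radial == 0)) radial <- c(0L, -1L)
  if (all(tangential == 0)) tangential <- c(1L, 0L)
  list(radial = as.integer(radial), tangential = as.integer(tangential))
}

# Shared per-region feature engine for the polar and lattice samplers.
# px: intensity matrix; idx_list: list of linear pixel index vectors;
# azimuth_deg: per-region azimuth, or NULL for axis-aligned offsets.
# Sobel gradients and LBP uniformity are computed once on the whole image
# (so neighbourhoods at region borders see genuine tissue, not padding) and
# averaged per region.
region_feature_matrix <- function(px, idx_list, azimuth_deg, G, breast_range) {
  nr <- nrow(px); ncp <- ncol(px)
  n_reg <- length(idx_list)
  out <- matrix(NA_real_, n_reg, 34, dimnames = list(NULL, tf_names()))
  grad <- sobel_mag(px)
  grad[c(1, nr), ] <- NA; grad[, c(1, ncp)] <- NA  # padded-border artifacts
  lbpu <- lbp_uniform_mask(px)
  axis_off <- rbind(c(0L, 1L), c(1L, 0L))
  for (g in seq_len(n_reg)) {
    idx <- idx_list[[g]]
    x <- px[idx]
    lv <- quantize(x, breast_range, G)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    pos <- cbind(rr - r0 + 1L, cc - c0 + 1L)
    lvm <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    lvm[pos] <- lv
    if (is.null(azimuth_deg)) {
      off <- axis_off; run_dir <- c(0L, 1L)
    } else {
      o <- orientation_offsets(azimuth_deg[g])
      off <- rbind(o$radial, o$tangential); run_dir <- o$radial
    }
    hist13 <- hist_features_fast(x, lv, G)
    # structural: TF32 edge index, TF33 fractal dimension, TF34 LBP fraction
    mu <- hist13[8]
    gi <- grad[idx]
    tf32 <- if (mu > 1e-12 && !all(is.na(gi))) mean(gi, na.rm = TRUE) / mu else 0
    tf33 <- 0
    if (r1 - r0 + 1L >= 8L && c1 - c0 + 1L >= 8L) {
      mk <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      mk[pos] <- x > hist13[13]
      tf33 <- box_counting_dimension(mk)
    }
    uu <- lbpu[idx]
    tf34 <- if (all(is.na(uu))) 1 else mean(uu, na.rm = TRUE)
    out[g, ] <- c(hist13,
                  cpp_glcm_features(lvm, G, off),
                  cpp_rlm_features(lvm, G, run_dir[1], run_dir[2]),
                  tf32, tf33, tf34)
  }
  out
}

#' Compute the 34 texture feature maps over a polar grid
#'
#' For every retained region of the grid, all 34 descriptors are computed.
#' In `anatomy_aligned` mode the co-occurrence matrix is accumulated over the
#' radial and tangential distance-1 offsets of the region's azimuth (realized
#' as the nearest integer displacements of the rotated unit vectors) and
#' run-lengths are traced along the radial direction; `axis_aligned` mode uses
#' horizontal + vertical co-occurrence offsets and horizontal runs.
#' Quantization bounds are the whole-breast intensity range, so levels are
#' comparable across regions.
#'
#' @param image standardized [mammogram] (or plain intensity matrix).
#' @param grid a [build_polar_grid()] result.
#' @param config a [run_config] (supplies `gray_levels`).
#' @param orientation_mode `"anatomy_aligned"` or `"axis_aligned"`.
#' @return `feature_maps` object: `features` (retained-regions x 34 matrix),
#'   `regions` (retained subset of `grid$regions`), `orientation_mode`, `G`,
#'   `breast_range`.
#' @export
compute_feature_maps <- function(image, grid, config = run_config(),
                                 orientation_mode = c("anatomy_aligned", "axis_aligned")) {
  orientation_mode <- match.arg(orientation_mode)
  px <- if (inherits(image, "mammogram")) image$pixels else image
  keep <- which(grid$regions$retained)
  if (length(keep) == 0)
    stop_mammotex("grid has no retained regions", "mammotex_grid_error")
  idx_list <- grid$pixel_idx[keep]
  breast_range <- range(px[unlist(grid$pixel_idx, use.names = FALSE)])
  az <- if (orientation_mode == "anatomy_aligned")
    grid$regions$azimuth_deg[keep] else NULL
  feats <- region_feature_matrix(px, idx_list, az, config$gray_levels, breast_range)
  structure(list(features = feats, regions = grid$regions[keep, , drop = FALSE],
                 orientation_mode = orientation_mode, G = config$gray_levels,
                 breast_range = breast_range),
            class = "feature_maps")
}
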