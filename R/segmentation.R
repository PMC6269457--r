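#' Segment the breast from the background
#'
#' Air-breast delineation by automatic global (Otsu) thresholding followed by
#' morphological closing, hole filling, and retention of the largest connected
#' foreground component.
#'
#' @param image a [mammogram].
#' @return logical matrix, the breast mask.
#' @export
segment_breast <- function(image) {
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) <= 0)
    stop_mammotex("empty foreground: image has no intensity contrast",
                  "mammotex_segmentation_error")
  x <- (px - rng[1]) / diff(rng)
  th <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  fg <- x > th
  if (!any(fg))
    stop_mammotex("empty foreground after thresholding", "mammotex_segmentation_error")
  brush_r <- max(3L, 2L * round(1 / image$pixel_spacing_mm) + 1L)
  kern <- EBImage::makeBrush(brush_r, shape = "disc")
  fg <- EBImage::closing(fg, kern) > 0
  fg <- EBImage::fillHull(fg) > 0
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0)
    stop_mammotex("empty foreground after morphology", "mammotex_segmentation_error")
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# 3x3 Sobel gradient (same size, zero-padded borders). gx: along columns,
# gy: along rows.
sobel_grad <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  s <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

sobel_mag <- function(m) sobel_grad(m)$mag

#' Segment the pectoralis muscle
#'
#' Finds the strongest straight line over intensity-edge pixels in the upper
#' chest-wall corner of the breast using a Hough transform constrained to
#' plausible pectoral angles (20-80 degrees from vertical), refines it by
#' least squares, and returns the triangular region between the line and the
#' chest-wall/top edges. "No pectoralis found" (no line reaches the
#' accumulator threshold) is a valid outcome: an empty mask and `NULL` line.
#'
#' @param image a [mammogram] (any laterality; right images are mirrored
#'   internally and the mask mirrored back).
#' @param breast_mask logical matrix from [segment_breast()].
#' @return list with `mask` (logical matrix) and `line` (`NULL`, or a list
#'   with `angle_deg` from vertical in the chest-wall-left frame and `point`
#'   `(row, col)` on the line in the image's own frame).
#' @export
segment_pectoralis <- function(image, breast_mask) {
  if (!any(breast_mask))
    stop_mammotex("breast mask is empty", "mammotex_segmentation_error")
  mirrored <- image$laterality == "right"
  px <- image$pixels
  if (mirrored) {
    px <- flop(px)
    breast_mask <- flop(breast_mask)
  }
  res <- pectoralis_left(px, breast_mask)
  if (mirrored) {
    res$mask <- flop(res$mask)
    if (!is.null(res$line))
      res$line$point[2] <- ncol(px) + 1 - res$line$point[2]
  }
  res
}

pectoralis_left <- function(px, breast) {
  nr <- nrow(px); nc <- ncol(px)
  gr <- sobel_grad(px)
  # candidate edges: strong gradients in the upper chest-wall corner, away
  # from the air-breast boundary
  inner <- EBImage::erode(breast, EBImage::makeBrush(7, "disc")) > 0
  cand <- inner & row_grid(nr, nc) <= 0.9 * nr & col_grid(nr, nc) <= 0.6 * nc
  empty <- list(mask = matrix(FALSE, nr, nc), line = NULL)
  if (!any(cand)) return(empty)
  g <- gr$mag[cand]
  edges <- cand & gr$mag >= quantile(g, 0.95)
  er <- row_grid(nr, nc)[edges]; ec <- col_grid(nr, nc)[edges]
  if (length(er) < 10) return(empty)
  # unit gradient direction per edge pixel, for orientation gating: only
  # edges whose gradient is normal to the candidate line may vote
  egc <- gr$gx[edges] / gr$mag[edges]
  egr <- gr$gy[edges] / gr$mag[edges]

  thetas <- seq(20, 80, by = 0.5) * pi / 180  # angle from vertical
  align_min <- cos(25 * pi / 180)
  best <- list(votes = 0)
  for (th in thetas) {
    ok <- abs(egr * sin(th) + egc * cos(th)) >= align_min
    if (sum(ok) < 10) next
    rho <- er[ok] * sin(th) + ec[ok] * cos(th)  # normal form, bin width 2 px
    b <- floor(rho / 2)
    b0 <- min(b)
    tb <- tabulate(b - b0 + 1L)
    v <- max(tb)
    if (v > best$votes)
      best <- list(votes = v, theta = th,
                   rho = (which.max(tb) + b0 - 1 + 0.5) * 2)
  }
  min_votes <- max(30, round(0.25 * nr))
  if (best$votes < min_votes) return(empty)

  # least-squares refinement on aligned pixels near the winning line
  d <- abs(er * sin(best$theta) + ec * cos(best$theta) - best$rho)
  keep <- d <= 3 &
    abs(egr * sin(best$theta) + egc * cos(best$theta)) >= align_min
  if (sum(keep) >= 10) {
    fit <- stats::lm.fit(cbind(1, er[keep]), ec[keep])
    slope <- fit$coefficients[2]; icpt <- fit$coefficients[1]
    angle <- atan(-slope) * 180 / pi
    point <- c(1, icpt + slope)
  } else {
    angle <- best$theta * 180 / pi
    point <- c(1, (best$rho - sin(best$theta)) / cos(best$theta))
  }
  # anatomical sanity: the boundary must descend from the upper chest-wall
  # corner (top intercept well inside the left part of the frame)
  if (angle < 15 || angle > 85 || point[2] <= 3 || point[2] > 0.75 * nc)
    return(empty)
  bound <- point[2] - (row_grid(nr, nc) - 1) * tan(angle * pi / 180)
  mask <- breast & col_grid(nr, nc) <= bound
  list(mask = mask, line = list(angle_deg = unname(angle), point = unname(point)))
}

#' Partition the breast into density clusters and a dense-tissue mask
#'
#' Fuzzy c-means clustering (fuzziness m = 2, tolerance 1e-5, max 200
#' iterations, deterministic intensity-quantile initialization) of the
#' within-breast intensities into `K` clusters; each pixel is hard-assigned to
#' its maximum-membership cluster and labels are reordered by ascending
#' centroid (1 = most fatty ... K = most dense). The dense mask aggregates the
#' clusters whose centroid exceeds the midpoint of the lowest and highest
#' centroids.
#'
#' @param image a [mammogram].
#' @param breast_mask,pectoralis_mask logical matrices; clustering runs on
#'   breast minus pectoralis.
#' @param K number of clusters (>= 2); silently reduced (with a warning) when
#'   the breast has fewer distinct intensities.
#' @return list: `cluster_labels` (integer matrix, 0 outside breast-minus-
#'   pectoralis), `dense_mask` (logical), `centroids` (ascending), `K`.
#' @export
segment_density <- function(image, breast_mask, pectoralis_mask = NULL, K = 4L) {
  if (is.null(pectoralis_mask)) pectoralis_mask <- matrix(FALSE, nrow(breast_mask), ncol(breast_mask))
  roi <- breast_mask & !pectoralis_mask
  if (!any(roi))
    stop_mammotex("breast minus pectoralis is empty", "mammotex_segmentation_error")
  x <- image$pixels[roi]
  n_distinct <- length(unique(x))
  if (n_distinct < K) {
    warning(sprintf("only %d distinct intensities; reducing K from %d", n_distinct, K))
    K <- n_distinct
  }
  labels <- matrix(0L, nrow(breast_mask), ncol(breast_mask))
  if (K == 1L) {
    warning("breast is constant-intensity; single cluster, empty dense mask")
    labels[roi] <- 1L
    return(list(cluster_labels = labels, dense_mask = roi & FALSE,
                centroids = mean(x), K = 1L))
  }
  init <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (anyDuplicated(init)) init <- seq(min(x), max(x), length.out = K)
  # cluster the intensity histogram (count-weighted) rather than every pixel:
  # equivalent objective up to binning, and much faster on large breasts
  B <- min(512L, n_distinct)
  bin <- quantize(x, range(x), B)
  counts <- tabulate(bin, nbins = B)
  nonzero <- which(counts > 0)
  centers_x <- min(x) + (nonzero - 0.5) / B * diff(range(x))
  fit <- e1071::cmeans(matrix(centers_x, ncol = 1),
                       centers = matrix(init, ncol = 1),
                       iter.max = 200, verbose = FALSE, method = "cmeans",
                       m = 2, weights = counts[nonzero],
                       control = list(reltol = 1e-5))
  stopifnot(all(abs(rowSums(fit$membership) - 1) < 1e-6))
  hard_bin <- integer(B)
  hard_bin[nonzero] <- max.col(fit$membership, ties.method = "first")
  ord <- order(fit$centers[, 1])
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  hard <- relabel[hard_bin[bin]]
  centroids <- sort(fit$centers[, 1])
  labels[roi] <- hard
  cutoff <- (centroids[1] + centroids[K]) / 2
  dense_ids <- which(centroids > cutoff)
  dense <- labels > 0 & matrix(labels %in% dense_ids, nrow(labels), ncol(labels))
  list(cluster_labels = labels, dense_mask = dense, centroids = centroids, K = K)
}

#' Run the full anatomical segmentation stage
#'
#' Breast mask, pectoralis muscle and density clusters in one call.
#'
#' @param image a [mammogram].
#' @param config a [run_config].
#' @return `breast_segmentation` object: `breast_mask` (pectoralis excluded),
#'   `pectoralis_mask`, `pect_line`, `cluster_labels`, `dense_mask`,
#'   `centroids`, `K`.
#' @export
segment_all <- function(image, config = run_config()) {
  breast <- segment_breast(image)
  pect <- segment_pectoralis(image, breast)
  dens <- segment_density(image, breast, pect$mask, K = config$density_clusters)
  structure(list(breast_mask = breast & !pect$mask,
                 pectoralis_mask = pect$mask, pect_line = pect$line,
                 cluster_labels = dens$cluster_labels,
                 dense_mask = dens$dense_mask,
                 centroids = dens$centroids, K = dens$K),
            class = "breast_segmentation")
}
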