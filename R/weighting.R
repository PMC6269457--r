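# Anatomical weight maps S (position), T (tissue composition), W = c*S + (1-c)*T,
# and the 68-element per-breast texture signature.

#' Position weights S from anatomical quadrant proximity
#'
#' For each retained region centroid, `S = a * (1 - dC) + (1 - a) * (1 - dU)`
#' where `dC`/`dU` are the Euclidean distances to the CBA / UOA mask centroids,
#' each normalized by its maximum over the retained regions (so both lie in
#' `[0, 1]` and S is scale-free across breast sizes). Regions inside or near a
#' quadrant get larger weights; `a` tunes the role of CBA versus UOA. If the
#' UOA is empty its term is dropped (`S = 1 - dC`, flagged with a warning).
#'
#' @param grid a [build_polar_grid()] result (retained regions are used).
#' @param cba_mask,uoa_mask logical quadrant masks from [define_quadrants()].
#' @param a CBA-vs-UOA mixing parameter in `[0, 1]`.
#' @return numeric vector of S in `[0, 1]`, one per retained region.
#' @export
position_weights <- function(grid, cba_mask, uoa_mask, a) {
  if (a < 0 || a > 1) stop_mammotex("a must lie in [0, 1]", "mammotex_parameter_error")
  if (!any(cba_mask)) stop_mammotex("CBA mask is empty", "mammotex_anatomy_error")
  reg <- grid$regions[grid$regions$retained, , drop = FALSE]
  ctr <- cbind(reg$centroid_row, reg$centroid_col)
  mask_centroid <- function(m) {
    w <- which(m, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }
  norm_dist <- function(center) {
    d <- sqrt((ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2)
    mx <- max(d)
    if (mx <= 0) rep(0, length(d)) else d / mx
  }
  dC <- norm_dist(mask_centroid(cba_mask))
  if (!any(uoa_mask)) {
    warning("UOA is empty: position weights use CBA proximity only")
    return(1 - dC)
  }
  dU <- norm_dist(mask_centroid(uoa_mask))
  a * (1 - dC) + (1 - a) * (1 - dU)
}

#' Tissue-composition weights T from density clusters
#'
#' Each retained region is scored by its mean density-cluster label mapped to
#' `chat = (mean label - 1) / (K - 1)` in `[0, 1]` (0 = most fatty, 1 = most
#' dense); then `T = b * chat + (1 - b) * (1 - chat)`, so `b = 1` up-weights
#' dense tissue and `b = 0` fatty tissue. A single-cluster breast (K = 1)
#' yields `T = 0.5` everywhere, flagged with a warning.
#'
#' @param grid a [build_polar_grid()] result.
#' @param cluster_labels integer label matrix from [segment_density()]
#'   (standardized frame).
#' @param b dense-vs-fatty mixing parameter in `[0, 1]`.
#' @param K cluster count used in segmentation.
#' @return numeric vector of T in `[0, 1]`, one per retained region.
#' @export
tissue_weights <- function(grid, cluster_labels, b, K) {
  if (b < 0 || b > 1) stop_mammotex("b must lie in [0, 1]", "mammotex_parameter_error")
  keep <- which(grid$regions$retained)
  chat <- region_mean_label(grid, cluster_labels, K)
  if (K == 1) {
    warning("single density cluster: T = 0.5 for all regions")
    return(rep(0.5, length(keep)))
  }
  b * chat + (1 - b) * (1 - chat)
}

# Mean cluster label per retained region mapped into [0, 1].
region_mean_label <- function(grid, cluster_labels, K) {
  keep <- which(grid$regions$retained)
  chat <- unname(vapply(grid$pixel_idx[keep], function(idx) {
    l <- cluster_labels[idx]
    l <- l[l > 0]
    if (length(l) == 0) 0.5 * (K - 1) + 1 else mean(l)
  }, numeric(1)))
  if (K == 1) rep(0.5, length(keep)) else (chat - 1) / (K - 1)
}

#' Combine position and tissue weights into the final weight map
#'
#' `W = c * S + (1 - c) * T`, elementwise; `c = 1` reduces to S, `c = 0` to T.
#'
#' @param S,T numeric vectors of equal length in `[0, 1]`.
#' @param c_mix mixing parameter in `[0, 1]`.
#' @return numeric vector W in `[0, 1]`.
#' @export
combine_weights <- function(S, T, c_mix) {
  if (c_mix < 0 || c_mix > 1) stop_mammotex("c must lie in [0, 1]", "mammotex_parameter_error")
  if (length(S) != length(T))
    stop_mammotex("S and T must have the same length", "mammotex_parameter_error")
  c_mix * S + (1 - c_mix) * T
}

#' Apply a region weight map to the 34 feature maps
#'
#' Region-wise multiplication: `weighted[r, k] = W[r] * features[r, k]`.
#'
#' @param maps a `feature_maps` object from [compute_feature_maps()].
#' @param W numeric weight vector aligned to the retained regions.
#' @return `weighted_feature_maps`: `features` (weighted matrix), `W`,
#'   `regions`, plus the originating map metadata.
#' @export
apply_weights <- function(maps, W) {
  if (length(W) != nrow(maps$features))
    stop_mammotex("weight vector is not aligned to the region list",
                  "mammotex_parameter_error")
  structure(list(features = maps$features * W, W = W, regions = maps$regions,
                 orientation_mode = maps$orientation_mode, G = maps$G),
            class = "weighted_feature_maps")
}

#' Summarize weighted feature maps into the 68-element texture signature
#'
#' For each of the 34 weighted maps, the mean over retained regions
#' (`TF#_mean`) and the standard deviation over regions (`TF#_std`), in the
#' fixed label order (all means, then all standard deviations).
#'
#' @param weighted a `weighted_feature_maps` (or `feature_maps`, treated as
#'   weights identically 1).
#' @param subject_id,side_label identifiers carried on the signature.
#' @return `texture_signature`: named numeric vector of length 68 with
#'   attributes `subject_id` and `side_label`.
#' @export
summarize_signature <- function(weighted, subject_id = "unknown", side_label = "") {
  f <- weighted$features
  if (nrow(f) < 2)
    stop_mammotex("need >= 2 retained regions for a signature", "mammotex_grid_error")
  v <- c(colMeans(f), apply(f, 2, sd))
  names(v) <- c(paste0(tf_names(), "_mean"), paste0(tf_names(), "_std"))
  structure(v, subject_id = subject_id, side_label = side_label,
            class = c("texture_signature", "numeric"))
}
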