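# End-to-end orchestration: per-breast anatomical context -> signatures for
# one or many (D, f, a, b, c) parameter tuples without recomputing texture.
# Texture features depend only on D (and the gray levels); the CBA/UOA
# geometry only on f; the weight map only on (a, b, c). A `breast_context`
# caches the per-D feature matrices and per-f quadrant centroids so the
# parameter grid search recomputes only the cheap weighting/summary stages.

context_key <- function(x) sprintf("%.8g", x)

#' Build the reusable anatomical texture context of one breast
#'
#' Runs segmentation, orientation standardization, nipple localization and,
#' for every requested polar radius unit `D`, the polar grid plus the 34
#' feature maps; for every requested CBA fraction `f`, the quadrant centroids.
#' The result is a compact summary from which [signature_from_context()]
#' produces a 68-element signature for any `(D, f, a, b, c)` combination.
#'
#' @param image a [mammogram].
#' @param config a [run_config].
#' @param D_values,f_values numeric vectors of parameter values to cache.
#' @param seg optional precomputed [segment_all()] result.
#' @return `breast_context` list: `per_D`, `per_f`, `K`, `diagnostics`
#'   (nipple, r_P_mm, pectoral angle, dense fraction, flags), identifiers.
#' @export
breast_context <- function(image, config = run_config(),
                           D_values = config$D_mm, f_values = config$f,
                           seg = NULL) {
  if (is.null(seg)) seg <- segment_all(image, config)
  std <- standardize_orientation(image, seg)
  sp <- image$pixel_spacing_mm
  nipple <- locate_nipple(std$breast_mask, sp)

  per_f <- list()
  r_P_mm <- NA_real_
  for (f in f_values) {
    quad <- define_quadrants(nipple, std$breast_mask, std$pect_col, f, sp)
    r_P_mm <- quad$r_P_mm
    ctr <- function(m) if (any(m)) {
      w <- which(m, arr.ind = TRUE); c(mean(w[, 1]), mean(w[, 2]))
    } else NULL
    per_f[[context_key(f)]] <- list(cba_centroid = ctr(quad$cba_mask),
                                    uoa_centroid = ctr(quad$uoa_mask),
                                    r_P_mm = quad$r_P_mm)
  }

  per_D <- list()
  for (D in D_values) {
    grid <- build_polar_grid(nipple, std$breast_mask, D, r_P_mm, sp,
                             config$region_min_coverage, config$region_min_pixels)
    maps <- compute_feature_maps(std$image, grid, config, "anatomy_aligned")
    per_D[[context_key(D)]] <- list(
      features = maps$features,
      centroids = cbind(maps$regions$centroid_row, maps$regions$centroid_col),
      chat = region_mean_label(grid, std$cluster_labels, seg$K),
      n_regions = nrow(maps$features))
  }

  structure(list(
    per_D = per_D, per_f = per_f, K = seg$K,
    subject_id = image$subject_id, side_label = image$side_label,
    diagnostics = list(
      nipple = nipple, r_P_mm = r_P_mm,
      pect_angle_deg = if (is.null(seg$pect_line)) NA_real_ else seg$pect_line$angle_deg,
      dense_fraction = sum(seg$dense_mask) / max(1, sum(seg$breast_mask)),
      no_pectoralis = is.null(seg$pect_line),
      transform = std$transform)),
    class = "breast_context")
}

#' Texture signature for one parameter tuple from a cached context
#'
#' @param ctx a [breast_context()].
#' @param D_mm,f,a,b,c_mix parameter tuple; `D_mm` and `f` must be among the
#'   values cached in the context.
#' @return a `texture_signature` (68 elements, sampler `"anatomy"`).
#' @export
signature_from_context <- function(ctx, D_mm, f, a, b, c_mix) {
  fd <- ctx$per_D[[context_key(D_mm)]]
  pf <- ctx$per_f[[context_key(f)]]
  if (is.null(fd) || is.null(pf))
    stop_mammotex("D_mm or f not cached in this context", "mammotex_parameter_error")
  if (is.null(pf$cba_centroid))
    stop_mammotex("CBA mask is empty", "mammotex_anatomy_error")
  norm_dist <- function(center) {
    d <- sqrt((fd$centroids[, 1] - center[1])^2 + (fd$centroids[, 2] - center[2])^2)
    mx <- max(d); if (mx <= 0) rep(0, length(d)) else d / mx
  }
  dC <- norm_dist(pf$cba_centroid)
  S <- if (is.null(pf$uoa_centroid)) 1 - dC
       else a * (1 - dC) + (1 - a) * (1 - norm_dist(pf$uoa_centroid))
  TT <- if (ctx$K == 1) rep(0.5, length(fd$chat))
        else b * fd$chat + (1 - b) * (1 - fd$chat)
  W <- combine_weights(S, TT, c_mix)
  sig <- summarize_signature(list(features = fd$features * W),
                             subject_id = ctx$subject_id,
                             side_label = ctx$side_label)
  attr(sig, "sampler") <- "anatomy"
  sig
}

#' Anatomy-weighted texture signature of one breast
#'
#' Convenience wrapper: full pipeline (segmentation, anatomy, polar-grid
#' texture, weighting, summarization) at the configuration's parameter tuple.
#'
#' @param image a [mammogram].
#' @param config a [run_config].
#' @return a `texture_signature` (68 elements).
#' @export
anatomy_signature <- function(image, config = run_config()) {
  ctx <- breast_context(image, config)
  signature_from_context(ctx, config$D_mm, config$f, config$a, config$b, config$c_mix)
}

#' Run the texture pipeline over a synthetic cohort
#'
#' Materializes each woman's left and right phantoms one at a time (streaming;
#' images are never all in memory), builds the per-breast contexts, optionally
#' the lattice comparator signatures, and collects ground-truth-based
#' diagnostics (breast-mask Dice, nipple localization error, pectoral angle
#' error) along with the covariate table.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [run_config].
#' @param D_values,f_values parameter values to cache in each context.
#' @param include_lattice also compute lattice signatures.
#' @param keep_contexts keep the per-breast contexts (needed for
#'   [optimize_parameters()]).
#' @return list: `anatomy` (2n x 68 per-breast signature matrix), `lattice`
#'   (or `NULL`), `subject_ids` (length 2n), `labels` (per woman),
#'   `covariates` (data.frame), `contexts` (or `NULL`), `diagnostics`
#'   (per-breast data.frame with dice, nipple_err_mm, angle_err_deg).
#' @export
run_cohort_pipeline <- function(cohort, config = run_config(),
                                D_values = config$D_mm, f_values = config$f,
                                include_lattice = FALSE, keep_contexts = FALSE) {
  m <- cohort$manifest
  n <- nrow(m)
  sides <- c("left", "right")
  n_b <- 2L * n
  anatomy <- matrix(NA_real_, n_b, 68)
  lattice <- if (include_lattice) matrix(NA_real_, n_b, 68) else NULL
  subject_ids <- character(n_b)
  contexts <- if (keep_contexts) vector("list", n_b) else NULL
  diag_df <- data.frame(subject_id = character(n_b), side = character(n_b),
                        dice = NA_real_, nipple_err_mm = NA_real_,
                        angle_err_deg = NA_real_, dense_fraction = NA_real_,
                        stringsAsFactors = FALSE)
  k <- 0L
  dense_fraction_truth <- numeric(n)
  for (i in seq_len(n)) {
    fr <- numeric(2)
    for (s in seq_along(sides)) {
      k <- k + 1L
      ph <- cohort_image(cohort, i, sides[s])
      seg <- segment_all(ph$image, config)
      ctx <- breast_context(ph$image, config, D_values, f_values, seg = seg)
      anatomy[k, ] <- as.numeric(signature_from_context(
        ctx, config$D_mm, config$f, config$a, config$b, config$c_mix))
      if (include_lattice) {
        lattice[k, ] <- as.numeric(
          lattice_signature(ph$image, seg$breast_mask, config))
      }
      subject_ids[k] <- m$subject_id[i]
      tr <- ph$truth
      fr[s] <- sum(tr$dense) / max(1, sum(tr$breast & !tr$pect))
      # diagnostics vs ground truth (pre-standardization frame)
      seg_full <- seg$breast_mask | seg$pectoralis_mask
      nip_std <- ctx$diagnostics$nipple
      nip_orig <- invert_point(nip_std, ctx$diagnostics$transform)
      diag_df$subject_id[k] <- m$subject_id[i]
      diag_df$side[k] <- sides[s]
      diag_df$dice[k] <- dice(seg_full, tr$breast)
      diag_df$nipple_err_mm[k] <- sqrt(sum((nip_orig - tr$nipple)^2)) *
        ph$image$pixel_spacing_mm
      diag_df$angle_err_deg[k] <-
        if (!is.null(tr$pect_line) && !is.na(ctx$diagnostics$pect_angle_deg))
          abs(ctx$diagnostics$pect_angle_deg - tr$pect_line$angle_deg) else NA_real_
      diag_df$dense_fraction[k] <- ctx$diagnostics$dense_fraction
      if (keep_contexts) contexts[[k]] <- ctx
    }
    dense_fraction_truth[i] <- mean(fr)
  }
  colnames(anatomy) <- c(paste0(tf_names(), "_mean"), paste0(tf_names(), "_std"))
  if (include_lattice) colnames(lattice) <- colnames(anatomy)
  list(anatomy = anatomy, lattice = lattice, subject_ids = subject_ids,
       labels = m$label, covariates = cohort_covariates(cohort, dense_fraction_truth),
       contexts = contexts, diagnostics = diag_df)
}

# Map a standardized-frame point back to the original image frame.
invert_point <- function(pt, transform) {
  nr <- transform$dims[1]; nc <- transform$dims[2]
  th <- -transform$rotation_deg * pi / 180
  cr <- (nr + 1) / 2; ccen <- (nc + 1) / 2
  x <- pt[2] - ccen; y <- -(pt[1] - cr)
  r <- cr - (sin(th) * x + cos(th) * y)
  c2 <- ccen + (cos(th) * x - sin(th) * y)
  if (transform$flip) c2 <- nc + 1 - c2
  c(r, c2)
}
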