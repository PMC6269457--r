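#' Specification of a synthetic MLO phantom
#'
#' Describes a seed-controlled synthetic mediolateral-oblique mammogram: a
#' half-ellipse breast attached to the chest-wall edge, a pectoralis wedge
#' under a straight line, a hemispherical nipple bump at the most anterior
#' silhouette point, hard-disk dense-tissue blobs on a fatty background, and a
#' spatially correlated Gaussian noise field standing in for stochastic
#' parenchymal texture. A case-vs-control texture "effect" is injected by
#' scaling the local noise variance by `(1 + effect_size)` inside a chosen
#' anatomical locus.
#'
#' Intensities use a raw-detector-like scale where higher value = denser
#' tissue (air ~20, fat 400, dense fat+250, pectoralis 700).
#'
#' @param rows,cols image size in pixels.
#' @param pixel_spacing_mm isotropic pixel spacing (mm).
#' @param laterality `"left"` or `"right"` (right phantoms are exact mirrors).
#' @param breast_radius_mm anterior-posterior semi-axis of the breast ellipse.
#' @param breast_semiheight_mm superior-inferior semi-axis.
#' @param pectoral_angle_deg angle of the pectoral boundary from vertical
#'   (degrees, in the chest-wall-left frame); `NA` omits the wedge.
#' @param pectoral_top_mm column (mm from the chest wall) where the pectoral
#'   boundary meets the top edge.
#' @param nipple_radius_mm radius of the hemispherical nipple bump.
#' @param n_blobs number of dense-tissue blobs (two are deterministically
#'   placed inside the CBA and the UOA so both loci contain dense tissue).
#' @param blob_radius_mm length-2 range of blob radii (mm).
#' @param blob_contrast added intensity inside dense blobs.
#' @param noise_sd marginal standard deviation of the texture noise field.
#' @param noise_corr_mm Gaussian correlation length of the noise field (mm).
#' @param effect locus of the case texture effect: `"none"`, `"cba_dense"`,
#'   `"uoa_dense"`, `"fatty"` or `"diffuse"`.
#' @param effect_size non-negative multiplier: noise variance inside the locus
#'   is scaled by `(1 + effect_size)`.
#' @param effect_f CBA fraction f used to delimit the effect locus.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 180L, cols = 150L, pixel_spacing_mm = 0.5,
                         laterality = c("left", "right"),
                         breast_radius_mm = 60, breast_semiheight_mm = 40,
                         pectoral_angle_deg = 30, pectoral_top_mm = 40,
                         nipple_radius_mm = 4,
                         n_blobs = 6L, blob_radius_mm = c(4, 9),
                         blob_contrast = 250,
                         noise_sd = 40, noise_corr_mm = 2,
                         effect = c("none", "cba_dense", "uoa_dense", "fatty", "diffuse"),
                         effect_size = 0, effect_f = 0.75, seed = 1L) {
  laterality <- match.arg(laterality)
  effect <- match.arg(effect)
  if (max(blob_radius_mm) >= breast_radius_mm)
    stop_mammotex("blob radius must be smaller than the breast radius",
                  "mammotex_spec_error")
  if (effect_size < 0)
    stop_mammotex("effect_size must be >= 0", "mammotex_spec_error")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a synthetic phantom mammogram with ground truth
#'
#' Materializes a [phantom_spec] into an image plus pixel-level ground truth
#' (breast / pectoralis / dense masks, nipple point, pectoral line parameters,
#' nipple-pectoralis distance `r_P`, and the per-pixel effect mask). The truth
#' is the oracle for segmentation, nipple-localization and parameter-recovery
#' tests throughout the package.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `image` (a [mammogram]) and `truth` (list of
#'   masks and landmarks; `pect_line` holds `angle_deg` from vertical and a
#'   `point` on the line, both in the generated image's frame).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  nr <- spec$rows; nc <- spec$cols; sp <- spec$pixel_spacing_mm
  rr <- row_grid(nr, nc); cc <- col_grid(nr, nc)
  rx <- spec$breast_radius_mm / sp
  ry <- spec$breast_semiheight_mm / sp

  # The breast protrudes perpendicular to the pectoral boundary, as in a real
  # MLO projection: a half-ellipse whose long axis is tilted below horizontal
  # by the pectoral angle, attached to the chest-wall (left) edge.
  tilt <- if (is.na(spec$pectoral_angle_deg)) 0 else spec$pectoral_angle_deg * pi / 180
  u <- c(sin(tilt), cos(tilt))    # axis direction (row, col): anterior-inferior
  v <- c(cos(tilt), -sin(tilt))   # perpendicular
  cy0 <- (nr + 1) / 2 - rx * sin(tilt) / 2
  s_ax <- (rr - cy0) * u[1] + cc * u[2]
  t_ax <- (rr - cy0) * v[1] + cc * v[2]
  breast <- (s_ax / rx)^2 + (t_ax / ry)^2 <= 1 & s_ax >= 0

  # nipple bump at the axis tip (the most anterior silhouette point after
  # orientation standardization)
  np_r <- cy0 + rx * u[1]; np_c <- rx * u[2]
  nrad <- spec$nipple_radius_mm / sp
  outward <- (rr - np_r) * u[1] + (cc - np_c) * u[2] >= 0
  breast <- breast | ((rr - np_r)^2 + (cc - np_c)^2 <= nrad^2 & outward)
  nipple <- c(np_r, np_c)  # center of the hemispherical bump

  # pectoralis wedge: boundary col(r) = x0 - (r - 1) * tan(theta)
  pect <- matrix(FALSE, nr, nc)
  pect_line <- NULL
  if (!is.na(spec$pectoral_angle_deg)) {
    th <- spec$pectoral_angle_deg * pi / 180
    x0 <- spec$pectoral_top_mm / sp
    bound <- x0 - (rr - 1) * tan(th)
    pect <- breast & (cc <= bound)
    pect_line <- list(angle_deg = spec$pectoral_angle_deg, point = c(1, x0))
  }

  # r_P: perpendicular distance (mm) from the pectoral line to the nipple
  if (!is.null(pect_line)) {
    th <- spec$pectoral_angle_deg * pi / 180
    r_P_mm <- abs((nipple[1] - pect_line$point[1]) * sin(th) +
                  (nipple[2] - pect_line$point[2]) * cos(th)) * sp
  } else {
    r_P_mm <- nipple[2] * sp
  }

  # dense blobs: hard disks; first two placed deterministically in CBA / UOA
  blob_r <- runif(max(spec$n_blobs, 2), spec$blob_radius_mm[1], spec$blob_radius_mm[2]) / sp
  f_rp_px <- spec$effect_f * r_P_mm / sp
  centers <- matrix(NA_real_, max(spec$n_blobs, 2), 2)
  centers[1, ] <- nipple - 0.5 * f_rp_px * u                             # CBA
  up_out <- (c(-1, 0) - u) / sqrt(sum((c(-1, 0) - u)^2))                 # UOA
  centers[2, ] <- nipple + 1.3 * f_rp_px * up_out
  if (spec$n_blobs > 2) {
    inside <- which(breast & !pect)
    idx <- sample(inside, spec$n_blobs - 2)
    centers[3:spec$n_blobs, ] <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
  }
  dense <- matrix(FALSE, nr, nc)
  for (k in seq_len(spec$n_blobs)) {
    dense <- dense | ((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= blob_r[k]^2)
  }
  dense <- dense & breast & !pect

  # intensity model
  img <- matrix(20, nr, nc)
  img[breast] <- 400
  img[dense] <- 400 + spec$blob_contrast
  img[pect] <- 700

  # effect locus
  dist_np <- sqrt((rr - nipple[1])^2 + (cc - nipple[2])^2) * sp
  cba <- breast & !pect & dist_np < spec$effect_f * r_P_mm
  uoa <- breast & !pect & rr < nipple[1] & dist_np > spec$effect_f * r_P_mm
  effect_mask <- switch(spec$effect,
    none = matrix(FALSE, nr, nc),
    cba_dense = cba & dense,
    uoa_dense = uoa & dense,
    fatty = breast & !pect & !dense,
    diffuse = breast & !pect)

  # spatially correlated noise (Gaussian random field), variance-modulated
  noise <- gaussian_field(nr, nc, sigma_px = spec$noise_corr_mm / sp)
  scale_map <- matrix(spec$noise_sd, nr, nc)
  scale_map[effect_mask] <- spec$noise_sd * sqrt(1 + spec$effect_size)
  img <- img + noise * scale_map * (breast | pect)
  img <- img + rnorm(nr * nc, sd = 2) * !(breast | pect)
  img <- pmax(img, 0)

  truth <- list(breast = breast, pect = pect, dense = dense,
                nipple = nipple, pect_line = pect_line, r_P_mm = r_P_mm,
                cba = cba, uoa = uoa, effect_mask = effect_mask,
                f = spec$effect_f)
  if (spec$laterality == "right") {
    img <- flop(img)
    for (nm in c("breast", "pect", "dense", "cba", "uoa", "effect_mask"))
      truth[[nm]] <- flop(truth[[nm]])
    truth$nipple[2] <- nc + 1 - truth$nipple[2]
    if (!is.null(truth$pect_line))
      truth$pect_line$point[2] <- nc + 1 - truth$pect_line$point[2]
  }
  list(image = mammogram(img, sp, spec$laterality,
                         side_label = spec$laterality),
       truth = truth)
}

# Unit-variance Gaussian random field via separable Gaussian smoothing of
# white noise (dense matrix products; images are small).
gaussian_field <- function(nr, nc, sigma_px) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma_px <= 0.25) return(w)
  k <- function(n) {
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * sigma_px^2))
    K
  }
  s <- k(nr) %*% w %*% k(nc)
  (s - mean(s)) / sd(s)
}

#' Generate a synthetic case-control phantom cohort
#'
#' Draws per-woman phantom geometry (breast size, pectoral angle, blob layout)
#' around a template spec, injects the template's texture effect bilaterally in
#' cases only, and simulates covariates (age, BMI, and a breast-density
#' measure equal to the true dense-area fraction plus noise, with a
#' configurable case-control shift). Cases and controls default to the 1:4
#' case:control design. Images are materialized lazily: call
#' [cohort_image()] with a manifest row, so arbitrarily large cohorts never
#' need to be held in memory.
#'
#' @param n_cases,n_controls class sizes (>= 2 each).
#' @param template a [phantom_spec]; its `effect` and `effect_size` apply to
#'   cases (controls always get `effect = "none"`).
#' @param covariate_shifts named list of case-minus-control shifts in SD units
#'   for `age`, `bmi`, `density` (defaults 0, 0, 0.25).
#' @param seed cohort seed.
#' @return An object of class `phantom_cohort`: `manifest` (one row per woman:
#'   subject_id, label, covariates, per-side seeds and geometry) and `template`.
#' @export
generate_cohort <- function(n_cases, n_controls, template = phantom_spec(),
                            covariate_shifts = list(age = 0, bmi = 0, density = 0.25),
                            seed = 1L) {
  if (n_cases < 2 || n_controls < 2)
    stop_mammotex("need at least 2 women per class", "mammotex_spec_error")
  n <- n_cases + n_controls
  with_seed(seed, {
    label <- c(rep(1L, n_cases), rep(0L, n_controls))
    manifest <- data.frame(
      subject_id = sprintf("W%04d", seq_len(n)),
      label = label,
      breast_radius_mm = pmax(45, rnorm(n, template$breast_radius_mm, 4)),
      breast_semiheight_mm = pmax(30, rnorm(n, template$breast_semiheight_mm, 3)),
      pectoral_angle_deg = pmin(45, pmax(22, rnorm(n, template$pectoral_angle_deg, 5))),
      pectoral_top_mm = pmin(50, pmax(25, rnorm(n, template$pectoral_top_mm, 4))),
      seed_left = derive_seeds(sample.int(.Machine$integer.max - 1L, 1), n),
      seed_right = derive_seeds(sample.int(.Machine$integer.max - 1L, 1), n),
      age = rnorm(n, 57, 11) + (covariate_shifts$age %||% 0) * 11 * label,
      bmi = rnorm(n, 29.6, 7.2) + (covariate_shifts$bmi %||% 0) * 7.2 * label
    )
    dens_shift <- covariate_shifts$density %||% 0.25
    # true dense fraction is computed lazily per image; here pre-draw the noise
    manifest$density_noise <- rnorm(n, 0, 0.015)
    manifest$density_shift <- dens_shift
    structure(list(manifest = manifest, template = template, seed = seed),
              class = "phantom_cohort")
  })
}

#' Materialize one breast image of a cohort woman
#'
#' @param cohort a [generate_cohort()] result.
#' @param i row index into `cohort$manifest`.
#' @param side `"left"` or `"right"`.
#' @return As [generate_phantom()].
#' @export
cohort_image <- function(cohort, i, side = c("left", "right")) {
  side <- match.arg(side)
  m <- cohort$manifest[i, ]
  tpl <- cohort$template
  spec <- phantom_spec(
    rows = tpl$rows, cols = tpl$cols, pixel_spacing_mm = tpl$pixel_spacing_mm,
    laterality = side,
    breast_radius_mm = m$breast_radius_mm,
    breast_semiheight_mm = m$breast_semiheight_mm,
    pectoral_angle_deg = m$pectoral_angle_deg,
    pectoral_top_mm = m$pectoral_top_mm,
    nipple_radius_mm = tpl$nipple_radius_mm,
    n_blobs = tpl$n_blobs, blob_radius_mm = tpl$blob_radius_mm,
    blob_contrast = tpl$blob_contrast,
    noise_sd = tpl$noise_sd, noise_corr_mm = tpl$noise_corr_mm,
    effect = if (m$label == 1L) tpl$effect else "none",
    effect_size = if (m$label == 1L) tpl$effect_size else 0,
    effect_f = tpl$effect_f,
    seed = if (side == "left") m$seed_left else m$seed_right)
  ph <- generate_phantom(spec)
  ph$image$subject_id <- m$subject_id
  ph$image$side_label <- paste0(m$subject_id, "_", side)
  ph
}

#' Covariate table of a cohort, with the density measure filled in
#'
#' The density covariate is the woman's true dense-area fraction (mean of both
#' sides) plus pre-drawn Gaussian noise plus the configured case shift.
#' Computing it requires materializing the masks, so it is exposed as a
#' separate step; pass `dense_fraction` if the masks were already generated.
#'
#' @param cohort a `phantom_cohort`.
#' @param dense_fraction optional numeric vector (one per woman) of true
#'   dense-area fractions; computed from the ground-truth masks if omitted.
#' @return data.frame: subject_id, label, age, bmi, density.
#' @export
cohort_covariates <- function(cohort, dense_fraction = NULL) {
  m <- cohort$manifest
  if (is.null(dense_fraction)) {
    dense_fraction <- vapply(seq_len(nrow(m)), function(i) {
      fr <- vapply(c("left", "right"), function(s) {
        t <- cohort_image(cohort, i, s)$truth
        sum(t$dense) / sum(t$breast & !t$pect)
      }, numeric(1))
      mean(fr)
    }, numeric(1))
  }
  sd_dens <- max(sd(dense_fraction), 1e-6)
  data.frame(subject_id = m$subject_id, label = m$label,
             age = m$age, bmi = m$bmi,
             density = dense_fraction + m$density_noise +
               m$density_shift * sd_dens * m$label)
}
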