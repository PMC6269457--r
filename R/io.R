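#' Construct a mammogram object
#'
#' Container for a 2D "for processing" mammographic image: a matrix of
#' non-negative intensities plus the metadata the anatomical pipeline needs
#' (isotropic pixel spacing in mm, laterality, view).
#'
#' @param pixels numeric matrix (>= 2 rows and columns) of finite,
#'   non-negative intensities; by convention higher value = denser tissue.
#' @param pixel_spacing_mm positive scalar, isotropic pixel spacing in mm.
#' @param laterality `"left"` or `"right"`.
#' @param view projection view; only `"MLO"` is supported.
#' @param subject_id,side_label opaque identifier strings.
#' @return An object of class `mammogram`.
#' @export
mammogram <- function(pixels, pixel_spacing_mm, laterality = c("left", "right"),
                      view = "MLO", subject_id = "unknown", side_label = laterality[1]) {
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || nrow(pixels) < 2 || ncol(pixels) < 2)
    stop_mammotex("pixels must be a matrix with >= 2 rows and columns", "mammotex_format_error")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_mammotex("pixel intensities must be finite and >= 0", "mammotex_format_error")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1 ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop_mammotex("pixel_spacing_mm must be a positive scalar", "mammotex_config_error")
  if (!identical(view, "MLO"))
    stop_mammotex("only the MLO view is supported", "mammotex_format_error")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 laterality = laterality, view = view,
                 subject_id = subject_id, side_label = side_label),
            class = "mammogram")
}

#' @method print mammogram
#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %d x %d px @ %.4g mm/px, %s %s, subject %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm,
              x$laterality, x$view, x$subject_id))
  invisible(x)
}

#' Read a mammographic image from disk
#'
#' Reads PNG or TIFF grayscale images into a [mammogram]. Integer intensities
#' are preserved exactly (16-bit PNGs are rescaled back to 0..65535 counts).
#' Pixel spacing must be supplied via `spacing_override` since PNG/TIFF carry
#' no calibrated spacing; laterality is taken from the `laterality` argument
#' or from a `_L`/`_R` (or `_left`/`_right`) filename token.
#'
#' @param path file path (.png, .tif/.tiff). DICOM is not supported by this
#'   build; convert to 16-bit PNG/TIFF preserving raw counts.
#' @param spacing_override positive scalar, pixel spacing in mm.
#' @param laterality optional `"left"`/`"right"`; default parsed from filename.
#' @param invert if `TRUE`, intensities are flipped (`max - x`) on load, for
#'   vendors whose raw images encode denser tissue as darker. The package
#'   convention is higher value = denser tissue.
#' @param subject_id identifier; default the file base name.
#' @return A [mammogram].
#' @export
read_image <- function(path, spacing_override = NULL, laterality = NULL,
                       invert = FALSE, subject_id = NULL) {
  if (!file.exists(path))
    stop_mammotex(sprintf("file not found: %s", path), "mammotex_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop_mammotex("DICOM input is not supported; convert to 16-bit PNG/TIFF",
                  "mammotex_format_error")
  px <- switch(ext,
    png = {
      img <- png::readPNG(path, info = TRUE)
      bits <- attr(img, "info")$bit.depth %||% 8L
      out <- round(as_gray(img) * (2^bits - 1))
      attributes(out) <- list(dim = dim(out))
      out
    },
    tif = ,
    tiff = {
      img <- tiff::readTIFF(path, as.is = TRUE)
      as_gray(img)
    },
    stop_mammotex(sprintf("unsupported image format: .%s", ext), "mammotex_format_error")
  )
  if (length(dim(px)) != 2)
    stop_mammotex("image is not 2D grayscale", "mammotex_format_error")
  if (is.null(spacing_override))
    stop_mammotex("no pixel spacing available: supply spacing_override (mm)",
                  "mammotex_config_error")
  if (is.null(laterality)) laterality <- laterality_from_filename(path)
  if (isTRUE(invert)) px <- max(px) - px
  mammogram(px, spacing_override, laterality,
            subject_id = subject_id %||% tools::file_path_sans_ext(basename(path)))
}

as_gray <- function(img) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

laterality_from_filename <- function(path) {
  b <- tolower(basename(path))
  if (grepl("(_|-)l(eft)?(_|-|\\.)", b)) return("left")
  if (grepl("(_|-)r(ight)?(_|-|\\.)", b)) return("right")
  stop_mammotex("laterality not in filename; pass laterality=", "mammotex_config_error")
}

#' Write a binary mask or label image as PNG
#'
#' Binary masks are written 0/255; integer label images are scaled into 8 bits.
#' @param mask logical or small-integer matrix.
#' @param path output .png path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (is.logical(mask)) mask * 1 else as.numeric(mask) / max(1, max(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Run configuration for the texture pipeline
#'
#' Bundles all tunable parameters: the polar grid radius unit `D_mm`, the CBA
#' fraction `f` (in `[0.5, 1]`), the weight-map parameters `a`, `b`, `c` (unit
#' interval), gray-level quantization depth, feature-filter threshold and
#' cross-validation layout. Defaults follow the optimized operating point of
#' the method (`D = 6.3` mm, `a = 0.8`, `b = 1`, `c = 0.4`).
#'
#' @param D_mm polar grid radius unit in mm.
#' @param f CBA fraction of the nipple-pectoralis distance, in `[0.5, 1]`.
#' @param a weight of CBA versus UOA proximity in the position weights S.
#' @param b weight of dense versus fatty tissue in the tissue weights T.
#' @param c_mix weight of S versus T in the final map W (named `c` in reports).
#' @param gray_levels quantization depth G for co-occurrence/run-length.
#' @param correlation_threshold absolute Pearson correlation above which one of
#'   a feature pair (the lower-IQR one) is removed.
#' @param cv_outer_folds,cv_inner_folds nested cross-validation layout.
#' @param seed integer RNG seed for all stochastic steps.
#' @param region_min_coverage minimum fraction of a polar region that must lie
#'   in breast tissue for the region to be retained.
#' @param region_min_pixels minimum region pixel count.
#' @param density_clusters number of fuzzy c-means density clusters K.
#' @param lattice_spacing_mm,lattice_window_mm lattice comparator geometry.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(D_mm = 6.3, f = 0.75, a = 0.8, b = 1, c_mix = 0.4,
                       gray_levels = 128L, correlation_threshold = 0.90,
                       cv_outer_folds = 10L, cv_inner_folds = 5L, seed = 1L,
                       region_min_coverage = 0.5, region_min_pixels = 25L,
                       density_clusters = 4L,
                       lattice_spacing_mm = 6.3, lattice_window_mm = 6.3) {
  cfg <- list(D_mm = D_mm, f = f, a = a, b = b, c_mix = c_mix,
              gray_levels = as.integer(gray_levels),
              correlation_threshold = correlation_threshold,
              cv_outer_folds = as.integer(cv_outer_folds),
              cv_inner_folds = as.integer(cv_inner_folds),
              seed = as.integer(seed),
              region_min_coverage = region_min_coverage,
              region_min_pixels = as.integer(region_min_pixels),
              density_clusters = as.integer(density_clusters),
              lattice_spacing_mm = lattice_spacing_mm,
              lattice_window_mm = lattice_window_mm)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_mammotex(msg, "mammotex_config_error")
  chk(cfg$D_mm > 0, "D_mm must be positive")
  chk(cfg$f >= 0.5 && cfg$f <= 1, "f must lie in [0.5, 1]")
  for (p in c("a", "b", "c_mix"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, sprintf("%s must lie in [0, 1]", p))
  chk(cfg$gray_levels >= 2, "gray_levels must be >= 2")
  chk(cfg$correlation_threshold > 0 && cfg$correlation_threshold <= 1,
      "correlation_threshold must lie in (0, 1]")
  chk(cfg$cv_outer_folds >= 2 && cfg$cv_inner_folds >= 2, "fold counts must be >= 2")
  chk(cfg$region_min_coverage > 0 && cfg$region_min_coverage <= 1,
      "region_min_coverage must lie in (0, 1]")
  invisible(cfg)
}

#' Serialize / parse a run configuration
#'
#' YAML round-trip of every [run_config] field.
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_mammotex(sprintf("config not found: %s", path), "mammotex_io_error")
  do.call(run_config, yaml::read_yaml(path))
}

#' Write / read a per-region feature table
#'
#' One row per retained polar-grid region: region id, ring and sector indices,
#' centroid, weight W and the 34 texture feature columns TF1..TF34. The TSV
#' round-trips losslessly through [read_feature_table()].
#'
#' @param maps a `weighted_feature_maps` object (see [compute_feature_maps()]
#'   and [combine_weights()]), or any list with elements `regions` (data.frame
#'   with region_id, ring, sector, centroid_row, centroid_col), `W` and
#'   `features` (regions x 34 matrix).
#' @param path output TSV path.
#' @export
write_feature_table <- function(maps, path) {
  feat <- maps$features
  if (is.null(dim(feat))) feat <- matrix(feat, nrow = 0, ncol = 34)
  colnames(feat) <- tf_names()
  tab <- cbind(maps$regions[, c("region_id", "ring", "sector",
                                "centroid_row", "centroid_col")],
               W = maps$W, as.data.frame(feat))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop_mammotex(sprintf("feature table not found: %s", path), "mammotex_io_error")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a model or comparison report as JSON
#' @param report named list of results (numbers, vectors, strings).
#' @param path output .json path.
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
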