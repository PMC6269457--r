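test_that("standardization rotates to a vertical pectoral line and flips right breasts", {
  ph <- generate_phantom(phantom_spec(seed = 3, pectoral_angle_deg = 32))
  seg <- segment_all(ph$image)
  std <- standardize_orientation(ph$image, seg)
  expect_false(std$transform$flip)
  expect_equal(std$transform$rotation_deg, seg$pect_line$angle_deg)
  # after standardization the pectoralis boundary is vertical: regressing its
  # rightmost column on the row index must give a near-zero slope
  cols <- apply(std$pectoralis_mask, 1, function(r) if (any(r)) max(which(r)) else NA)
  ok <- !is.na(cols)
  slope <- coef(lm(cols[ok] ~ which(ok)))[2]
  expect_lt(abs(slope), 0.05)  # < ~3 degrees from vertical
  # right breast with a vertical line: flip only
  phr <- generate_phantom(phantom_spec(seed = 3, laterality = "right"))
  segr <- segment_all(phr$image)
  stdr <- standardize_orientation(phr$image, segr)
  expect_true(stdr$transform$flip)
})

test_that("standardization transform round-trips masks nearly exactly", {
  ph <- test_phantom(6)
  seg <- segment_all(ph$image)
  std <- standardize_orientation(ph$image, seg)
  back <- mammotex:::invert_transform(std$breast_mask, std$transform, FALSE)
  orig <- seg$breast_mask
  expect_gt(mammotex:::dice(back, orig), 0.98)
  # the flip component inverts exactly
  tr_flip <- list(flip = TRUE, rotation_deg = 0, dims = dim(orig))
  expect_identical(
    mammotex:::invert_transform(mammotex:::apply_transform(orig, tr_flip, FALSE),
                                tr_flip, FALSE), orig)
})

test_that("a missing pectoral line falls back to identity rotation with a warning", {
  ph <- generate_phantom(phantom_spec(seed = 3, pectoral_angle_deg = NA))
  seg <- segment_all(ph$image)
  expect_warning(std <- standardize_orientation(ph$image, seg), "pectoral")
  expect_equal(std$transform$rotation_deg, 0)
  expect_true(std$flagged)
})

test_that("nipple localization matches brute-force centroid on a half disk", {
  nr <- 121; nc <- 100; R <- 80
  mask <- half_disk_mask(nr, nc, R)
  sp <- 0.5
  nip <- locate_nipple(mask, sp)
  # independent enumeration of the paper's construction
  c_max <- max(which(colSums(mask) > 0))
  box <- round(15 / sp)
  rows_at <- which(mask[, c_max]); r_mid <- mean(range(rows_at))
  rs <- c(); cs <- c()
  for (r in max(1, ceiling(r_mid - box / 2)):min(nr, floor(r_mid + box / 2)))
    for (c in max(1, c_max - box + 1):c_max)
      if (mask[r, c]) { rs <- c(rs, r); cs <- c(cs, c) }
  expect_equal(nip, c(mean(rs), mean(cs)), tolerance = 1e-12)
  expect_lt(abs(nip[1] - (nr + 1) / 2), 2)
  expect_lt(abs(nip[2] - R), 15 / sp)
  # degenerate single-column mask
  m1 <- matrix(FALSE, 30, 20); m1[10:20, 7] <- TRUE
  expect_equal(locate_nipple(m1, 0.5), c(15, 7))
  expect_error(locate_nipple(matrix(FALSE, 5, 5), 0.5),
               class = "mammotex_segmentation_error")
})

test_that("nipple lands within 1.5 cm of the phantom bump", {
  ph <- test_phantom(8)
  ctx <- breast_context(ph$image)
  nip <- mammotex:::invert_point(ctx$diagnostics$nipple, ctx$diagnostics$transform)
  err_mm <- sqrt(sum((nip - ph$truth$nipple)^2)) * ph$image$pixel_spacing_mm
  expect_lt(err_mm, 15)
})

test_that("quadrant geometry: r_P, CBA/UOA definitions and bounds on f", {
  mask <- half_disk_mask(301, 260, 220)
  quad <- define_quadrants(c(151, 200), mask, pect_col = 0, f = 0.5,
                           pixel_spacing_mm = 0.1)
  expect_equal(quad$r_P_mm, 20)
  expect_error(define_quadrants(c(151, 200), mask, 0, f = 0.3, 0.1),
               class = "mammotex_parameter_error")
  # brute-force CBA pixel recount
  d <- sqrt((row(mask) - 151)^2 + (col(mask) - 200)^2) * 0.1
  expect_equal(sum(quad$cba_mask), sum(mask & d < 0.5 * 20))
  expect_equal(sum(quad$uoa_mask), sum(mask & row(mask) < 151 & d > 0.5 * 20))
  expect_false(any(quad$cba_mask & quad$uoa_mask))
  # f = 1 with the whole breast within r_P of the nipple: UOA empty
  small <- matrix(FALSE, 60, 50)
  small[(row(small) - 30)^2 + (col(small) - 40)^2 <= 25] <- TRUE
  q2 <- define_quadrants(c(30, 40), small, pect_col = 0, f = 1,
                         pixel_spacing_mm = 1)
  expect_equal(sum(q2$uoa_mask), 0)
  expect_gt(sum(q2$cba_mask), 0)
})

test_that("polar grid partitions the breast and scales with D", {
  ph <- test_phantom(10)
  seg <- segment_all(ph$image)
  std <- standardize_orientation(ph$image, seg)
  nip <- locate_nipple(std$breast_mask, 0.5)
  quad <- define_quadrants(nip, std$breast_mask, std$pect_col, 0.75, 0.5)
  g1 <- build_polar_grid(nip, std$breast_mask, 6.3, quad$r_P_mm, 0.5)
  # candidate regions partition breast-minus-pectoralis exactly
  all_idx <- sort(unlist(g1$pixel_idx))
  expect_identical(all_idx, which(std$breast_mask))
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_equal(sum(g1$regions$n_pixels), sum(std$breast_mask))
  # retained regions have adequate coverage and size
  kept <- g1$regions[g1$regions$retained, ]
  expect_true(all(kept$coverage >= 0.5))
  expect_true(all(kept$n_pixels >= 25))
  # analytic full-region area is non-decreasing in ring index
  w <- diff(g1$span_rad) / g1$n_sectors
  area <- function(i) w / 2 * ((i + 1)^2 - i^2) * 6.3^2
  rings <- sort(unique(kept$ring))
  expect_true(all(diff(area(rings)) >= 0))
  # doubling D strictly decreases the region count
  g2 <- build_polar_grid(nip, std$breast_mask, 12.6, quad$r_P_mm, 0.5)
  expect_lt(sum(g2$regions$retained), sum(g1$regions$retained))
  expect_error(build_polar_grid(nip, std$breast_mask, -1, quad$r_P_mm, 0.5),
               class = "mammotex_parameter_error")
})

test_that("r_P is stable under resampling and mirroring", {
  pl <- test_phantom(9)
  ctx1 <- breast_context(pl$image)
  hi <- generate_phantom(phantom_spec(seed = 9, rows = 360L, cols = 300L,
                                      pixel_spacing_mm = 0.25))
  ctx2 <- breast_context(hi$image)
  expect_lt(abs(ctx1$diagnostics$r_P_mm - ctx2$diagnostics$r_P_mm) /
              ctx1$diagnostics$r_P_mm, 0.02)
  pr <- test_phantom(9, laterality = "right")
  ctx3 <- breast_context(pr$image)
  expect_equal(ctx3$diagnostics$r_P_mm, ctx1$diagnostics$r_P_mm, tolerance = 1e-9)
  expect_equal(ctx3$diagnostics$nipple, ctx1$diagnostics$nipple, tolerance = 1e-9)
})
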