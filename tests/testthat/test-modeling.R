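test_that("bilateral aggregation averages per woman", {
  sig <- matrix(rnorm(6 * 68), 6, 68)
  ids <- rep(c("A", "B", "C"), each = 2)
  agg <- aggregate_signatures(sig, ids)
  expect_equal(dim(agg), c(3, 68))
  expect_equal(agg["B", ], (sig[3, ] + sig[4, ]) / 2)
  # identical left/right signatures: per-woman equals either one
  sig[2, ] <- sig[1, ]
  expect_equal(aggregate_signatures(sig, ids)["A", ], sig[1, ])
  expect_warning(aggregate_signatures(sig[1:3, ], c("A", "A", "B")), "single")
})

test_that("correlation filter removes the lower-IQR member of each pair", {
  set.seed(50)
  base <- rnorm(60)
  x <- cbind(a = base * 2,            # IQR ~ 2x
             b = base,                # duplicate, lower IQR
             c = rnorm(60), d = rnorm(60))
  out <- correlation_filter(x, 0.9)
  expect_identical(attr(out, "removed"), "b")
  expect_identical(colnames(out), c("a", "c", "d"))
  # independent noise columns survive untouched
  x2 <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, letters[1:5]))
  expect_length(attr(correlation_filter(x2, 0.9), "removed"), 0)
})

test_that("correlation filter matches a naive re-implementation on cliques", {
  naive_filter <- function(x, th) {
    act <- colnames(x)
    repeat {
      r <- suppressWarnings(cor(x[, act, drop = FALSE]))
      r[!is.finite(r)] <- 0
      diag(r) <- 0
      if (max(abs(r)) <= th) break
      ij <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
      pair <- act[sort(ij)]
      iqrs <- apply(x[, pair], 2, IQR)
      victim <- if (iqrs[2] < iqrs[1] || iqrs[2] == iqrs[1]) pair[2] else pair[1]
      act <- setdiff(act, victim)
    }
    act
  }
  set.seed(51)
  for (rep in 1:5) {
    base <- rnorm(80)
    x <- cbind(p = base + rnorm(80, sd = 0.05),
               q = base * 1.5 + rnorm(80, sd = 0.05),
               r = base + rnorm(80, sd = 0.08),
               s = rnorm(80))
    out <- correlation_filter(x, 0.9)
    expect_identical(colnames(out), naive_filter(x, 0.9))
    # the filter never removes the last member of a correlated clique
    expect_true(any(c("p", "q", "r") %in% colnames(out)))
  }
})

test_that("nested elastic net detects strong signal and is reproducible", {
  set.seed(60)
  n <- 400
  x <- matrix(rnorm(n * 30), n, 30); colnames(x) <- paste0("F", 1:30)
  y <- rep(c(1L, 0L), c(100, 300))
  x[y == 1, 1:10] <- x[y == 1, 1:10] + 1   # standardized effect 1.0
  m <- suppressWarnings(fit_elastic_net_cv(x, y, seed = 4, boot_reps = 200))
  expect_gte(m$cv_auc, 0.85)
  expect_false(any(is.na(m$oof)))
  expect_true(all(table(seq_along(y)[!is.na(m$oof)]) == 1))
  expect_gt(length(m$selected_features), 0)
  m2 <- suppressWarnings(fit_elastic_net_cv(x, y, seed = 4, boot_reps = 200))
  expect_identical(m$oof, m2$oof)
  expect_identical(m$cv_auc, m2$cv_auc)
  expect_identical(m$ci95, m2$ci95)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  # single-replicate null cv-AUC has sd ~0.08 at n = 125 (25 cases); bands
  # below are ~3.5 sd for the mean of 6 and for single draws
  set.seed(61)
  aucs <- sapply(1:6, function(s) {
    x <- matrix(rnorm(125 * 40), 125, 40); colnames(x) <- paste0("F", 1:40)
    y <- sample(rep(c(1L, 0L), c(25, 100)))
    suppressWarnings(fit_elastic_net_cv(x, y, seed = s, boot_reps = 50))$cv_auc
  })
  expect_gt(mean(aucs), 0.39)
  expect_lt(mean(aucs), 0.61)
  expect_true(all(aucs > 0.22 & aucs < 0.78))
})

test_that("pooled out-of-fold AUC equals exhaustive pair counting", {
  set.seed(62)
  x <- matrix(rnorm(80 * 10), 80, 10); colnames(x) <- paste0("F", 1:10)
  y <- rep(c(1L, 0L), 40)
  x[y == 1, 1] <- x[y == 1, 1] + 0.8
  m <- suppressWarnings(fit_elastic_net_cv(x, y, outer_folds = 5, seed = 9,
                                           boot_reps = 100))
  expect_equal(m$cv_auc, brute_auc(m$oof, y), tolerance = 1e-10)
  expect_error(fit_elastic_net_cv(x, rep(1L, 80)), class = "mammotex_fold_error")
})

test_that("DeLong test: conventions, significance, permutation agreement", {
  set.seed(63)
  y <- rep(c(1L, 0L), c(20, 40))
  p1 <- runif(60)
  d0 <- delong_test(p1, p1, y)
  expect_equal(d0$delta_auc, 0)
  expect_equal(d0$p, 1)
  # perfect vs random predictor, n = 200
  y2 <- rep(c(1L, 0L), each = 100)
  perfect <- y2 + rnorm(200, sd = 0.01)
  rand <- runif(200)
  expect_lt(delong_test(perfect, rand, y2)$p, 0.001)
  # small-sample p within 0.02 of the paired permutation reference
  y3 <- rep(c(1L, 0L), c(25, 35))
  pa <- y3 * 0.7 + runif(60)
  pb <- y3 * 0.25 + runif(60)
  dl <- delong_test(pa, pb, y3)
  pp <- perm_delong_p(pa, pb, y3, reps = 4000, seed = 2)
  expect_lt(abs(dl$p - pp), 0.02)
  expect_error(delong_test(pa, pb[-1], y3), class = "mammotex_parameter_error")
})

test_that("NRI components match per-subject counting", {
  y <- rep(c(1L, 0L), c(4, 6))
  old <- rep(0.5, 10)
  new <- c(rep(0.9, 4), rep(0.1, 6))
  r <- nri(new, old, y)
  expect_equal(r$nri_case_component, 1)
  expect_equal(r$nri_control_component, 1)
  expect_equal(r$nri_overall, 2)
  r0 <- nri(old, old, y)
  expect_equal(unlist(r0[1:3]), c(nri_overall = 0, nri_case_component = 0,
                                  nri_control_component = 0))
  set.seed(64)
  for (i in 1:5) {
    pn <- runif(30); po <- runif(30); yy <- rbinom(30, 1, 0.4)
    if (length(unique(yy)) < 2) next
    r <- nri(pn, po, yy)
    up <- 0; down <- 0
    for (j in which(yy == 1)) { up <- up + (pn[j] > po[j]); down <- down + (pn[j] < po[j]) }
    expect_equal(r$nri_case_component, (up - down) / sum(yy == 1))
  }
})

test_that("baseline augmentation shows texture value only when it exists", {
  set.seed(65)
  n <- 160
  y <- rep(c(1L, 0L), c(40, 120))
  covs <- data.frame(density = rnorm(n) + 0.6 * y, bmi = rnorm(n), age = rnorm(n))
  texture_signal <- matrix(rnorm(n * 3), n, 3,
                           dimnames = list(NULL, paste0("T", 1:3)))
  texture_signal[, 1] <- texture_signal[, 1] + 0.9 * y
  res <- augment_baseline(covs, texture_signal, y, seed = 2)
  expect_gt(res$augmented$auc, res$baseline$auc)
  expect_gt(res$baseline$auc, 0.55)
  # constant covariates carry no information
  const <- data.frame(density = rep(1, n), bmi = rep(2, n))
  res0 <- suppressWarnings(augment_baseline(const, texture_signal[, 2:3], y, seed = 2))
  expect_gt(res0$baseline$auc, 0.42); expect_lt(res0$baseline$auc, 0.58)
  # missing covariates are dropped with a warning
  covs$bmi[c(3, 9)] <- NA
  expect_warning(res2 <- augment_baseline(covs, texture_signal, y, seed = 2),
                 "missing")
  expect_equal(res2$n_dropped, 2)
  expect_length(res2$baseline$oof, n - 2)
})

test_that("a single-tuple grid is returned as the optimum", {
  # lightweight hand-built contexts: 30 women x 2 breasts, 12 regions each
  set.seed(66)
  fake_ctx <- function() {
    structure(list(
      per_D = list("6.3" = list(
        features = matrix(rnorm(12 * 34, 100, 10), 12, 34,
                          dimnames = list(NULL, tf_names())),
        centroids = cbind(runif(12, 1, 100), runif(12, 1, 100)),
        chat = runif(12), n_regions = 12)),
      per_f = list("0.75" = list(cba_centroid = c(50, 80),
                                 uoa_centroid = c(20, 40), r_P_mm = 40)),
      K = 4L, subject_id = "x", side_label = "x"),
      class = "breast_context")
  }
  ctxs <- replicate(60, fake_ctx(), simplify = FALSE)
  ids <- rep(sprintf("w%02d", 1:30), each = 2)
  labels <- rep(c(1L, 0L), c(10, 20))
  cfg <- run_config(cv_outer_folds = 3, cv_inner_folds = 2, seed = 1)
  grid <- data.frame(D_mm = 6.3, f = 0.75, a = 0.8, b = 1, c_mix = 0.4)
  res <- suppressWarnings(optimize_parameters(ctxs, ids, labels, grid, cfg))
  expect_equal(res$best, grid)
  expect_equal(nrow(res$auc_table), 1)
  expect_s3_class(res$model, "model_result")
  expect_error(optimize_parameters(ctxs, ids, labels, grid[0, ], cfg),
               class = "mammotex_parameter_error")
})
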