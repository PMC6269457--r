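# Case-control modeling: per-woman aggregation, IQR/correlation feature
# filtering, elastic-net logistic regression with nested cross-validation,
# cross-validated AUC, DeLong test, net reclassification improvement, and
# parameter-grid optimization over (D, f, a, b, c).

#' Aggregate per-breast signatures into per-woman features
#'
#' Per-woman texture estimates are the average of the woman's (usually two)
#' bilateral breast signatures. Women with a single breast are allowed but
#' flagged with a warning.
#'
#' @param signatures numeric matrix, one row per breast, 68 columns.
#' @param subject_ids character vector, one per row of `signatures`.
#' @return numeric matrix, one row per woman (rownames = subject ids), in
#'   first-appearance order of the ids.
#' @export
aggregate_signatures <- function(signatures, subject_ids) {
  ids <- unique(subject_ids)
  counts <- table(subject_ids)
  if (any(counts == 1))
    warning(sprintf("%d women have a single breast signature", sum(counts == 1)))
  out <- rowsum(signatures, group = factor(subject_ids, levels = ids)) /
    as.vector(counts[ids])
  rownames(out) <- ids
  out
}

#' Remove one feature of each highly correlated pair
#'
#' Pairs with absolute Pearson correlation above `threshold` are visited in
#' decreasing |r| order; for each pair whose members are both still active,
#' the member with the smaller interquartile range (IQR) is removed (ties
#' remove the later column), keeping the more variable representative of each
#' correlated clique.
#'
#' @param x numeric feature matrix (>= 2 rows) with column names.
#' @param threshold absolute correlation threshold in (0, 1].
#' @return the reduced matrix, with attribute `removed` (character vector of
#'   dropped column names).
#' @export
correlation_filter <- function(x, threshold = 0.90) {
  if (nrow(x) < 2) stop_mammotex("need >= 2 rows", "mammotex_parameter_error")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  v <- apply(x, 2, var)
  active <- rep(TRUE, ncol(x))
  usable <- which(v > 0)
  if (length(usable) >= 2) {
    r <- suppressWarnings(cor(x[, usable, drop = FALSE]))
    r[!is.finite(r)] <- 0
    ut <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
    if (nrow(ut) > 0) {
      ord <- order(-abs(r[ut]))
      iqr <- apply(x, 2, stats::IQR)
      for (k in ord) {
        i <- usable[ut[k, 1]]; j <- usable[ut[k, 2]]
        if (!active[i] || !active[j]) next
        drop_j <- iqr[j] < iqr[i] || (iqr[j] == iqr[i])  # tie: later column
        active[if (drop_j) j else i] <- FALSE
      }
    }
  }
  out <- x[, active, drop = FALSE]
  attr(out, "removed") <- colnames(x)[!active]
  out
}

# Balanced stratified fold assignment (1..k per subject).
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Trapezoidal ROC AUC (equals the midrank Mann-Whitney statistic).
auc_value <- function(pred, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, pred, direction = "<",
                                 levels = c(0, 1), quiet = TRUE)))
}

#' Elastic-net logistic regression with nested cross-validation
#'
#' Outer folds provide leakage-free out-of-fold predicted probabilities (each
#' subject predicted exactly once); within each outer training fold, features
#' are z-scored (the scaling applied to the held-out fold), zero-variance
#' columns are dropped, and an inner stratified cross-validation selects the
#' elastic-net mixing `alpha` and penalty `lambda` by inner AUC over a fixed
#' grid. The cross-validated AUC is the pooled out-of-fold AUC; its 95% CI
#' comes from a stratified bootstrap of the pooled predictions. The reported
#' feature set is the nonzero coefficients of a final refit on all data at the
#' hyperparameters most often chosen across outer folds.
#'
#' @param x numeric feature matrix (one row per woman).
#' @param y 0/1 labels.
#' @param outer_folds,inner_folds fold counts (stratified).
#' @param seed RNG seed (folds and bootstrap).
#' @param alphas elastic-net mixing grid (a coarse near-ridge / balanced /
#'   near-lasso grid by default; elastic-net fits vary slowly in the mixing
#'   parameter, so this keeps the nested search affordable).
#' @param nlambda penalty path length per alpha.
#' @param boot_reps bootstrap replicates for the AUC CI.
#' @return `model_result`: `oof` (out-of-fold probabilities), `labels`,
#'   `cv_auc`, `ci95`, `fold` assignment, `chosen` (per-fold alpha/lambda),
#'   `final_alpha`, `final_lambda`, `selected_features`, `coefficients`.
#' @export
fit_elastic_net_cv <- function(x, y, outer_folds = 10L, inner_folds = 5L,
                               seed = 1L, alphas = c(0.1, 0.5, 0.9),
                               nlambda = 20L, boot_reps = 2000L) {
  y <- as.integer(y)
  if (length(unique(y)) != 2)
    stop_mammotex("labels must contain both classes", "mammotex_fold_error")
  fold <- stratified_folds(y, outer_folds, seed)
  oof <- rep(NA_real_, length(y))
  chosen <- data.frame(fold = seq_len(outer_folds), alpha = NA_real_, lambda = NA_real_)
  for (k in seq_len(outer_folds)) {
    tr <- fold != k; te <- !tr
    if (length(unique(y[tr])) != 2)
      stop_mammotex("single-class outer training fold", "mammotex_fold_error")
    xs <- scale_fold(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    ytr <- y[tr]
    inner_id <- stratified_folds(ytr, inner_folds, seed + 1000L + k)
    best <- list(cvm = -Inf)
    for (a in alphas) {
      # master fit defines the lambda path; inner folds are scored by the
      # pooled inner out-of-fold AUC at every lambda on that path
      master <- glmnet::glmnet(xs$train, ytr, family = "binomial",
                               alpha = a, nlambda = nlambda, standardize = FALSE)
      lam <- master$lambda
      pred_in <- matrix(NA_real_, nrow(xs$train), length(lam))
      for (j in seq_len(inner_folds)) {
        itr <- inner_id != j
        fit <- glmnet::glmnet(xs$train[itr, , drop = FALSE], ytr[itr],
                              family = "binomial", alpha = a, lambda = lam,
                              standardize = FALSE)
        pred_in[!itr, ] <- predict(fit, xs$train[!itr, , drop = FALSE],
                                   s = lam, type = "link")
      }
      inner_auc <- apply(pred_in, 2, auc_mw, y = ytr)
      i <- which.max(inner_auc)
      if (inner_auc[i] > best$cvm)
        best <- list(cvm = inner_auc[i], alpha = a, lambda = lam[i], fit = master)
    }
    oof[te] <- as.numeric(predict(best$fit, newx = xs$test,
                                  s = best$lambda, type = "response"))
    chosen$alpha[k] <- best$alpha; chosen$lambda[k] <- best$lambda
  }
  cv_auc <- auc_value(oof, y)
  ci95 <- with_seed(seed + 2000L, boot_auc_ci(oof, y, boot_reps))
  # final refit at the modal alpha / median chosen lambda
  tab <- table(chosen$alpha)
  final_alpha <- as.numeric(names(tab)[which.max(tab)])
  final_lambda <- median(chosen$lambda[chosen$alpha == final_alpha])
  xs_all <- scale_fold(x, x)
  final <- glmnet::glmnet(xs_all$train, y, family = "binomial",
                          alpha = final_alpha, lambda = final_lambda,
                          standardize = FALSE)
  cf <- as.matrix(coef(final))
  nz <- rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  structure(list(oof = oof, labels = y, cv_auc = cv_auc, ci95 = ci95,
                 fold = fold, chosen = chosen, final_alpha = final_alpha,
                 final_lambda = final_lambda, selected_features = nz,
                 coefficients = cf[, 1]),
            class = "model_result")
}

# Z-score columns on the training rows; drop training-zero-variance columns
# (warned) and apply the same transform to the test rows.
scale_fold <- function(train, test) {
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  keep <- sdev > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance columns in training fold", sum(!keep)))
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  te <- sweep(sweep(test[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  list(train = tr, test = te)
}

boot_auc_ci <- function(pred, y, reps) {
  cases <- which(y == 1); controls <- which(y == 0)
  aucs <- vapply(seq_len(reps), function(i) {
    idx <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
    auc_mw(pred[idx], y[idx])
  }, numeric(1))
  unname(quantile(aucs, c(0.025, 0.975)))
}

# Midrank Mann-Whitney AUC (fast; used for bootstrap resamples).
auc_mw <- function(pred, y) {
  r <- rank(pred)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @method print model_result
#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> cross-validated AUC %.3f (95%% CI %.3f-%.3f), %d features selected\n",
              x$cv_auc, x$ci95[1], x$ci95[2], length(x$selected_features)))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided covariance-based comparison of the AUCs of two paired prediction
#' vectors on the same subjects. Identical (or variance-degenerate)
#' predictions return `delta_auc = 0, p = 1` by convention.
#'
#' @param pred_a,pred_b paired prediction vectors.
#' @param labels 0/1 labels.
#' @return list: `delta_auc` (AUC_a - AUC_b), `p`, `auc_a`, `auc_b`.
#' @export
delong_test <- function(pred_a, pred_b, labels) {
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(labels))
    stop_mammotex("predictions and labels must be paired (equal length)",
                  "mammotex_parameter_error")
  roc_a <- pROC::roc(labels, pred_a, direction = "<", levels = c(0, 1), quiet = TRUE)
  roc_b <- pROC::roc(labels, pred_b, direction = "<", levels = c(0, 1), quiet = TRUE)
  auc_a <- as.numeric(pROC::auc(roc_a)); auc_b <- as.numeric(pROC::auc(roc_b))
  if (isTRUE(all.equal(pred_a, pred_b)) || (var(pred_a - pred_b) == 0))
    return(list(delta_auc = 0, p = 1, auc_a = auc_a, auc_b = auc_b))
  tst <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  list(delta_auc = auc_a - auc_b, p = unname(tst$p.value),
       auc_a = auc_a, auc_b = auc_b)
}

#' Category-free net reclassification improvement
#'
#' "Up"/"down" is any increase/decrease of the predicted probability under the
#' new model. Case component = P(up|case) - P(down|case); control component =
#' P(down|control) - P(up|control); overall NRI is their sum.
#'
#' @param pred_new,pred_old paired prediction vectors.
#' @param labels 0/1 labels.
#' @return list: `nri_overall`, `nri_case_component`, `nri_control_component`,
#'   and the raw directional fractions `p_up_case`, `p_down_case`,
#'   `p_up_control`, `p_down_control`.
#' @export
nri <- function(pred_new, pred_old, labels) {
  if (length(pred_new) != length(pred_old) || length(pred_new) != length(labels))
    stop_mammotex("predictions and labels must be paired (equal length)",
                  "mammotex_parameter_error")
  up <- pred_new > pred_old; down <- pred_new < pred_old
  case <- labels == 1; ctrl <- labels == 0
  puc <- mean(up[case]); pdc <- mean(down[case])
  puk <- mean(up[ctrl]); pdk <- mean(down[ctrl])
  list(nri_overall = (puc - pdc) + (pdk - puk),
       nri_case_component = puc - pdc,
       nri_control_component = pdk - puk,
       p_up_case = puc, p_down_case = pdc,
       p_up_control = puk, p_down_control = pdk)
}

#' Baseline risk-factor models and texture augmentation
#'
#' Fits a logistic baseline on the supplied covariates (e.g. a breast density
#' measure adjusted by BMI and age) and an augmented model adding the texture
#' features selected by a texture `model_result`, under the same outer folds,
#' and compares the two out-of-fold AUCs with the DeLong test. Rows with
#' missing covariates are dropped with a warning.
#'
#' @param covariates numeric data.frame/matrix of per-woman covariates.
#' @param texture numeric matrix of per-woman texture features (already
#'   filtered/selected; may have zero columns for a covariates-only check).
#' @param labels 0/1 labels.
#' @param outer_folds,seed fold layout.
#' @return list: `baseline` and `augmented` (each with `oof`, `auc`),
#'   `delong` (augmented vs baseline), `labels`, `n_dropped`.
#' @export
augment_baseline <- function(covariates, texture, labels, outer_folds = 10L, seed = 1L) {
  covariates <- as.data.frame(covariates)
  cc <- stats::complete.cases(covariates)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    warning(sprintf("dropping %d women with missing covariates", n_dropped))
    covariates <- covariates[cc, , drop = FALSE]
    texture <- texture[cc, , drop = FALSE]
    labels <- labels[cc]
  }
  y <- as.integer(labels)
  fold <- stratified_folds(y, outer_folds, seed)
  oof_b <- rep(NA_real_, length(y)); oof_a <- oof_b
  db <- cbind(y = y, covariates)
  da <- cbind(db, as.data.frame(texture))
  for (k in seq_len(outer_folds)) {
    tr <- fold != k
    fb <- suppressWarnings(glm(y ~ ., data = db[tr, , drop = FALSE], family = binomial()))
    fa <- suppressWarnings(glm(y ~ ., data = da[tr, , drop = FALSE], family = binomial()))
    oof_b[!tr] <- suppressWarnings(predict(fb, db[!tr, , drop = FALSE], type = "response"))
    oof_a[!tr] <- suppressWarnings(predict(fa, da[!tr, , drop = FALSE], type = "response"))
  }
  list(baseline = list(oof = oof_b, auc = auc_value(oof_b, y)),
       augmented = list(oof = oof_a, auc = auc_value(oof_a, y)),
       delong = delong_test(oof_a, oof_b, y),
       labels = y, n_dropped = n_dropped)
}

#' Optimize the texture-analysis parameters over a grid
#'
#' For every candidate `(D, f, a, b, c)` tuple, per-breast signatures are
#' produced from the cached [breast_context()]s, aggregated per woman,
#' correlation/IQR-filtered and scored by nested-cross-validated AUC; the
#' tuple with the maximum cross-validated AUC wins (ties broken toward smaller
#' `D`, then larger `c`).
#'
#' @param contexts list of `breast_context`s (one per breast) whose cached
#'   `D`/`f` values cover the grid.
#' @param subject_ids character vector aligned to `contexts`.
#' @param labels per-woman 0/1 labels (order of first appearance of ids).
#' @param grid data.frame with columns `D_mm`, `f`, `a`, `b`, `c_mix`.
#' @param config a [run_config] (filter threshold, folds, seed).
#' @return list: `best` (winning grid row), `auc_table` (grid + cv_auc),
#'   `model` (the winning `model_result`).
#' @export
optimize_parameters <- function(contexts, subject_ids, labels, grid,
                                config = run_config()) {
  if (nrow(grid) == 0)
    stop_mammotex("empty parameter grid", "mammotex_parameter_error")
  aucs <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (t in seq_len(nrow(grid))) {
    g <- grid[t, ]
    sigs <- t(vapply(contexts, function(ctx) as.numeric(
      signature_from_context(ctx, g$D_mm, g$f, g$a, g$b, g$c_mix)),
      numeric(68)))
    colnames(sigs) <- c(paste0(tf_names(), "_mean"), paste0(tf_names(), "_std"))
    per_woman <- aggregate_signatures(sigs, subject_ids)
    filt <- correlation_filter(per_woman, config$correlation_threshold)
    models[[t]] <- suppressWarnings(fit_elastic_net_cv(
      filt, labels, config$cv_outer_folds, config$cv_inner_folds,
      seed = config$seed, boot_reps = 200L))
    aucs[t] <- models[[t]]$cv_auc
  }
  ord <- order(-aucs, grid$D_mm, -grid$c_mix)
  best <- ord[1]
  list(best = grid[best, ], auc_table = cbind(grid, cv_auc = aucs),
       model = models[[best]])
}
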