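# Independent brute-force oracles, deliberately written as plain loops so they
# share no code with the package implementation.

# Co-occurrence features by exhaustive pair enumeration.
brute_glcm <- function(lv, G, offsets) {
  P <- matrix(0, G, G)
  nr <- nrow(lv); nc <- ncol(lv)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (r in 1:nr) for (c in 1:nc) {
      a <- lv[r, c]
      if (a == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      b <- lv[r2, c2]
      if (b == 0) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  tot <- sum(P)
  if (tot == 0) return(c(0, 0, 1, 1, 0, 1, 0))
  P <- P / tot
  ii <- row(P); jj <- col(P)
  mu <- sum(ii * P)
  sig2 <- sum((ii - mu)^2 * P)
  pos <- P > 0
  c(contrast = sum((ii - jj)^2 * P),
    correlation = if (sig2 > 1e-12) sum((ii - mu) * (jj - mu) * P) / sig2 else 0,
    homogeneity = sum(P / (1 + abs(ii - jj))),
    energy = sum(P^2),
    entropy = -sum(P[pos] * log2(P[pos])),
    idm = sum(P / (1 + (ii - jj)^2)),
    shade = sum((ii + jj - 2 * mu)^3 * P))
}

# Run-length features by exhaustive run listing.
brute_rlm <- function(lv, G, dir) {
  nr <- nrow(lv); nc <- ncol(lv)
  dr <- dir[1]; dc <- dir[2]
  runs <- list()
  for (r in 1:nr) for (c in 1:nc) {
    g <- lv[r, c]
    if (g == 0) next
    pr <- r - dr; pc <- c - dc
    prev_same <- pr >= 1 && pr <= nr && pc >= 1 && pc <= nc && lv[pr, pc] == g
    if (prev_same) next
    len <- 0; rr <- r; cc <- c
    while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && lv[rr, cc] == g) {
      len <- len + 1; rr <- rr + dr; cc <- cc + dc
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  Np <- sum(lv > 0)
  if (length(runs) == 0) return(rep(0, 11))
  M <- do.call(rbind, runs)
  g <- M[, 1]; l <- M[, 2]; Nr <- nrow(M)
  c(SRE = sum(1 / l^2) / Nr, LRE = sum(l^2) / Nr,
    GLN = sum(table(g)^2) / Nr, RLN = sum(table(l)^2) / Nr,
    RP = Nr / Np, LGRE = sum(1 / g^2) / Nr, HGRE = sum(g^2) / Nr,
    SRLGE = sum(1 / (g^2 * l^2)) / Nr, SRHGE = sum(g^2 / l^2) / Nr,
    LRLGE = sum(l^2 / g^2) / Nr, LRHGE = sum(g^2 * l^2) / Nr)
}

# AUC by exhaustive case-control pair counting (ties count 1/2).
brute_auc <- function(pred, labels) {
  cases <- pred[labels == 1]; controls <- pred[labels == 0]
  s <- 0
  for (a in cases) for (b in controls)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Permutation reference for the paired AUC difference: randomly swap the two
# predictors per subject and recompute the AUC difference.
perm_delong_p <- function(pred_a, pred_b, labels, reps, seed = 1) {
  obs <- abs(auc_rank(pred_a, labels) - auc_rank(pred_b, labels))
  set.seed(seed)
  n <- length(labels)
  hits <- 0
  for (i in seq_len(reps)) {
    sw <- runif(n) < 0.5
    pa <- ifelse(sw, pred_b, pred_a)
    pb <- ifelse(sw, pred_a, pred_b)
    if (abs(auc_rank(pa, labels) - auc_rank(pb, labels)) >= obs - 1e-12)
      hits <- hits + 1
  }
  (hits + 1) / (reps + 1)
}

# Midrank AUC used inside the permutation oracle (vectorized for speed but
# independent of the package's pROC-based implementation).
auc_rank <- function(pred, labels) {
  r <- rank(pred)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A random quantized "region" with holes, for texture oracle checks.
random_region <- function(nr, nc, G, p_hole = 0.2) {
  lv <- matrix(sample.int(G, nr * nc, replace = TRUE), nr, nc)
  lv[matrix(runif(nr * nc) < p_hole, nr, nc)] <- 0L
  if (all(lv == 0)) lv[1] <- 1L
  storage.mode(lv) <- "integer"
  lv
}
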