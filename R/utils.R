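# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive `n` child seeds (< 2^31) reproducibly from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mammotex <- function(msg, class) {
  stop(structure(class = c(class, "mammotex_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Dice overlap between two binary masks.
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Row/column coordinate matrices for an nr x nc grid (1-based).
row_grid <- function(nr, nc) matrix(seq_len(nr), nr, nc)
col_grid <- function(nr, nc) matrix(rep(seq_len(nc), each = nr), nr, nc)

# Mirror a matrix left<->right (reverse columns).
flop <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

# Nearest-neighbour rotation of a matrix by `angle_deg` counterclockwise
# (in the y-up sense) about the image center; out-of-frame pixels get `fill`.
rotate_nn <- function(m, angle_deg, fill = 0) {
  if (abs(angle_deg) < 1e-12) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  r <- row_grid(nr, nc) - cr
  c <- col_grid(nr, nc) - cc
  # inverse map: rotate output coords by -angle to find source pixel.
  # Image rows grow downward, so a CCW (y-up) rotation by `th` maps
  # (x, y) = (c, -r); inverse rotation of the output grid:
  x <- c; y <- -r
  xs <- cos(-th) * x - sin(-th) * y
  ys <- sin(-th) * x + cos(-th) * y
  sr <- round(cr - ys)
  sc <- round(cc + xs)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- matrix(fill, nr, nc)
  out[ok] <- m[cbind(sr[ok], sc[ok])]
  out
}
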