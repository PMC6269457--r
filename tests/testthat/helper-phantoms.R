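# Shared fixtures: all phantoms are generated in code at test time.

test_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

# A varied, realistic phantom for recovery tests (mixed laterality, pectoral
# angles across the MLO range).
varied_phantom <- function(i) {
  set.seed(5000 + i)
  phantom_spec(seed = 5000 + i,
               laterality = if (i %% 2 == 0) "right" else "left",
               breast_radius_mm = runif(1, 50, 68),
               breast_semiheight_mm = runif(1, 34, 44),
               pectoral_angle_deg = runif(1, 22, 45),
               pectoral_top_mm = runif(1, 30, 48))
}

# Half-disk breast mask of radius R px centered on the left edge midpoint.
half_disk_mask <- function(nr, nc, R) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  cy <- (nr + 1) / 2
  (cc^2 + (rr - cy)^2) <= R^2
}
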