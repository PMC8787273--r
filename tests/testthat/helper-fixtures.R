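# Geometric fixtures and independent oracles used across the suite.

# axis-aligned rectangle mask
rect_mask <- function(nr, nc, rows, cols) {
  m <- matrix(0L, nr, nc)
  m[rows, cols] <- 1L
  m
}

# filled ellipse with semi-axes a (cols) and b (rows)
ellipse_mask <- function(a, b, pad = 3) {
  nr <- 2 * (b + pad) + 1; nc <- 2 * (a + pad) + 1
  cr <- b + pad + 1; cc <- a + pad + 1
  ix <- outer(((seq_len(nr) - cr) / b)^2, ((seq_len(nc) - cc) / a)^2, "+")
  matrix(as.integer(ix <= 1), nr, nc)
}

disc_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1; ctr <- r + pad + 1
  ix <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  matrix(as.integer(ix <= r^2), n, n)
}

# fusiform tube rendered from the analytic width profile
fusiform_mask <- function(w_min, w_max, length_um, ps = 0.5) {
  npx <- as.integer(length_um / ps)
  nr <- as.integer(w_max / ps) + 10L; nc <- npx + 8L
  m <- matrix(0L, nr, nc); yc <- nr / 2; x0 <- 5L
  t_um <- (seq_len(npx) - (npx + 1) / 2) * ps
  w <- fibre_width_um(t_um, length_um, w_min, w_max)
  k <- pmax(2L, 2L * as.integer(round(w / (2 * ps))))
  for (u in seq_along(k)) {
    top <- as.integer(floor(yc - k[u] / 2)) + 1L
    m[top:(top + k[u] - 1L), x0 + u - 1L] <- 1L
  }
  m
}

# brute-force perpendicular-scan width oracle for horizontal shapes:
# the width at a medial-axis point is the column's foreground extent
colscan_width <- function(mask, cols) colSums(mask > 0)[cols]

# brute-force background threshold oracle: smallest integer T such that
# at most 1% of positive pixels remain above T
brute_threshold <- function(v) {
  pos <- v[v > 0]
  if (!length(pos)) return(0L)
  allowed <- floor(0.01 * length(pos))
  for (t in 0:max(pos)) {
    if (sum(pos > t) <= allowed) return(t)
  }
  max(pos)
}

# compact condition parameters for fast pipeline-level tests
small_conditions <- function() {
  list(
    control = condition_params("control", myotubes_per_fov = 4,
                               nuclei_per_fov_mean = 45,
                               area_per_nucleus_mean = 400),
    nrg1 = condition_params("nrg1", myotubes_per_fov = 4.5,
                            nuclei_per_fov_mean = 58,
                            area_per_nucleus_mean = 350))
}

paper_thresholds <- function() ddr_thresholds(1.81, 0.37, 4.03, 1.32)
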