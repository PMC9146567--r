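# Independent oracles and small fixture builders used across the suite.

# Brute-force rotation-search RMSD oracle: coarse-to-fine grid over Euler
# angles (z-y-z), translation removed by centering. Independent of the
# SVD-based Kabsch implementation.
rmsd_rotation_oracle <- function(X, Y, levels = 6L) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot_zyz <- function(a, b, g) {
    rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    rz(a) %*% ry(b) %*% rz(g)
  }
  score <- function(a, b, g) {
    R <- rot_zyz(a, b, g)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  # coarse scan, keep a few candidate basins
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      g = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- mapply(score, grid$a, grid$b, grid$g)
  cands <- grid[order(vals)[1:3], ]
  best <- Inf
  for (ci in seq_len(nrow(cands))) {
    centre <- as.numeric(cands[ci, ])
    span <- c(2 * pi / 12, pi / 6, 2 * pi / 12)
    for (lv in seq_len(levels)) {
      g2 <- expand.grid(a = centre[1] + seq(-span[1], span[1], length.out = 7),
                        b = centre[2] + seq(-span[2], span[2], length.out = 7),
                        g = centre[3] + seq(-span[3], span[3], length.out = 7))
      v2 <- mapply(score, g2$a, g2$b, g2$g)
      k <- which.min(v2)
      centre <- as.numeric(g2[k, ])
      span <- span / 3
      best <- min(best, v2[k])
    }
  }
  best
}

# random proper rotation + translation
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rt) {
  xyz %*% t(rt$R) + matrix(rt$t, nrow(xyz), 3, byrow = TRUE)
}

# hand-built Hoogsteen pair table (for graph-level tests)
pairs_df <- function(donor, acceptor, d = 2.9) {
  data.frame(donor = donor, acceptor = acceptor,
             d_N1_O6 = rep(d, length.out = length(donor)),
             d_N2_N7 = rep(d, length.out = length(donor)))
}

# the thirteen damage rows of the reference single/double break scheme,
# ASCII-star notation
scheme_rows <- function() {
  c(Native      = "A GGG TTA GGG TTA GGG TTA GGG",
    "2-3"       = "A G*GG TTA GGG TTA GGG TTA GGG",
    "3-4"       = "A GG*G TTA GGG TTA GGG TTA GGG",
    "9-10"      = "A GGG TTA GG*G TTA GGG TTA GGG",
    "14-15"     = "A GGG TTA GGG TTA G*GG TTA GGG",
    "15-16"     = "A GGG TTA GGG TTA GG*G TTA GGG",
    "21-22"     = "A GGG TTA GGG TTA GGG TTA GG*G",
    "2-3-4"     = "A G*G*G TTA GGG TTA GGG TTA GGG",
    "2-3/14-15" = "A G*GG TTA GGG TTA G*GG TTA GGG",
    "3-4/9-10"  = "A GG*G TTA GG*G TTA GGG TTA GGG",
    "3-4/14-15" = "A GG*G TTA GGG TTA G*GG TTA GGG",
    "3-4/15-16" = "A GG*G TTA GGG TTA GG*G TTA GGG",
    "14-15-16"  = "A GGG TTA GGG TTA G*G*G TTA GGG")
}
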