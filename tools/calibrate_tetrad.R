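# One-off calibration of the ideal-tetrad placement frozen in R/templates.R.
#
# A planar guanine template (standard base reference frame, xy-plane) is
# translated in-plane by t = (tx, ty); guanine s of the tetrad is the placed
# template rotated by s*90 deg about the z axis (donor -> acceptor direction
# follows the +90 deg rotation).  Requiring both Hoogsteen heavy-atom
# distances to be exactly d = 2.9 A,
#   |N1_0 - O6_1| = d   and   |N2_0 - N7_1| = d   with  g1 = Rz(90) g0,
# reduces to intersecting two circles in u = (I - Rz(90)) t, which has two
# solutions; rotating the template first only rotates the whole tetrad, so
# the geometry is unique up to global rotation and the branch choice.  The
# physical branch places the O6 carbonyls nearest the channel axis (K+-O6
# coordination ~2.8 A for a cation midway between planes at rise 3.3 A) and
# fixes the C1' radius at ~8.21 A, which is therefore the builder default.
#
# Run from the repository root:  Rscript tools/calibrate_tetrad.R

G <- rbind(
  N9 = c(-1.289, 4.551), C8 = c( 0.023, 4.962), N7 = c( 0.870, 3.969),
  C5 = c( 0.071, 2.833), C6 = c( 0.424, 1.460), O6 = c( 1.554, 0.955),
  N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
  N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177), `C1'` = c(-2.477, 5.399))
R90 <- matrix(c(0, 1, -1, 0), 2, 2)
d <- 2.9

v1 <- G["N1", ] - R90 %*% G["O6", ]
v2 <- G["N2", ] - R90 %*% G["N7", ]
c1 <- -as.numeric(v1); c2 <- -as.numeric(v2)
dd <- sqrt(sum((c2 - c1)^2))
stopifnot(dd <= 2 * d)                       # circles intersect
mid <- (c1 + c2) / 2
h <- sqrt(d^2 - (dd / 2)^2)
perp <- c(-(c2 - c1)[2], (c2 - c1)[1]) / dd

for (s in c(1, -1)) {
  u <- mid + s * h * perp
  t <- solve(diag(2) - R90, u)               # u = (I - R90) t
  g0 <- sweep(G, 2, t, `+`)
  g1 <- g0 %*% t(R90)
  cat(sprintf(
    "branch %+d: tx = %.12f  ty = %.12f\n  d(N1,O6) = %.10f  d(N2,N7) = %.10f\n  r(C1') = %.10f  r(O6) = %.6f  r(N9) = %.6f\n",
    s, t[1], t[2],
    sqrt(sum((g0["N1", ] - g1["O6", ])^2)),
    sqrt(sum((g0["N2", ] - g1["N7", ])^2)),
    sqrt(sum(g0["C1'", ]^2)), sqrt(sum(g0["O6", ]^2)), sqrt(sum(g0["N9", ]^2))))
}
cat("frozen: branch -1 (O6 lines the channel)\n")
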