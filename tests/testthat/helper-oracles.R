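# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Closed-form 1:1 Langmuir sensorgram: association towards
# Req = rmax*C/(C + kd1/ka1) with observed rate (ka1*C + kd1), then simple
# exponential dissociation.
langmuir_closed_form <- function(ka1, kd1, rmax, conc, times, t_assoc) {
  req <- rmax * conc / (conc + kd1 / ka1)
  kobs <- ka1 * conc + kd1
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(times <= t_assoc,
         req * (1 - exp(-kobs * times)),
         r_end * exp(-kd1 * (times - t_assoc)))
}

# Horn's closed-form quaternion solution of the optimal rigid superposition:
# the best rotation is the eigenvector of the 4x4 key matrix with the
# largest eigenvalue. Independent of the SVD-based Kabsch path.
horn_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)   # sum_i a_i b_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Monte-Carlo rejection-sampling oracle for the solvent-accessible area of a
# small set of spheres: sample points uniformly on each expanded sphere and
# count those outside all other expanded spheres.
mc_sasa <- function(centers, radii, probe = 1.4, n = 40000, seed = 1) {
  set.seed(seed)
  rext <- radii + probe
  total <- 0
  for (i in seq_len(nrow(centers))) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rext[i], 2, centers[i, ], "+")
    acc <- rep(TRUE, n)
    for (j in seq_len(nrow(centers))[-i]) {
      d2 <- (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2 +
            (pts[, 3] - centers[j, 3])^2
      acc <- acc & d2 >= rext[j]^2
    }
    total <- total + 4 * pi * rext[i]^2 * mean(acc)
  }
  total
}

# A uniformly random proper rotation matrix.
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

table2_mg <- rate_constants(ka1 = 3.1e4, ka2 = 1.9e-3, kd1 = 3.6e-1, kd2 = 2.0e-2)
table2_camg <- rate_constants(ka1 = 1.6e4, ka2 = 4.2e-4, kd1 = 4.0e-1, kd2 = 5.3e-2)
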