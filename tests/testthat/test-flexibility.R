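test_that("Kabsch superposition: identity, known transform, Horn oracle", {
  set.seed(21)
  X <- matrix(rnorm(36, sd = 4), ncol = 3)

  # identical sets: zero rmsd, identity rotation
  s <- kabsch_superpose(X, X)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)

  # rotated + translated copy superposes exactly
  R <- rand_rotation()
  Y <- X %*% t(R) + matrix(c(4, -2, 9), nrow(X), 3, byrow = TRUE)
  expect_lt(kabsch_superpose(Y, X)$rmsd, 1e-9)

  # fixed 4-point toy sets against the closed-form quaternion oracle
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, 0), c(0.3, 0.2, 2))
  B <- rbind(c(0.1, 0, 0.2), c(1.2, 0.1, 0), c(-0.2, 1.4, 0.3), c(0.5, 0, 1.8))
  expect_equal(kabsch_superpose(A, B)$rmsd, horn_rmsd(A, B), tolerance = 1e-6)
  # and on random sets
  for (i in 1:5) {
    M <- matrix(rnorm(30), ncol = 3)
    N <- matrix(rnorm(30), ncol = 3)
    expect_equal(kabsch_superpose(M, N)$rmsd, horn_rmsd(M, N), tolerance = 1e-8)
  }

  # collinear geometry is degenerate
  L <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(L, L + 1), class = "protomer_domain_error")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]),
               class = "protomer_domain_error")
})

test_that("RMSF: static and rigidly moved trajectories fluctuate zero", {
  tr <- fluctuation_trajectory(n_residues = 12, n_frames = 20, sigma_nm = 0,
                               seed = 4)
  expect_equal(max(rmsf_per_residue(tr, fit = FALSE)$rmsf), 0)

  # per-frame rigid translation is removed by the fitting step
  ref <- attr(tr, "truth")$reference
  frames <- tr$frames
  for (f in seq_len(dim(frames)[3]))
    frames[, , f] <- frames[, , f] + matrix(rnorm(3, 0, 10), 12, 3, byrow = TRUE)
  tr2 <- trajectory(frames, tr$atoms, reference = ref)
  expect_lt(max(rmsf_per_residue(tr2, fit = TRUE)$rmsf), 1e-9)
})

test_that("RMSF follows the sigma*sqrt(3) law and is rigid-motion invariant", {
  # isotropic Gaussian displacement, sigma = 0.1 nm per coordinate
  tr <- fluctuation_trajectory(n_residues = 20, n_frames = 10000,
                               sigma_nm = 0.1, seed = 6)
  prof <- rmsf_per_residue(tr, reference = attr(tr, "truth")$reference,
                           fit = FALSE)
  expect_equal(mean(prof$rmsf), 0.1 * sqrt(3), tolerance = 0.02)
  expect_true(all(abs(prof$rmsf - 0.1 * sqrt(3)) / (0.1 * sqrt(3)) < 0.02))

  # a non-flat profile is reproduced per residue
  sig <- seq(0.05, 0.25, length.out = 15)
  trp <- fluctuation_trajectory(n_residues = 15, n_frames = 4000,
                                sigma_nm = sig, seed = 7)
  pp <- rmsf_per_residue(trp, reference = attr(trp, "truth")$reference,
                         fit = FALSE)
  expect_equal(pp$rmsf, sig * sqrt(3), tolerance = 0.05)

  # random per-frame rigid transforms + fitting: same profile within 1%
  tr_c <- fluctuation_trajectory(n_residues = 20, n_frames = 2000,
                                 sigma_nm = 0.1, rigid_contamination = TRUE,
                                 seed = 9)
  tr_u <- fluctuation_trajectory(n_residues = 20, n_frames = 2000,
                                 sigma_nm = 0.1, rigid_contamination = FALSE,
                                 seed = 9)
  p_c <- rmsf_per_residue(tr_c, reference = attr(tr_c, "truth")$reference)
  p_u <- rmsf_per_residue(tr_u, reference = attr(tr_u, "truth")$reference)
  expect_equal(p_c$rmsf, p_u$rmsf, tolerance = 0.01)

  # a global rigid transform of every frame changes nothing when fitting
  R <- rand_rotation()
  frames <- tr_u$frames
  for (f in seq_len(dim(frames)[3]))
    frames[, , f] <- frames[, , f] %*% t(R) + 25
  p_g <- rmsf_per_residue(trajectory(frames, tr_u$atoms),
                          reference = attr(tr_u, "truth")$reference)
  expect_equal(p_g$rmsf, p_u$rmsf, tolerance = 1e-9)
})

test_that("RMSF about the time-average is a lower bound", {
  tr <- fluctuation_trajectory(n_residues = 10, n_frames = 300, sigma_nm = 0.15,
                               seed = 12)
  fixed <- rmsf_per_residue(tr, reference = "first", fit = TRUE)
  about_mean <- rmsf_per_residue(tr, reference = "mean", fit = TRUE)
  expect_true(all(about_mean$rmsf <= fixed$rmsf + 1e-12))
})

test_that("trajectories roundtrip through multi-model PDB", {
  tr <- fluctuation_trajectory(n_residues = 8, n_frames = 5, sigma_nm = 0.05,
                               seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(tr, f)
  tr2 <- read_pdb_trajectory(f)
  expect_equal(dim(tr2$frames), dim(tr$frames))
  expect_lt(max(abs(tr2$frames - tr$frames)), 1e-3)  # %8.3f precision
  p1 <- rmsf_per_residue(tr, reference = tr$frames[, , 1])
  p2 <- rmsf_per_residue(tr2, reference = tr2$frames[, , 1])
  expect_equal(p2$rmsf, p1$rmsf, tolerance = 1e-2)

  expect_error(rmsf_per_residue(tr, reference = matrix(0, 3, 3)),
               class = "protomer_domain_error")
})
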