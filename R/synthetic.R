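#' Noise specification for synthetic data generators
#'
#' Additive homoscedastic Gaussian noise, optionally with a linear baseline
#' drift, under a single seeded pseudo-random stream. The same seed always
#' reproduces the same dataset bit for bit.
#'
#' @param sigma Gaussian standard deviation (RU, or intensity units).
#' @param drift Linear baseline drift (RU/s), default 0.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, drift = 0, seed = 1) {
  if (sigma < 0) abort("sigma must be >= 0", "protomer_domain_error")
  structure(list(sigma = sigma, drift = drift, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Geometric concentration series for a kinetic titration
#'
#' Descending geometric dilution series, the standard layout of an SPR
#' titration. The default emulates two-fold dilutions from 30 uM over
#' 8 steps, spanning roughly 230 nM - 30 uM.
#'
#' @param c_max Top concentration (molar).
#' @param dilution_factor Dilution factor between steps (> 1).
#' @param n_steps Number of concentrations (>= 2).
#' @return Numeric vector of concentrations, descending from `c_max`.
#' @examples
#' make_series(30e-6, 2, 8) * 1e6  # micromolar
#' @export
make_series <- function(c_max = 30e-6, dilution_factor = 2, n_steps = 8) {
  if (c_max <= 0) abort("c_max must be > 0", "protomer_domain_error")
  if (dilution_factor <= 1) abort("dilution factor must be > 1", "protomer_domain_error")
  if (n_steps < 2) abort("need at least 2 steps", "protomer_domain_error")
  c_max / dilution_factor^(seq_len(n_steps) - 1)
}

#' Generate noisy sensorgrams with known ground truth
#'
#' Simulates one sensorgram per concentration under the bivalent-analyte
#' model and adds seeded Gaussian noise (and optional drift). The generating
#' parameters are attached as a `truth` attribute so downstream recovery can
#' be scored without re-reading generator internals.
#'
#' @param k A [rate_constants()] object (the ground truth).
#' @param rmax Surface capacity (RU). 500 RU by default: a realistic mid
#'   immobilization level for a small-protein surface.
#' @param series Concentrations (molar), e.g. from [make_series()].
#' @param protocol An [injection_protocol()] template (its concentration is
#'   replaced per curve).
#' @param noise A [noise_spec()].
#' @return A list of [sensorgram()]s with attribute
#'   `truth = list(constants, rmax, noise)`.
#' @examples
#' k <- rate_constants(3.1e4, 1.9e-3, 0.36, 0.02)
#' sgs <- noisy_sensorgrams(k, 500, make_series(30e-6, 2, 4),
#'                          noise = noise_spec(sigma = 1, seed = 7))
#' attr(sgs, "truth")$rmax
#' @export
noisy_sensorgrams <- function(k, rmax = 500, series = make_series(),
                              protocol = injection_protocol(0),
                              noise = noise_spec()) {
  k <- as_rate_constants(k)
  restore <- local_rng(noise$seed)
  on.exit(restore())
  out <- lapply(series, function(cc) {
    p <- injection_protocol(cc, protocol$t_association, protocol$t_dissociation,
                            protocol$sampling_interval, protocol$flow_rate_ul_min)
    sg <- simulate_sensorgram(k, rmax, p)
    if (noise$sigma > 0)
      sg$response <- sg$response + rnorm(nrow(sg), 0, noise$sigma)
    if (noise$drift != 0)
      sg$response <- sg$response + noise$drift * sg$time
    sg
  })
  attr(out, "truth") <- list(constants = k, rmax = rmax, noise = noise)
  out
}

#' Synthetic electrospray charge-state peak series
#'
#' Generates the peak list of a single neutral species observed at the given
#' charges in positive-mode ESI: `m/z_i = (M + z_i * m_proton) / z_i`.
#' [deconvolute_charge_series()] is its exact inverse when no rounding is
#' applied.
#'
#' @param neutral_mass Neutral average mass (Da), > 0.
#' @param charges Integer charge states (e.g. `8:10`).
#' @param intensities Peak intensities (same length as `charges`); equal by
#'   default.
#' @param mz_digits If non-`NULL`, round m/z to this many decimal places
#'   (0 emulates values printed as integers).
#' @return A [peak_list()], sorted by ascending m/z.
#' @examples
#' synthetic_peaks(21767, 8:10, mz_digits = 0)
#' @export
synthetic_peaks <- function(neutral_mass, charges, intensities = NULL,
                            mz_digits = NULL) {
  if (neutral_mass <= 0) abort("mass must be > 0", "protomer_domain_error")
  charges <- as.integer(charges)
  if (any(charges < 1)) abort("charges must be >= 1", "protomer_domain_error")
  if (is.null(intensities)) intensities <- rep(1, length(charges))
  mz <- (neutral_mass + charges * PROTON_MASS) / charges
  if (!is.null(mz_digits)) mz <- round(mz, mz_digits)
  o <- order(mz)
  peak_list(mz[o], intensities[o])
}

#' Toy structures with analytically known shape metrics
#'
#' Fixture generator for the structure-based metrics:
#' * `"two_point"`: two equal-mass atoms separated by `d` Angstrom
#'   (Rg = d/2 exactly);
#' * `"bead_sphere"`: `n_beads` equal beads drawn uniformly from a solid
#'   sphere of radius `radius` Angstrom (Rg -> sqrt(3/5) * radius);
#' * `"dumbbell"`: two spherical atoms of radius `atom_radius` at separation
#'   `d` (solvent-accessible area additive once `d` exceeds the contact
#'   distance).
#'
#' @param kind One of `"two_point"`, `"bead_sphere"`, `"dumbbell"`.
#' @param d Separation (Angstrom) for `two_point` / `dumbbell`.
#' @param radius Sphere radius (Angstrom) for `bead_sphere`.
#' @param n_beads Number of beads for `bead_sphere`.
#' @param atom_radius Van der Waals radius (Angstrom) assigned to the atoms.
#' @param seed RNG seed for `bead_sphere`.
#' @return A [structure_model()] with a `truth` attribute holding the
#'   analytic radius of gyration (`rg_nm`) and, where defined, the isolated
#'   solvent-accessible area.
#' @export
toy_structures <- function(kind = c("two_point", "bead_sphere", "dumbbell"),
                           d = 20, radius = 20, n_beads = 1000,
                           atom_radius = 1.9, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "two_point" || kind == "dumbbell") {
    if (d < 0) abort("separation must be >= 0", "protomer_domain_error")
    xyz <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
    s <- structure_model(
      data.frame(element = c("C", "C"), name = c("C1", "C2"),
                 resid = 1:2, resname = "TOY",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      radius = atom_radius, mass = 12.011)
    attr(s, "truth") <- list(
      rg_nm = d / 2 / 10,
      sasa_isolated_A2 = 4 * pi * (atom_radius + 1.4)^2)
    return(s)
  }
  # bead_sphere: uniform rejection-free radial sampling
  restore <- local_rng(seed)
  on.exit(restore())
  r <- radius * runif(n_beads)^(1 / 3)
  u <- runif(n_beads, -1, 1)
  phi <- runif(n_beads, 0, 2 * pi)
  st <- sqrt(1 - u^2)
  xyz <- cbind(r * st * cos(phi), r * st * sin(phi), r * u)
  s <- structure_model(
    data.frame(element = "C", name = "C", resid = seq_len(n_beads),
               resname = "TOY", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    radius = atom_radius, mass = 12.011)
  attr(s, "truth") <- list(rg_nm = sqrt(3 / 5) * radius / 10)
  s
}

#' Synthetic trajectory with prescribed per-residue fluctuation
#'
#' Builds a C-alpha pseudo-chain (seeded self-avoiding-ish random walk with
#' 3.8 Angstrom steps) and generates frames as the reference plus isotropic
#' Gaussian displacements with per-residue standard deviation `sigma_nm`
#' per Cartesian coordinate. For large frame counts the per-residue RMSF
#' converges to `sigma_nm * sqrt(3)`. Optionally each frame is additionally
#' rotated and translated at random to exercise the superposition step.
#'
#' @param n_residues Number of residues (C-alpha atoms).
#' @param n_frames Number of frames (>= 2).
#' @param sigma_nm Per-coordinate displacement SD in nm; scalar or
#'   per-residue vector.
#' @param rigid_contamination If `TRUE`, apply a random rigid transform to
#'   every frame.
#' @param seed RNG seed.
#' @return A [trajectory()] with attribute `truth = list(sigma_nm,
#'   rmsf_nm = sigma_nm * sqrt(3), reference)`.
#' @export
fluctuation_trajectory <- function(n_residues = 20, n_frames = 100,
                                   sigma_nm = 0.1, rigid_contamination = FALSE,
                                   seed = 1) {
  if (n_residues < 3) abort("need >= 3 residues", "protomer_domain_error")
  if (n_frames < 2) abort("need >= 2 frames", "protomer_domain_error")
  sigma <- rep_len(sigma_nm, n_residues)
  if (any(sigma < 0)) abort("sigma must be >= 0", "protomer_domain_error")
  restore <- local_rng(seed)
  on.exit(restore())

  # reference chain: cumulated random unit steps of 3.8 A
  steps <- matrix(rnorm(3 * (n_residues - 1)), ncol = 3)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  ref <- rbind(0, apply(steps, 2, cumsum))

  # all displacement noise is drawn before any contamination transform, so a
  # given seed yields the same fluctuation field with contamination on or off
  sigmaA <- sigma * 10  # nm -> Angstrom
  disp <- array(rnorm(n_residues * 3 * n_frames), c(n_residues, 3, n_frames)) *
    array(sigmaA, c(n_residues, 3, n_frames))
  frames <- array(0, dim = c(n_residues, 3, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- ref + disp[, , f]
    if (rigid_contamination) {
      R <- random_rotation()
      fr <- fr %*% t(R) + matrix(rnorm(3, 0, 5), n_residues, 3, byrow = TRUE)
    }
    frames[, , f] <- fr
  }
  atoms <- data.frame(element = "C", name = "CA", resid = seq_len(n_residues),
                      resname = "ALA", calpha = TRUE)
  tr <- trajectory(frames, atoms, reference = ref)
  attr(tr, "truth") <- list(sigma_nm = sigma, rmsf_nm = sigma * sqrt(3),
                            reference = ref)
  tr
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
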