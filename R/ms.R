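PROTON_MASS <- 1.00728   # u, positive-mode ESI charge carrier
WATER_MASS <- 18.0153    # u, average
DSBU_BRIDGE_MASS <- 196.1  # u, mass added by one fully reacted DSBU bridge
HYDROLYSIS_DELTA <- 18.011 # u, extra water on a one-side-reacted linker

# Average residue masses (u) of the 20 standard amino acids.
RESIDUE_MASSES <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Peak list from a mass spectrum
#'
#' @param mz m/z values (Th), > 0.
#' @param intensity Intensities (arbitrary units, >= 0); equal by default.
#' @return An object of class `peak_list` (a data frame sorted by
#'   ascending m/z).
#' @export
peak_list <- function(mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  if (length(mz) != length(intensity))
    abort("mz and intensity must have the same length", "protomer_domain_error")
  if (any(mz <= 0) || any(intensity < 0))
    abort("m/z must be > 0 and intensities >= 0", "protomer_domain_error")
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            class = c("peak_list", "data.frame"))
}

#' Deconvolute an ESI charge-state series to a neutral mass
#'
#' In positive-mode electrospray a single species of neutral mass M appears
#' at `m/z = (M + z m_p) / z` for a run of consecutive charges z. This
#' routine searches every consecutive charge assignment inside
#' `[z_min, z_max]` (charges descend as m/z ascends), computes the implied
#' neutral masses `M_i = z_i (m/z_i - m_p)`, and keeps the assignment whose
#' masses agree best (smallest standard deviation; ties broken by higher
#' total intensity). The reported mass is the intensity-weighted mean.
#'
#' If no assignment brings the dispersion below `threshold` (a fraction of
#' the mass), the peaks are not a consistent series and a
#' `protomer_no_consistent_series` error is signalled.
#'
#' A single peak is only accepted with a stated charge (`z_min == z_max`).
#'
#' @param peaks A [peak_list()] (or two-column data frame).
#' @param z_min,z_max Charge search window, `1 <= z_min <= z_max <= 50`.
#' @param proton_mass Charge-carrier mass (u).
#' @param threshold Maximum acceptable relative dispersion (default 0.002,
#'   i.e. 0.2% of the mass).
#' @return List with `neutral_mass` (Da, intensity-weighted), `charges`
#'   (per peak), `masses` (per peak), `dispersion` (Da, sd of the per-peak
#'   masses).
#' @examples
#' deconvolute_charge_series(peak_list(c(2178, 2420, 2722)), 5, 15)
#' @export
deconvolute_charge_series <- function(peaks, z_min = 1, z_max = 50,
                                      proton_mass = PROTON_MASS,
                                      threshold = 0.002) {
  if (!inherits(peaks, "peak_list")) peaks <- peak_list(peaks[[1]], peaks[[2]])
  if (z_min < 1 || z_max > 50 || z_min > z_max)
    abort("charge window must satisfy 1 <= z_min <= z_max <= 50",
          "protomer_domain_error")
  n <- nrow(peaks)
  if (n == 1) {
    if (z_min != z_max)
      abort("a single peak needs a stated charge (z_min == z_max)",
            "protomer_domain_error")
    m <- z_min * (peaks$mz - proton_mass)
    return(list(neutral_mass = m, charges = z_min, masses = m, dispersion = 0))
  }
  if (z_max - z_min + 1 < n)
    abort("charge window narrower than the number of peaks",
          "protomer_domain_error")

  best <- NULL
  for (z_top in seq(z_min + n - 1, z_max)) {
    z <- seq(z_top, by = -1, length.out = n)    # descending with ascending m/z
    m <- z * (peaks$mz - proton_mass)
    disp <- sd(m)
    if (is.null(best) || disp < best$dispersion)  # ties keep the lower window
      best <- list(charges = z, masses = m, dispersion = disp)
  }
  mass <- sum(best$masses * peaks$intensity) / sum(peaks$intensity)
  if (best$dispersion > threshold * mass)
    abort(sprintf(
      "no consistent charge series in [%d, %d] (best dispersion %.1f Da on %.0f Da)",
      z_min, z_max, best$dispersion, mass), "protomer_no_consistent_series")
  list(neutral_mass = mass, charges = best$charges, masses = best$masses,
       dispersion = best$dispersion)
}

#' Average mass of a peptide from its sequence
#'
#' Sum of standard average residue masses plus one water, with optional
#' terminal modifications: N-terminal acetylation adds 42.037 u, C-terminal
#' amidation subtracts 0.985 u (OH -> NH2). Average (not monoisotopic)
#' masses are used throughout, matching intact-protein measurements at the
#' tens-of-kDa scale.
#'
#' @param sequence One-letter amino-acid string (standard 20 letters).
#' @param n_term `"free"` or `"acetyl"`.
#' @param c_term `"free"` or `"amide"`.
#' @return Average mass in Da.
#' @examples
#' peptide_average_mass("LLLWKMGFFKRAKHPE")            # ~2001.5
#' peptide_average_mass("LLLWKMGFFKRAKHPE", c_term = "amide")
#' @export
peptide_average_mass <- function(sequence, n_term = c("free", "acetyl"),
                                 c_term = c("free", "amide")) {
  n_term <- match.arg(n_term); c_term <- match.arg(c_term)
  if (!nzchar(sequence)) abort("empty sequence", "protomer_invalid_sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASSES))
  if (length(bad))
    abort(paste0("unknown residue letter(s): ", paste(unique(bad), collapse = ", ")),
          "protomer_invalid_sequence")
  m <- sum(RESIDUE_MASSES[aa]) + WATER_MASS
  if (n_term == "acetyl") m <- m + 42.0367
  if (c_term == "amide") m <- m - 0.9847
  unname(m)
}

#' Cross-linker adduct mass ladder
#'
#' Expected masses of a species decorated with 0..`n_max` cross-linker
#' molecules: `mass(n) = base_mass + n * bridge_mass` for fully bridged
#' linkers; a partially hydrolyzed (one-side-reacted) linker carries an
#' extra water (+18.011 u each).
#'
#' @param base_mass Unmodified species mass (Da), > 0.
#' @param n_max Largest adduct count (>= 0).
#' @param bridge_mass Mass added per bridged linker (u); default the DSBU
#'   bridge, 196.1 u.
#' @param hydrolyzed If `TRUE`, report the hydrolyzed-linker ladder
#'   (each linker one-side-reacted, + water).
#' @return An object of class `mass_ladder`: data frame with `n_adducts`,
#'   `species`, `mass` (strictly increasing).
#' @examples
#' adduct_masses(21770, 5)  # MALDI ladder of a cross-linked protein
#' @export
adduct_masses <- function(base_mass, n_max, bridge_mass = DSBU_BRIDGE_MASS,
                          hydrolyzed = FALSE) {
  if (base_mass <= 0) abort("base mass must be > 0", "protomer_domain_error")
  if (n_max < 0) abort("n_max must be >= 0", "protomer_domain_error")
  n <- 0:n_max
  per <- bridge_mass + if (hydrolyzed) HYDROLYSIS_DELTA else 0
  structure(data.frame(
    n_adducts = n,
    species = ifelse(n == 0, "base",
                     if (hydrolyzed) "hydrolyzed" else "bridged"),
    mass = base_mass + n * per),
    class = c("mass_ladder", "data.frame"))
}

#' Mass of a cross-linked protein-peptide complex
#'
#' `protein_mass + peptide_mass + n * bridge_mass`: the expected intact mass
#' of a 1:1 (or higher) complex held together by `n` cross-linker bridges.
#'
#' @param protein_mass,peptide_mass Component masses (Da), > 0.
#' @param n_crosslinkers Number of bridges (>= 0).
#' @param bridge_mass Mass per bridge (u); default DSBU, 196.1.
#' @return Complex mass in Da.
#' @examples
#' pep <- peptide_average_mass("LLLWKMGFFKRAKHPE", c_term = "amide")
#' complex_mass(21767, pep, 1)   # ~23964
#' @export
complex_mass <- function(protein_mass, peptide_mass, n_crosslinkers = 1,
                         bridge_mass = DSBU_BRIDGE_MASS) {
  if (protein_mass <= 0 || peptide_mass <= 0)
    abort("masses must be > 0", "protomer_domain_error")
  if (n_crosslinkers < 0) abort("n_crosslinkers must be >= 0", "protomer_domain_error")
  protein_mass + peptide_mass + n_crosslinkers * bridge_mass
}
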