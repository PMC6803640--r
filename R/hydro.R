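#' Radius of gyration
#'
#' Root-mean-square distance of the atoms from their (weighted) centroid,
#' \deqn{R_g = \sqrt{\sum_i w_i |r_i - r_{cm}|^2 / \sum_i w_i},}
#' a measure of molecular compaction. Mass weighting is the default, as in
#' common structure-analysis tools; uniform weighting is available for
#' comparison. Coordinates are in Angstrom internally; the result is
#' reported in nm.
#'
#' @param structure A [structure_model()].
#' @param weighting `"mass"` (default) or `"uniform"`.
#' @return Radius of gyration in nm. A single-atom structure returns 0 with
#'   a warning.
#' @examples
#' radius_of_gyration(toy_structures("two_point", d = 20))  # 1 nm
#' @export
radius_of_gyration <- function(structure, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (!inherits(structure, "structure_model"))
    abort("need a structure_model", "protomer_domain_error")
  xyz <- coords(structure)
  if (nrow(xyz) < 2) {
    warning("radius of gyration of a single atom is 0")
    return(0)
  }
  w <- if (weighting == "mass") structure$mass else rep(1, nrow(xyz))
  cm <- colSums(xyz * w) / sum(w)
  d2 <- (xyz[, 1] - cm[1])^2 + (xyz[, 2] - cm[2])^2 + (xyz[, 3] - cm[3])^2
  sqrt(sum(w * d2) / sum(w)) / 10
}

BOLTZMANN <- 1.380649e-23  # J/K

#' Stokes-Einstein hydrodynamic diameter
#'
#' Converts a translational diffusion coefficient to the hydrodynamic
#' (Stokes) diameter of the equivalent sphere,
#' \deqn{d = k_B T / (3 \pi \eta D).}
#'
#' @param diffusion_coefficient Translational diffusion coefficient (m^2/s).
#' @param temperature Absolute temperature (K); default 310.15 K (37 C).
#' @param viscosity Solvent dynamic viscosity (Pa s); default water at
#'   37 C, 6.913e-4 Pa s.
#' @return Hydrodynamic diameter in nm.
#' @examples
#' stokes_einstein_diameter(1.218e-10)  # ~5.4 nm
#' @export
stokes_einstein_diameter <- function(diffusion_coefficient,
                                     temperature = 310.15,
                                     viscosity = 6.913e-4) {
  if (any(c(diffusion_coefficient, temperature, viscosity) <= 0))
    abort("diffusion coefficient, temperature and viscosity must be > 0",
          "protomer_domain_error")
  BOLTZMANN * temperature / (3 * pi * viscosity * diffusion_coefficient) * 1e9
}

#' @rdname stokes_einstein_diameter
#' @param diameter_nm Hydrodynamic diameter (nm), for the inverse
#'   conversion to a diffusion coefficient (m^2/s).
#' @export
stokes_einstein_diffusion <- function(diameter_nm, temperature = 310.15,
                                      viscosity = 6.913e-4) {
  if (any(c(diameter_nm, temperature, viscosity) <= 0))
    abort("diameter, temperature and viscosity must be > 0",
          "protomer_domain_error")
  BOLTZMANN * temperature / (3 * pi * viscosity * diameter_nm * 1e-9)
}

#' Scattering vector magnitude for a DLS geometry
#'
#' `q = 4 pi n sin(theta/2) / lambda`. Defaults are the backscatter
#' geometry of a common Zetasizer-class instrument: 173 degrees, 633 nm
#' laser, water refractive index 1.330.
#'
#' @param angle_deg Scattering angle (degrees).
#' @param wavelength_m Laser wavelength in vacuo (m).
#' @param refractive_index Solvent refractive index.
#' @return q in 1/m.
#' @export
scattering_vector <- function(angle_deg = 173, wavelength_m = 633e-9,
                              refractive_index = 1.330) {
  4 * pi * refractive_index * sin(angle_deg * pi / 360) / wavelength_m
}

#' Cumulant analysis of a DLS correlogram
#'
#' Second-order method of cumulants: fits
#' \deqn{\ln(g_2 - 1) = \ln B - 2 \Gamma \tau + \mu_2 \tau^2}
#' to the intensity autocorrelation decay, by least squares weighted with
#' `(g2-1)^2` (late, noise-dominated lags carry little weight). The mean
#' decay rate gives the z-average diffusion coefficient `D = Gamma / q^2`,
#' converted to a hydrodynamic diameter via [stokes_einstein_diameter()];
#' the polydispersity index is `PDI = mu2 / Gamma^2`.
#'
#' Lags after the signal has decayed below `cutoff` times its initial value
#' are excluded from the fit (the log transform amplifies their noise).
#'
#' @param lag_s Lag times (s), >= 10 values.
#' @param g2m1 Correlogram values `g2 - 1` at those lags.
#' @param temperature,viscosity Passed to [stokes_einstein_diameter()].
#' @param q Scattering vector (1/m); default [scattering_vector()].
#' @param cutoff Relative decay level below which lags are dropped
#'   (default `exp(-3)`).
#' @return List with `diameter_nm`, `pdi`, `gamma` (1/s), `diffusion`
#'   (m^2/s) and the fitted intercept.
#' @export
dls_cumulant_diameter <- function(lag_s, g2m1, temperature = 310.15,
                                  viscosity = 6.913e-4,
                                  q = scattering_vector(), cutoff = exp(-3)) {
  if (length(lag_s) != length(g2m1) || length(lag_s) < 10)
    abort("need >= 10 (lag, g2-1) pairs", "protomer_domain_error")
  o <- order(lag_s)
  lag_s <- lag_s[o]; g2m1 <- g2m1[o]
  top <- max(g2m1)
  keep <- g2m1 > max(top * cutoff, 0)
  if (sum(keep) < 5 || top <= 0)
    abort("correlogram does not decay from a positive amplitude",
          "protomer_fit_failure")
  tau <- lag_s[keep]; y <- log(g2m1[keep])
  fit <- lm(y ~ tau + I(tau^2), weights = g2m1[keep]^2)
  b <- coef(fit)
  gamma <- -b[[2]] / 2
  mu2 <- b[[3]]
  if (!is.finite(gamma) || gamma <= 0)
    abort("correlogram is not decaying: no diffusive signal",
          "protomer_fit_failure")
  D <- gamma / q^2
  list(diameter_nm = stokes_einstein_diameter(D, temperature, viscosity),
       pdi = max(mu2, 0) / gamma^2, gamma = gamma, diffusion = D,
       intercept = exp(b[[1]]))
}

#' Size-exclusion chromatography calibration
#'
#' Fits the standard SEC calibration line `log10(MW) = a + b * V` to a
#' table of globular standards of known molecular weight, for later
#' conversion of elution volumes to apparent molecular weights
#' ([mw_from_elution()]). A negative slope (later elution = smaller
#' protein) is the physically meaningful orientation.
#'
#' @param mw_kda Standard molecular weights (kDa), >= 3 values.
#' @param elution Elution volumes (mL) or times, distinct.
#' @return An object of class `sec_calibration`: `slope`, `intercept`,
#'   `r_squared`, `range` (calibrated elution range).
#' @examples
#' cal <- sec_calibrate(c(670, 158, 44, 17, 1.35), c(9, 11, 13, 15, 17.5))
#' mw_from_elution(cal, 12)
#' @export
sec_calibrate <- function(mw_kda, elution) {
  if (length(mw_kda) != length(elution))
    abort("mw and elution must have the same length", "protomer_domain_error")
  if (length(mw_kda) < 3)
    abort("need >= 3 calibration standards", "protomer_insufficient_data")
  if (length(unique(elution)) != length(elution))
    abort("elution volumes must be distinct", "protomer_domain_error")
  if (any(mw_kda <= 0)) abort("MW must be > 0", "protomer_domain_error")
  fit <- lm(log10(mw_kda) ~ elution)
  y <- log10(mw_kda)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 range = range(elution),
                 standards = data.frame(mw_kda = mw_kda, elution = elution)),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "SEC calibration: log10(MW/kDa) = %.4g %+.4g V;  R^2 = %.4f, V in [%g, %g]\n",
    x$intercept, x$slope, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Apparent molecular weight from an elution volume
#'
#' `MW_SEC = 10^(intercept + slope * V)`. Values outside the calibrated
#' elution range are still computed but flagged with a warning: SEC
#' calibration lines should not be extrapolated silently.
#'
#' @param cal A [sec_calibrate()] result.
#' @param elution_volume Elution volume(s), same units as the calibration.
#' @return Apparent MW in kDa.
#' @export
mw_from_elution <- function(cal, elution_volume) {
  if (!inherits(cal, "sec_calibration"))
    abort("need a sec_calibration", "protomer_domain_error")
  out <- any(elution_volume < cal$range[1] | elution_volume > cal$range[2])
  if (out) warning("elution volume outside the calibrated range: extrapolating")
  10^(cal$intercept + cal$slope * elution_volume)
}
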