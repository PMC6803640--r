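#' Kinetic rate constants of the bivalent-analyte scheme
#'
#' Bundle of the four rate constants of the two-step surface binding scheme
#' in which an analyte A first binds an immobilized ligand L (`A + L <-> AL`)
#' and the complex can then bridge a second ligand (`AL + L <-> AL2`).
#' Setting `ka2 = kd2 = 0` reduces the scheme to the 1:1 Langmuir model.
#'
#' Units follow standard SPR practice for a bivalent analyte: the first-step
#' association rate is per molar per second, while the second step couples
#' two surface species so its association rate is per response unit (RU) per
#' second.
#'
#' @param ka1 Association rate of `A + L -> AL` (M^-1 s^-1).
#' @param ka2 Association rate of `AL + L -> AL2` (RU^-1 s^-1).
#' @param kd1 Dissociation rate of `AL -> A + L` (s^-1).
#' @param kd2 Dissociation rate of `AL2 -> AL + L` (s^-1).
#' @return An object of class `rate_constants` (a named numeric vector).
#' @examples
#' k <- rate_constants(ka1 = 3.1e4, ka2 = 1.9e-3, kd1 = 0.36, kd2 = 0.02)
#' kd_app1(k)  # first-step apparent dissociation constant, molar
#' @export
rate_constants <- function(ka1, ka2 = 0, kd1 = 0, kd2 = 0) {
  k <- c(ka1 = as.numeric(ka1), ka2 = as.numeric(ka2),
         kd1 = as.numeric(kd1), kd2 = as.numeric(kd2))
  if (anyNA(k) || any(!is.finite(k)))
    abort("rate constants must be finite numbers", "protomer_domain_error")
  if (any(k < 0))
    abort("rate constants must be non-negative", "protomer_domain_error")
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Bivalent-analyte rate constants:\n")
  cat(sprintf("  ka1 = %.4g M^-1 s^-1   kd1 = %.4g s^-1\n", x[["ka1"]], x[["kd1"]]))
  cat(sprintf("  ka2 = %.4g RU^-1 s^-1  kd2 = %.4g s^-1\n", x[["ka2"]], x[["kd2"]]))
  cat(sprintf("  KD_app1 = kd1/ka1 = %.4g M\n",
              if (x[["ka1"]] > 0) x[["kd1"]] / x[["ka1"]] else NA_real_))
  invisible(x)
}

#' First-step apparent dissociation constant
#'
#' The apparent affinity of the first binding event, `KD_app1 = kd1 / ka1`,
#' in molar. This is the equilibrium constant of `A + L <-> AL` alone and
#' ignores avidity from the bridging step (compare [steady_state_fit()]).
#'
#' @param k A [rate_constants()] object (or anything coercible to one).
#' @return Dissociation constant in molar.
#' @examples
#' kd_app1(rate_constants(3.1e4, kd1 = 0.36))  # 11.6 micromolar
#' @export
kd_app1 <- function(k) {
  k <- as_rate_constants(k)
  if (k[["ka1"]] <= 0)
    abort("kd_app1 undefined for ka1 = 0", "protomer_domain_error")
  unname(k[["kd1"]] / k[["ka1"]])
}

as_rate_constants <- function(k) {
  if (inherits(k, "rate_constants")) return(k)
  if (is.numeric(k) && length(k) == 4) {
    if (is.null(names(k))) names(k) <- c("ka1", "ka2", "kd1", "kd2")
    return(rate_constants(k[["ka1"]], k[["ka2"]], k[["kd1"]], k[["kd2"]]))
  }
  abort("cannot interpret object as rate constants", "protomer_domain_error")
}
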