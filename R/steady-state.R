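#' Steady-state (avidity) affinity from equilibrium responses
#'
#' Fits the saturation hyperbola
#' \deqn{R_{eq}(C) = R_{max,eq} \, C / (C + K_D^{appTOT})}
#' to a table of equilibrium (maximum) responses versus analyte
#' concentration. The resulting `kd_app_tot` is the total apparent
#' dissociation constant including avidity from multivalent binding, as
#' opposed to the first-step `kd1/ka1` of a kinetic fit.
#'
#' @param concentration Analyte concentrations (molar), at least 3 distinct.
#' @param response Equilibrium responses (RU), non-negative, same length.
#' @param weights Optional least-squares weights. Unweighted by default;
#'   when the measurement noise is relative (constant CV), `1/response^2`
#'   weights make the fit the statistically matched estimator.
#' @return An object of class `steady_state_fit` with `kd_app_tot` (M),
#'   `rmax_eq` (RU), standard errors, `sse` and `r_squared`. Supports
#'   `print`, `coef`, `predict`, `residuals` and `plot`.
#' @examples
#' C <- c(1, 2, 5, 10, 20, 50, 100) * 1e-6
#' R <- 200 * C / (C + 100e-6)
#' fit <- steady_state_fit(C, R)
#' coef(fit)
#' @export
steady_state_fit <- function(concentration, response, weights = NULL) {
  C <- as.numeric(concentration); R <- as.numeric(response)
  if (length(C) != length(R))
    abort("concentration and response must have the same length",
          "protomer_domain_error")
  if (length(unique(C)) < 3)
    abort("need at least 3 distinct concentrations", "protomer_domain_error")
  if (any(C < 0) || any(R < 0))
    abort("concentrations and responses must be >= 0", "protomer_domain_error")
  if (max(R) <= 0 || sd(R) == 0)
    abort("responses carry no concentration dependence: KD unidentifiable",
          "protomer_unidentifiable_fit")

  # starting values from the double-reciprocal linearization on C > 0 points
  pos <- C > 0 & R > 0
  st <- tryCatch({
    lb <- lm(I(1 / R[pos]) ~ I(1 / C[pos]))
    rm0 <- 1 / coef(lb)[1]
    kd0 <- coef(lb)[2] * rm0
    if (!is.finite(rm0) || !is.finite(kd0) || rm0 <= 0 || kd0 <= 0)
      list(rmax_eq = max(R) * 2, kd = stats::median(C[pos]))
    else list(rmax_eq = unname(rm0), kd = unname(kd0))
  }, error = function(e) list(rmax_eq = max(R) * 2, kd = stats::median(C[pos])))

  d <- data.frame(C = C, R = R)
  if (is.null(weights)) weights <- rep(1, length(C))
  d$w <- weights
  fit <- tryCatch(
    nls(R ~ rmax_eq * C / (C + kd), data = d, weights = w,
        start = list(rmax_eq = st$rmax_eq, kd = st$kd),
        lower = c(rmax_eq = 1e-12, kd = 1e-15), algorithm = "port",
        control = list(maxiter = 500, warnOnly = TRUE)),
    error = function(e)
      abort(paste0("steady-state fit failed: ", conditionMessage(e)),
            "protomer_unidentifiable_fit"))

  cf <- coef(fit)
  if (cf[["kd"]] <= 0)
    abort("steady-state fit degenerate (KD <= 0)", "protomer_unidentifiable_fit")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax_eq = NA_real_, kd = NA_real_))
  res <- R - predict(fit)
  sse <- sum(res^2)
  sst <- sum((R - mean(R))^2)

  structure(list(kd_app_tot = unname(cf[["kd"]]),
                 rmax_eq = unname(cf[["rmax_eq"]]),
                 se = c(kd_app_tot = unname(se[["kd"]]),
                        rmax_eq = unname(se[["rmax_eq"]])),
                 sse = sse, r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 concentration = C, response = R, fitted = predict(fit),
                 nls = fit, call = match.call()),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat("Steady-state affinity fit (saturation hyperbola)\n")
  cat(sprintf("  KD_appTOT = %.4g M (se %.2g), Rmax_eq = %.4g RU (se %.2g)\n",
              x$kd_app_tot, x$se[["kd_app_tot"]], x$rmax_eq, x$se[["rmax_eq"]]))
  cat(sprintf("  n = %d, SSE = %.4g RU^2, R^2 = %.4f\n",
              length(x$response), x$sse, x$r_squared))
  invisible(x)
}

#' @export
coef.steady_state_fit <- function(object, ...)
  c(kd_app_tot = object$kd_app_tot, rmax_eq = object$rmax_eq)

#' @export
residuals.steady_state_fit <- function(object, ...)
  object$response - object$fitted

#' @export
predict.steady_state_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) return(object$fitted)
  object$rmax_eq * concentration / (concentration + object$kd_app_tot)
}

#' @export
plot.steady_state_fit <- function(x, ...) {
  plot(x$concentration, x$response, xlab = "Concentration (M)",
       ylab = "Equilibrium response (RU)", log = "x", ...)
  cc <- exp(seq(log(min(x$concentration[x$concentration > 0])),
                log(max(x$concentration)), length.out = 200))
  lines(cc, predict(x, cc), col = "red3")
  invisible(x)
}
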