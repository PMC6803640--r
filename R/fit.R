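#' Global kinetic fit of an SPR concentration series
#'
#' Fits all sensorgrams of a titration series simultaneously, sharing the
#' kinetic constants and the surface capacity `rmax` across curves, by
#' minimizing the summed squared residuals. Two models are available:
#'
#' * `"bivalent"`: the two-step bivalent-analyte scheme
#'   `A + L <-> AL`, `AL + L <-> AL2` (5 shared parameters
#'   `ka1, ka2, kd1, kd2, rmax`);
#' * `"langmuir"`: the 1:1 Langmuir model (`ka2 = kd2 = 0`; 3 shared
#'   parameters).
#'
#' Parameters are optimized on the log scale (they are positive and span
#' decades) by Nelder-Mead followed by a BFGS polish, from `n_starts`
#' starting points (the supplied/default guess plus seeded log-uniform
#' perturbations) to reduce the risk of local minima. Non-convergence is
#' reported through the `converged` flag, not as an error.
#'
#' @param sensorgrams List of [sensorgram()] objects at distinct analyte
#'   concentrations, on a common time grid.
#' @param model `"bivalent"` or `"langmuir"`.
#' @param start Optional named numeric vector of starting values among
#'   `ka1, ka2, kd1, kd2, rmax`; defaults are
#'   `ka1 = 1e4, ka2 = 1e-3, kd1 = 0.1, kd2 = 0.01, rmax = max(response)`.
#' @param n_starts Number of multi-start repetitions (>= 1).
#' @param baseline If `TRUE`, fit an additive per-curve baseline offset (RU).
#' @param seed Seed for the multi-start perturbations.
#' @param rtol,atol Integrator tolerances (see [simulate_sensorgram()]).
#' @return An object of class `spr_fit` with components `constants`
#'   ([rate_constants()]), `rmax`, `kd_app1` (`= kd1/ka1`), `se` (standard
#'   errors from the residual-scaled inverse Hessian), `sse`,
#'   `per_curve_sse`, `aic`, `converged`, `fitted`, and the input data.
#'   Supports `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`, `simulate`, `logLik`, `deviance` and `anova` (model
#'   discrimination).
#' @examples
#' k <- rate_constants(3.1e4, 1.9e-3, 0.36, 0.02)
#' series <- make_series(30e-6, 2, 4)
#' sgs <- noisy_sensorgrams(k, rmax = 500, series,
#'                          noise = noise_spec(sigma = 0, seed = 1))
#' \donttest{
#' fit <- spr_fit(sgs, model = "bivalent", n_starts = 1)
#' coef(fit)
#' }
#' @export
spr_fit <- function(sensorgrams, model = c("bivalent", "langmuir"),
                    start = NULL, n_starts = 5, baseline = FALSE, seed = 1,
                    rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (!is.list(sensorgrams) || !all(vapply(sensorgrams, inherits, TRUE, "sensorgram")))
    abort("sensorgrams must be a list of sensorgram objects", "protomer_domain_error")

  obs <- vapply(sensorgrams, function(s) s$response, numeric(nrow(sensorgrams[[1]])))
  obs <- as.matrix(obs)
  if (max(abs(obs)) < sqrt(.Machine$double.eps))
    abort("all responses are zero: kinetic parameters are unidentifiable",
          "protomer_degenerate_fit")
  if (length(sensorgrams) < 2)
    abort("global fitting needs at least two concentrations", "protomer_domain_error")

  times <- sensorgrams[[1]]$time
  protos <- lapply(sensorgrams, attr, "protocol")
  conc <- vapply(protos, `[[`, numeric(1), "concentration")
  t_assoc <- protos[[1]]$t_association
  same_grid <- all(vapply(sensorgrams, function(s)
    length(s$time) == length(times) && all(s$time == times), logical(1)))
  if (!same_grid || any(vapply(protos, `[[`, numeric(1), "t_association") != t_assoc))
    abort("all sensorgrams must share one time grid and association time",
          "protomer_domain_error")
  if (length(unique(conc)) < 2)
    abort("concentrations must be distinct", "protomer_domain_error")

  n_obs <- length(obs)
  m <- length(conc)

  # parameter packing: log kinetic parameters, raw baseline offsets
  kin_names <- if (model == "bivalent") c("ka1", "ka2", "kd1", "kd2", "rmax")
               else c("ka1", "kd1", "rmax")
  defaults <- c(ka1 = 1e4, ka2 = 1e-3, kd1 = 0.1, kd2 = 0.01,
                rmax = max(obs))
  if (!is.null(start)) defaults[names(start)] <- start
  base_start <- log(defaults[kin_names])

  unpack <- function(theta) {
    p <- exp(theta[seq_along(kin_names)])
    names(p) <- kin_names
    k4 <- if (model == "bivalent") p[c("ka1", "ka2", "kd1", "kd2")]
          else c(p[["ka1"]], 0, p[["kd1"]], 0)
    offs <- if (baseline) theta[-seq_along(kin_names)] else numeric(0)
    list(k4 = unname(k4), rmax = unname(p[["rmax"]]), offsets = offs)
  }
  # soft box +-4 decades around the starting guess: keeps the optimizer out
  # of pathologically stiff parameter regions without constraining any
  # plausible SPR fit
  box_halfwidth <- log(1e4)
  objective <- function(theta) {
    kin <- theta[seq_along(kin_names)]
    excess <- sum(pmax(0, abs(kin - base_start) - box_halfwidth))
    if (excess > 0) return(1e12 * (1 + excess))
    u <- unpack(theta)
    v <- tryCatch(
      bivalent_sse_cpp(u$k4, u$rmax, conc, times, t_assoc, u$offsets, obs,
                       rtol, atol),
      error = function(e) Inf)
    if (!is.finite(v)) 1e30 else v
  }

  starts <- list(c(base_start, if (baseline) rep(0, m)))
  if (n_starts > 1) {
    rng <- local_rng(seed)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- c(base_start + log(10) * runif(length(base_start), -0.5, 0.5),
                           if (baseline) rep(0, m))
    rng()
  }

  best <- NULL
  for (th0 in starts) {
    o1 <- optim(th0, objective, method = "Nelder-Mead",
                control = list(maxit = 800, reltol = 1e-10))
    o2 <- tryCatch(
      optim(o1$par, objective, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  u <- unpack(best$par)
  p_nat <- exp(best$par[seq_along(kin_names)])
  names(p_nat) <- kin_names
  n_par <- length(best$par)
  sigma2 <- best$value / max(n_obs - n_par, 1)

  # per-parameter uncertainty: 2 * sigma2 * inverse Hessian of the SSE,
  # delta method back to the natural scale
  se <- rep(NA_real_, length(kin_names))
  names(se) <- kin_names
  hess_ok <- FALSE
  H <- tryCatch(optimHess(best$par, objective), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)[seq_along(kin_names)]
      if (all(is.finite(d)) && all(d >= 0)) {
        se <- p_nat * sqrt(d)   # d theta = d log p  =>  d p = p d theta
        hess_ok <- TRUE
      }
    }
  }

  fitted_mat <- bivalent_responses_cpp(u$k4, u$rmax, conc, times, t_assoc,
                                       u$offsets, rtol, atol)
  per_curve <- colSums((fitted_mat - obs)^2)
  constants <- rate_constants(u$k4[1], u$k4[2], u$k4[3], u$k4[4])
  aic <- n_obs * log(best$value / n_obs) + 2 * n_par

  structure(list(
    model = model, constants = constants, rmax = u$rmax,
    baseline = if (baseline) u$offsets else NULL,
    kd_app1 = kd_app1(constants),
    se = se, sse = best$value, per_curve_sse = per_curve,
    n_obs = n_obs, n_par = n_par, sigma = sqrt(sigma2), aic = aic,
    converged = best$convergence == 0 && hess_ok,
    optim_convergence = best$convergence,
    fitted = fitted_mat, times = times, conc = conc, t_assoc = t_assoc,
    data = sensorgrams, obs = obs,
    rtol = rtol, atol = atol, call = match.call()),
    class = "spr_fit")
}

# run code with a seeded RNG, restoring the caller's RNG state on exit;
# returns the restore function so callers control when to restore
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(unclass(object$constants)[if (object$model == "bivalent")
      c("ka1", "ka2", "kd1", "kd2") else c("ka1", "kd1")],
    rmax = object$rmax)
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("Global SPR kinetic fit (%s model), %d curves, %d points\n",
              x$model, length(x$conc), x$n_obs))
  print(x$constants)
  cat(sprintf("  rmax = %.1f RU, SSE = %.4g RU^2, sigma = %.3g RU\n",
              x$rmax, x$sse, x$sigma))
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
summary.spr_fit <- function(object, ...) {
  est <- coef(object)
  se <- c(object$se[names(est)[names(est) != "rmax"]], rmax = unname(object$se["rmax"]))
  tab <- cbind(Estimate = est, `Std. Error` = se[names(est)])
  structure(list(fit = object, coefficients = tab,
                 kd_app1 = object$kd_app1, aic = object$aic),
            class = "summary.spr_fit")
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("\nKD_app1 = kd1/ka1 = %.4g M;  AIC = %.2f\n", x$kd_app1, x$aic))
  cat("Per-curve SSE (RU^2):\n")
  print(signif(x$fit$per_curve_sse, 4))
  invisible(x)
}

#' @export
fitted.spr_fit <- function(object, ...) object$fitted

#' @export
residuals.spr_fit <- function(object, ...) object$obs - object$fitted

#' @export
deviance.spr_fit <- function(object, ...) object$sse

#' @export
logLik.spr_fit <- function(object, ...) {
  n <- object$n_obs
  val <- -n / 2 * (log(2 * pi * object$sse / n) + 1)
  structure(val, df = object$n_par + 1, nobs = n, class = "logLik")
}

#' Predict sensorgrams from a fitted kinetic model
#'
#' @param object An `spr_fit`.
#' @param concentrations Optional vector of analyte concentrations (M); the
#'   fitted series by default.
#' @param protocol Optional [injection_protocol()] template; the fitted
#'   protocol by default (its concentration field is ignored).
#' @param ... Unused.
#' @return A list of noise-free [sensorgram()]s at the fitted parameters.
#' @export
predict.spr_fit <- function(object, concentrations = NULL, protocol = NULL, ...) {
  if (is.null(concentrations)) concentrations <- object$conc
  lapply(concentrations, function(cc) {
    p <- if (is.null(protocol))
      injection_protocol(cc, object$t_assoc,
                         max(object$times) - object$t_assoc,
                         diff(object$times[1:2]))
    else injection_protocol(cc, protocol$t_association, protocol$t_dissociation,
                            protocol$sampling_interval)
    simulate_sensorgram(object$constants, object$rmax, p,
                        rtol = object$rtol, atol = object$atol)
  })
}

#' @export
plot.spr_fit <- function(x, ...) {
  matplot(x$times, x$obs, type = "l", lty = 1, col = "grey40",
          xlab = "Time (s)", ylab = "Response (RU)", ...)
  matplot(x$times, x$fitted, type = "l", lty = 2, col = "red3", add = TRUE)
  abline(v = x$t_assoc, lty = 3)
  legend("topright", c("data", "fit"), lty = c(1, 2),
         col = c("grey40", "red3"), bty = "n")
  invisible(x)
}

#' Simulate replicate datasets from a fitted kinetic model
#'
#' @param object An `spr_fit`.
#' @param nsim Number of replicate series.
#' @param seed RNG seed.
#' @param sigma Noise standard deviation (RU); defaults to the fit's
#'   residual sigma.
#' @param ... Unused.
#' @return A list of `nsim` lists of noisy [sensorgram()]s.
#' @export
simulate.spr_fit <- function(object, nsim = 1, seed = 1, sigma = NULL, ...) {
  if (is.null(sigma)) sigma <- object$sigma
  p0 <- injection_protocol(object$conc[1], object$t_assoc,
                           max(object$times) - object$t_assoc,
                           diff(object$times[1:2]))
  lapply(seq_len(nsim), function(i)
    noisy_sensorgrams(object$constants, object$rmax, object$conc,
                      protocol = p0,
                      noise = noise_spec(sigma = sigma, seed = seed + i - 1)))
}

#' Model discrimination between two global kinetic fits
#'
#' Compares two fits of the same data (typically 1:1 Langmuir versus the
#' bivalent-analyte model) by their SSE ratio and AIC difference, the usual
#' evidence cited when a titration "cannot be fitted by a 1:1 model".
#'
#' @param object,fit2 Two `spr_fit` objects on the same data.
#' @param ... Unused.
#' @return A data frame with one row per model (SSE, parameters, AIC) plus
#'   attributes `sse_ratio` and `delta_aic` (first relative to second).
#' @export
anova.spr_fit <- function(object, fit2, ...) {
  if (!inherits(fit2, "spr_fit"))
    abort("need two spr_fit objects to compare", "protomer_domain_error")
  if (object$n_obs != fit2$n_obs)
    abort("fits must be on the same data", "protomer_domain_error")
  tab <- data.frame(model = c(object$model, fit2$model),
                    n_par = c(object$n_par, fit2$n_par),
                    sse = c(object$sse, fit2$sse),
                    aic = c(object$aic, fit2$aic))
  attr(tab, "sse_ratio") <- object$sse / fit2$sse
  attr(tab, "delta_aic") <- object$aic - fit2$aic
  tab
}
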