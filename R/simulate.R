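#' Right-hand side of the bivalent-analyte rate equations
#'
#' Time derivatives of the surface species for the two-step scheme
#' `A + L <-> AL`, `AL + L <-> AL2`:
#' \deqn{dL/dt   = -(ka1 A L - kd1 AL) - (ka2 AL L - kd2 AL2)}
#' \deqn{dAL/dt  =  (ka1 A L - kd1 AL) - (ka2 AL L - kd2 AL2)}
#' \deqn{dAL2/dt =   ka2 AL L - kd2 AL2}
#' The combination `L + AL + 2 AL2` is algebraically conserved: each bridged
#' complex sequesters two ligands.
#'
#' @param state Named numeric vector `c(L=, AL=, AL2=)` in RU.
#' @param analyte Analyte concentration (molar).
#' @param k A [rate_constants()] object.
#' @return Named numeric vector of derivatives (RU/s).
#' @examples
#' k <- rate_constants(3.1e4, 1.9e-3, 0.36, 0.02)
#' bivalent_rhs(c(L = 100, AL = 10, AL2 = 5), 1e-6, k)
#' @export
bivalent_rhs <- function(state, analyte, k) {
  k <- as_rate_constants(k)
  if (length(state) != 3 || anyNA(state))
    abort("state must be the three species amounts (L, AL, AL2)",
          "protomer_domain_error")
  if (any(state < 0) || analyte < 0)
    abort("species amounts and analyte concentration must be >= 0",
          "protomer_domain_error")
  L <- state[[1]]; AL <- state[[2]]; AL2 <- state[[3]]
  f1 <- k[["ka1"]] * analyte * L - k[["kd1"]] * AL
  f2 <- k[["ka2"]] * AL * L - k[["kd2"]] * AL2
  c(L = -f1 - f2, AL = f1 - f2, AL2 = f2)
}

#' Simulate an SPR sensorgram under the bivalent-analyte model
#'
#' Integrates the rate equations (see [bivalent_rhs()]) over an injection:
#' analyte at the protocol concentration during association, zero during
#' dissociation, starting from an empty surface (`L(0) = rmax`,
#' `AL(0) = AL2(0) = 0`). The observed response is `AL + AL2`: each bound
#' analyte contributes its mass once whether or not it bridges two ligands.
#'
#' With `ka2 = kd2 = 0` the simulation reduces exactly to the 1:1 Langmuir
#' model, whose association phase has the closed form
#' `R(t) = Req (1 - exp(-(ka1 C + kd1) t))` with
#' `Req = rmax C / (C + kd1/ka1)`.
#'
#' @param k A [rate_constants()] object.
#' @param rmax Surface capacity (RU), the amount of active immobilized
#'   ligand; must be > 0.
#' @param protocol An [injection_protocol()].
#' @param rtol,atol Integrator tolerances (relative; absolute in RU). The
#'   defaults keep the conservation defect of `L + AL + 2 AL2` below
#'   `1e-6 * rmax`.
#' @return A [sensorgram()] whose `species` attribute holds the full
#'   `(L, AL, AL2)` trajectories.
#' @examples
#' k <- rate_constants(3.1e4, 1.9e-3, 0.36, 0.02)
#' sg <- simulate_sensorgram(k, rmax = 500, injection_protocol(30e-6))
#' max(sg$response)
#' @export
simulate_sensorgram <- function(k, rmax, protocol, rtol = 1e-8, atol = 1e-10) {
  k <- as_rate_constants(k)
  if (rmax <= 0) abort("rmax must be > 0", "protomer_domain_error")
  if (protocol$concentration < 0)
    abort("analyte concentration must be >= 0", "protomer_domain_error")
  times <- protocol_times(protocol)
  states <- tryCatch(
    bivalent_states_cpp(unclass(k), rmax, protocol$concentration, times,
                        protocol$t_association, rtol, atol),
    error = function(e) abort(conditionMessage(e), "protomer_integration_failure"))
  colnames(states) <- c("L", "AL", "AL2")
  sensorgram(times, states[, "AL"] + states[, "AL2"], protocol,
             species = states)
}
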