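test_that("bivalent rate equations match the reaction scheme", {
  k <- table2_mg

  # empty surface with no analyte is at equilibrium
  expect_equal(unname(bivalent_rhs(c(L = 500, AL = 0, AL2 = 0), 0, k)),
               c(0, 0, 0))

  # direct arithmetic at a mixed state with the Mg-only constants:
  # dAL2/dt = ka2*AL*L - kd2*AL2 = 1.9e-3*10*100 - 2.0e-2*5
  d <- bivalent_rhs(c(L = 100, AL = 10, AL2 = 5), 1e-6, k)
  expect_equal(unname(d[["AL2"]]), 1.9e-3 * 10 * 100 - 2.0e-2 * 5)
  expect_equal(unname(d[["AL2"]]), 1.8, tolerance = 1e-12)

  # ka2 = kd2 = 0 collapses to the 1:1 scheme
  k1 <- rate_constants(3.1e4, 0, 0.36, 0)
  d1 <- bivalent_rhs(c(L = 100, AL = 10, AL2 = 0), 1e-6, k1)
  expect_equal(unname(d1[["AL2"]]), 0)
  expect_equal(unname(d1[["L"]]), -(3.1e4 * 1e-6 * 100 - 0.36 * 10))

  # d(L + AL + 2 AL2)/dt = 0 algebraically, at random states
  set.seed(42)
  for (i in 1:20) {
    st <- runif(3, 0, 300)
    dd <- bivalent_rhs(st, runif(1, 0, 1e-4),
                       rate_constants(10^runif(1, 3, 5), 10^runif(1, -4, -2),
                                      10^runif(1, -2, 0), 10^runif(1, -3, -1)))
    expect_equal(unname(dd[1] + dd[2] + 2 * dd[3]), 0, tolerance = 1e-9)
  }

  expect_error(bivalent_rhs(c(-1, 0, 0), 1e-6, k), class = "protomer_domain_error")
  expect_error(bivalent_rhs(c(1, 0, 0), -1e-6, k), class = "protomer_domain_error")
  expect_error(rate_constants(-1, 0, 0, 0), class = "protomer_domain_error")
})

test_that("simulated sensorgrams conserve ligand and respect phase structure", {
  # no analyte, no binding
  sg0 <- simulate_sensorgram(table2_mg, 500, injection_protocol(0))
  expect_equal(max(abs(sg0$response)), 0)

  set.seed(7)
  for (i in 1:5) {
    k <- rate_constants(10^runif(1, 3.5, 4.8), 10^runif(1, -4, -2.5),
                        10^runif(1, -1.5, -0.2), 10^runif(1, -2.5, -1))
    rmax <- runif(1, 100, 800)
    cc <- 10^runif(1, -6.5, -4.5)
    sg <- simulate_sensorgram(k, rmax, injection_protocol(cc))
    sp <- attr(sg, "species")
    # conservation: L + AL + 2 AL2 = Rmax at every sample
    expect_lt(max(abs(sp[, "L"] + sp[, "AL"] + 2 * sp[, "AL2"] - rmax)),
              1e-6 * rmax)
    expect_true(all(sp >= -1e-9 * rmax))
    # dissociation-phase response is non-increasing
    diss <- sg$response[sg$time >= 120]
    expect_true(all(diff(diss) <= 1e-9 * rmax))
    expect_equal(sg$response[1], 0)
  }
})

test_that("bivalent simulator reduces to closed-form 1:1 Langmuir kinetics", {
  ka1 <- 3.1e4; kd1 <- 0.36; rmax <- 500
  k <- rate_constants(ka1, 0, kd1, 0)
  for (cc in c(0.5e-6, 5e-6, 30e-6)) {
    sg <- simulate_sensorgram(k, rmax, injection_protocol(cc))
    ref <- langmuir_closed_form(ka1, kd1, rmax, cc, sg$time, 120)
    expect_lt(max(abs(sg$response - ref)) / max(ref), 1e-6)
  }
})

test_that("extreme rate constants signal integration failure, not nonsense", {
  k <- rate_constants(1e15, 0, 1e12, 0)
  expect_error(simulate_sensorgram(k, 500, injection_protocol(30e-6)),
               class = "protomer_integration_failure")
})

test_that("first-step apparent affinity is the ratio kd1/ka1", {
  # printed rate constants reproduce the printed apparent KDs
  expect_equal(kd_app1(table2_mg) * 1e6, 11.6, tolerance = 0.02)
  expect_equal(kd_app1(table2_camg) * 1e6, 25, tolerance = 0.01)
  expect_equal(kd_app1(rate_constants(3.1e4, 0, 0, 0)), 0)
  expect_error(kd_app1(rate_constants(0, 0, 0.1, 0)),
               class = "protomer_domain_error")
})

test_that("global fit recovers generating constants from noise-free data", {
  sgs <- noisy_sensorgrams(table2_mg, rmax = 500, make_series(30e-6, 2, 8),
                           noise = noise_spec(sigma = 0, seed = 1))
  fit <- spr_fit(sgs, model = "bivalent")
  est <- c(coef(fit)[c("ka1", "ka2", "kd1", "kd2")], rmax = fit$rmax)
  truth <- c(unclass(table2_mg), rmax = 500)
  expect_lt(max(abs(est - truth) / truth), 1e-3)
  expect_true(fit$converged)
  # internal consistency: reported kd_app1 is exactly kd1/ka1 of the fit
  expect_identical(fit$kd_app1, kd_app1(fit$constants))
  # fitted responses and residuals line up
  expect_equal(dim(residuals(fit)), c(321, 8))
  expect_lt(fit$sse, 1e-2)
})

test_that("model discrimination separates 1:1 from bivalent data", {
  sgs <- noisy_sensorgrams(table2_mg, rmax = 500, make_series(30e-6, 2, 4),
                           noise = noise_spec(sigma = 0.5, seed = 11))
  fb <- spr_fit(sgs, model = "bivalent", n_starts = 3)
  fl <- spr_fit(sgs, model = "langmuir", n_starts = 3)
  cmp <- anova(fl, fb)
  # bivalent data cannot be fitted by the 1:1 model
  expect_gt(attr(cmp, "sse_ratio"), 10)
  expect_gt(attr(cmp, "delta_aic"), 0)

  # and on genuinely 1:1 data the Langmuir fit recovers its constants
  k1 <- rate_constants(3.1e4, 0, 0.36, 0)
  sgs1 <- noisy_sensorgrams(k1, rmax = 300, make_series(30e-6, 2, 4),
                            noise = noise_spec(sigma = 0, seed = 2))
  f1 <- spr_fit(sgs1, model = "langmuir", n_starts = 3)
  expect_lt(abs(coef(f1)[["ka1"]] - 3.1e4) / 3.1e4, 1e-3)
  expect_lt(abs(coef(f1)[["kd1"]] - 0.36) / 0.36, 1e-3)
})

test_that("degenerate inputs raise classed signals", {
  p <- injection_protocol(1e-6)
  t <- seq(0, 320, 1)
  flat <- sensorgram(t, rep(0, length(t)), p)
  expect_error(spr_fit(list(flat), model = "bivalent"),
               class = "protomer_degenerate_fit")
  sg <- simulate_sensorgram(table2_mg, 500, p)
  expect_error(spr_fit(list(sg), model = "bivalent"),
               class = "protomer_domain_error")  # one curve is not a series
  expect_error(spr_fit(list(sg, sg), model = "bivalent"),
               class = "protomer_domain_error")  # duplicated concentration
})

test_that("steady-state hyperbola fit recovers exact and refuses flat data", {
  C <- c(1, 2, 5, 10, 20, 50, 100, 200, 500) * 1e-6
  R <- 200 * C / (C + 100e-6)
  f <- steady_state_fit(C, R)
  expect_equal(f$kd_app_tot, 100e-6, tolerance = 1e-6)
  expect_equal(f$rmax_eq, 200, tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)
  expect_equal(predict(f, 100e-6), f$rmax_eq / 2, tolerance = 1e-5)

  expect_error(steady_state_fit(C, rep(0, length(C))),
               class = "protomer_unidentifiable_fit")
  expect_error(steady_state_fit(C, rep(50, length(C))),
               class = "protomer_unidentifiable_fit")
  expect_error(steady_state_fit(C[1:2], R[1:2]), class = "protomer_domain_error")
})
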