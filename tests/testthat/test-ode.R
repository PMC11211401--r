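test_that("boundary equilibria satisfy the closed forms and zero the rhs", {
  p <- ode_params()
  eqI <- equilibrium_I(p)
  expect_equal(as.numeric(eqI), c(0, 500))
  expect_equal(attr(eqI, "total_hosts"), 1000)
  expect_equal(unname(equilibrium_I(ode_params(b0 = 6))["x_minus"]), 1000)
  expect_equal(unname(equilibrium_I(ode_params(b0 = 2))["x_minus"]), 0)
  expect_equal(unname(equilibrium_II(ode_params(w = 1))["x_plus"]), 500)
  expect_equal(unname(equilibrium_II(ode_params(w = 0.6))["x_plus"]), 100)
  expect_equal(unname(equilibrium_II(ode_params(w = 0.5))["x_plus"]), 0)
  set.seed(51)
  for (i in 1:15) {
    # equilibrium II requires one parent to transmit with certainty
    # (alpha = 1 here, as in every mode the model uses); otherwise the
    # all-carrier state leaks non-carrier offspring at rate (1-a)(1-b)
    pr <- ode_params(b0 = runif(1, 2.5, 6), d0 = runif(1, 0.5, 1.2),
                     dprime = runif(1, 5e-4, 5e-3), nu = runif(1, 0.5, 2),
                     alpha = 1, beta = runif(1), w = runif(1, 0.6, 2))
    expect_equal(max(abs(rhs_two_type(equilibrium_I(pr), pr))), 0,
                 tolerance = 1e-10)
    expect_equal(max(abs(rhs_two_type(equilibrium_II(pr), pr))), 0,
                 tolerance = 1e-10)
  }
})

test_that("invasion rate at equilibrium I matches its linearisation", {
  expect_equal(invasion_rate_at_I(ode_params(w = 0.5), "biparental"), 0)
  expect_equal(invasion_rate_at_I(ode_params(w = 1), "maternal"), 0)
  expect_equal(invasion_rate_at_I(ode_params(w = 0.6), "biparental"), 2 / 3)
  # numeric per-capita growth of a tiny carrier density at equilibrium I
  set.seed(52)
  for (i in 1:10) {
    p <- ode_params(b0 = runif(1, 2.5, 6), d0 = runif(1, 0.5, 1.2),
                    w = runif(1, 0.3, 2))
    mode <- sample(c("biparental", "maternal"), 1)
    p2 <- symsieve:::.ode_with_mode(p, mode)
    xI <- unname(equilibrium_I(p)["x_minus"])
    eps <- 1e-8 * xI
    f <- rhs_two_type(c(eps, xI), p2)
    expect_equal(f[1] / eps, invasion_rate_at_I(p, mode), tolerance = 1e-6)
  }
})

test_that("thresholds take their closed-form values", {
  expect_equal(unname(ode_thresholds(ode_params())), c(0.5, 1, 0.5))
  expect_equal(unname(ode_thresholds(ode_params(b0 = 2, d0 = 1))["w1"]), 1)
  # w1 = 2 d0 / b0 does not involve dprime or nu
  expect_equal(ode_thresholds(ode_params(dprime = 0.1, nu = 7))[["w1"]],
               ode_thresholds(ode_params())[["w1"]])
})

test_that("integration is stationary at equilibria and respects thresholds", {
  p <- ode_params()
  eqI <- equilibrium_I(p)
  sol <- integrate_two_type(eqI, p, c(0, 20), mode = "biparental")
  expect_equal(sol$x_minus[nrow(sol)], 500, tolerance = 1e-6)
  expect_equal(sol$x_plus[nrow(sol)], 0, tolerance = 1e-6)
  # supercritical maternal invasion converges to equilibrium II
  p2 <- ode_params(w = 1.2)
  sol2 <- integrate_two_type(c(5, 500), p2, c(0, 300), mode = "maternal")
  expect_equal(sol2$x_plus[nrow(sol2)],
               unname(equilibrium_II(p2)["x_plus"]), tolerance = 1e-4)
  expect_lt(sol2$x_minus[nrow(sol2)], 1e-4)
})

test_that("outcome classification matches the stated examples", {
  expect_identical(as.character(
    classify_outcome(ode_params(w = 0.37, e0 = 0.1), "biparental")),
    "bimorphic")
  expect_identical(as.character(
    classify_outcome(ode_params(w = 1.2), "maternal")), "fixation")
  expect_identical(as.character(
    classify_outcome(ode_params(w = 0.6), "maternal")), "loss")
  expect_identical(as.character(
    classify_outcome(ode_params(w = 0.3, e0 = 0.5), "biparental")),
    "host_extinction")
})

test_that("C and R classification engines agree", {
  cases <- expand.grid(w = c(0.3, 0.6, 0.9, 1.2), e0 = c(0, 0.1, 0.5),
                       mode = c("biparental", "maternal"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    p <- ode_params(w = cases$w[i], e0 = cases$e0[i])
    cc <- classify_outcome(p, cases$mode[i], engine = "C")
    cr <- classify_outcome(p, cases$mode[i], engine = "R")
    info <- sprintf("w=%g e0=%g %s", cases$w[i], cases$e0[i], cases$mode[i])
    if ("unresolved" %in% c(cc, cr) && !identical(as.character(cc),
                                                  as.character(cr))) {
      # weakly damped spiral cells can split the razor-edge stopping rule;
      # the two integrations must still agree on the terminal state
      expect_equal(attr(cc, "state"), attr(cr, "state"), tolerance = 1e-3,
                   info = info)
    } else {
      expect_identical(as.character(cc), as.character(cr), info = info)
    }
  }
})

test_that("classification flips loss/fixation at the invasion threshold", {
  for (mode in c("biparental", "maternal")) {
    w0 <- unname(ode_thresholds(ode_params())[
      if (mode == "biparental") "w0_biparental" else "w0_maternal"])
    below <- classify_outcome(ode_params(w = w0 - 0.02), mode)
    above <- classify_outcome(ode_params(w = w0 + 0.02), mode)
    expect_identical(as.character(below), "loss")
    expect_identical(as.character(above), "fixation")
  }
})

test_that("maternal and paternal transmission are interchangeable", {
  pm <- ode_params(w = 0.8, e0 = 0.05, alpha = 1, beta = 0)
  pp <- ode_params(w = 0.8, e0 = 0.05, alpha = 0, beta = 1)
  s1 <- integrate_two_type(c(5, 500), pm, c(0, 30), t_eval = seq(0, 30, 5))
  s2 <- integrate_two_type(c(5, 500), pp, c(0, 30), t_eval = seq(0, 30, 5))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("six-type system degenerates correctly", {
  p <- ode_params(w = 0.6)
  # no fathers: mating fractions undefined
  expect_error(rhs_six_type(c(1, 499, 0, 0, 0, 0), p), "structural extinction")
  # without carriers the system reduces to two-sex logistic growth
  p1 <- ode_params(w = 1)
  Nstar <- uniroot(function(N) p1$d0 + p1$dprime * p1$nu * N - p1$b0 / 2,
                   c(1, 1e5))$root
  tr <- modifier_trajectory(p1, init = c(0, 300, 0, 40, 0, 360),
                            t_span = c(0, 400), t_eval = c(0, 400))
  expect_equal(tr$N[2], Nstar, tolerance = 1e-5)
  # M- absent initially stays absent (no mutation term)
  tr2 <- modifier_trajectory(ode_params(w = 0.6), init = c(5, 495, 0, 0, 0, 500),
                             t_span = c(0, 40), t_eval = c(0, 40))
  expect_equal(tr2$mminus_freq, c(0, 0))
  # neutral symbiont carried by every host: the modifier is exactly neutral
  tr3 <- modifier_trajectory(ode_params(w = 1), init = c(500, 0, 50, 0, 450, 0),
                             t_span = c(0, 50), t_eval = c(0, 50))
  expect_lt(abs(tr3$mminus_freq[2] - tr3$mminus_freq[1]), 1e-9)
})

test_that("phase scan reproduces the expected region structure", {
  wg <- seq(0.05, 1.45, 0.1)
  pd <- phase_scan(wg, c(0, 0.2), "biparental", refine = 4)
  expect_identical(dim(pd$labels), c(length(wg), 2L))
  # e0 = 0 column: loss below 1/2, fixation above
  expect_true(all(pd$labels[wg < 0.45, 1] == "loss"))
  expect_true(all(pd$labels[wg > 0.55, 1] == "fixation"))
  # an extinction region exists at low w for e0 > 0 under biparental rules
  expect_true("host_extinction" %in% pd$labels[, 2])
  # boundary refinement brackets the analytic threshold at e0 = 0
  b <- pd$boundaries[pd$boundaries$e0 == 0, ]
  expect_true(any(b$w_lo <= 0.5 & b$w_hi >= 0.5))
  # maternal: no extinction region for e0 < 1
  pm <- phase_scan(wg, c(0, 0.2), "maternal")
  expect_false("host_extinction" %in% pm$labels)
  expect_true(all(pm$labels[wg < 0.95, 1] == "loss"))
})
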