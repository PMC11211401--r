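test_that("offspring carriage probabilities match presets and enumeration", {
  # preset evaluations of the per-class P(S) row (0, alpha, beta, a+b-ab)
  expect_equal(offspring_carriage_probs("biparental")$p_S, c(0, 1, 1, 1))
  expect_equal(offspring_carriage_probs("maternal")$p_S, c(0, 1, 0, 1))
  expect_equal(offspring_carriage_probs(transmission_params(0.5, 0.5))$p_S,
               c(0, 0.5, 0.5, 0.75))
  # brute-force enumeration oracle across random transmission parameters
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    tab <- offspring_carriage_probs(transmission_params(a, b))
    expect_equal(tab$p_S, enum_offspring_pS(a, b), tolerance = 1e-12)
    expect_equal(tab$p_S + tab$p_s, rep(1, 4))
  }
})

test_that("mean fitness matches its closed form and the class-sum oracle", {
  expect_equal(mean_fitness(0, 0.3, "biparental"), 1)    # no carriers
  expect_equal(mean_fitness(0.7, 1, "maternal"), 1)      # neutral symbiont
  expect_equal(mean_fitness(0.5, 0.6, "biparental"), 0.7)
  set.seed(12)
  for (i in 1:30) {
    p <- runif(1); w <- runif(1, 0.1, 2.5); a <- runif(1); b <- runif(1)
    expect_equal(mean_fitness(p, w, transmission_params(a, b)),
                 enum_mean_fitness(p, w, a, b), tolerance = 1e-12)
  }
  expect_error(mean_fitness(1.2, 0.6, "maternal"), "frequency")
  expect_error(mean_fitness(0.5, -1, "maternal"), "positive")
})

test_that("next_frequency and delta_p are consistent, with correct fixed points", {
  expect_equal(next_frequency(0.5, 0.6, "maternal"), 0.375)
  expect_equal(delta_p(0.5, 0.6, "maternal"), -0.125)
  expect_gt(delta_p(0.01, 0.6, "biparental"), 0) # deleterious but invading
  expect_equal(delta_p(0.5, 1, "maternal"), 0)   # neutral, maternal
  grid <- expand.grid(p = seq(0, 1, 0.05), w = c(0.3, 0.6, 1, 1.4),
                      a = c(1, 1, 0.5), b = c(1, 0, 0.5))
  for (i in seq_len(nrow(grid))) {
    tp <- transmission_params(grid$a[i], grid$b[i])
    pp <- next_frequency(grid$p[i], grid$w[i], tp)
    expect_true(pp >= 0 && pp <= 1)
    expect_equal(delta_p(grid$p[i], grid$w[i], tp), pp - grid$p[i],
                 tolerance = 1e-12)
  }
  # absorbing states under both presets
  for (mode in c("biparental", "maternal")) {
    expect_equal(next_frequency(0, 0.6, mode), 0)
    expect_equal(next_frequency(1, 0.6, mode), 1)
  }
})

test_that("maternal sign law: sign(delta p) = sign(w - 1) on (0, 1)", {
  for (p in c(0.01, 0.3, 0.9)) {
    expect_lt(delta_p(p, 0.8, "maternal"), 0)
    expect_gt(delta_p(p, 1.2, "maternal"), 0)
    expect_equal(delta_p(p, 1, "maternal"), 0)
  }
})

test_that("invasion threshold equals 1/(alpha+beta) and the bisection oracle", {
  expect_equal(invasion_threshold("biparental"), 0.5)
  expect_equal(invasion_threshold("maternal"), 1)
  expect_equal(invasion_threshold(transmission_params(0.5, 0.5)), 1)
  expect_error(invasion_threshold(transmission_params(0, 0)),
               "no vertical transmission route")
  set.seed(13)
  for (i in 1:8) {
    a <- runif(1, 0.05, 1); b <- runif(1, 0, 1)
    tp <- transmission_params(a, b)
    expect_equal(bisect_threshold(tp), invasion_threshold(tp),
                 tolerance = 1e-6)
  }
})

test_that("recursion trajectories converge according to the threshold law", {
  # below threshold: monotone decline to loss
  tr <- iterate_generations(0.01, 0.6, "maternal", 50)
  expect_true(all(diff(tr) <= 0))
  expect_lt(tr[51], 1e-4)
  # constant at zero
  expect_equal(iterate_generations(0, 0.9, "biparental", 10), rep(0, 11))
  # above threshold: harmful symbiont still sweeps under biparental rules
  fate <- recursion_fate(0.01, 0.6, "biparental")
  expect_identical(fate$outcome, "fixation")
  # threshold law at p0 = 1e-4 for both presets
  for (mode in c("biparental", "maternal")) {
    w0 <- invasion_threshold(mode)
    expect_identical(recursion_fate(1e-4, w0 * 0.95, mode)$outcome, "loss")
    expect_identical(recursion_fate(1e-4, w0 * 1.05, mode)$outcome, "fixation")
  }
  # biparental interval: every w in (0.5, 1] sweeps in finite generations
  for (w in c(0.52, 0.6, 0.8, 1)) {
    fate <- recursion_fate(1e-4, w, "biparental", tol = 1e-6, max_gen = 1e5)
    expect_identical(fate$outcome, "fixation")
  }
})
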