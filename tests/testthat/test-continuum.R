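test_that("floor mapping fixes the lattice correspondence", {
  cp <- continuum_params(12, 18, 0.1, 0.69)
  mp <- as_model_params(cp)
  expect_identical(c(mp$r, mp$s, mp$n0), c(120L, 180L, 180L))

  # both parameterizations of the wide worked example are available:
  # floors give 106 marks for mass on (12, 118] at unit spacing, while the
  # site-level description "marks on sites 12..118" gives 107
  expect_identical(length(make_initial_state(
    as_model_params(continuum_params(12, 118, 1, 0.69)))$marked_positions),
    106L)
  expect_identical(length(make_initial_state(
    model_params(0.69, 118, 11, 118))$marked_positions), 107L)

  expect_error(continuum_params(-1, 5, 0.1, 0.69))
  expect_error(continuum_params(5, 3, 0.1, 0.69))
  expect_error(continuum_occupancy(cp, -2, 1), "positive")
})

test_that("defining sum and binomial closed form agree on dense grids", {
  for (delta in c(0.1, 0.01, 0.001)) {
    cp <- continuum_params(12, 18, delta, 0.69)
    y <- seq(6, 1.3 * 18 * exp(0.69 * 4), length.out = 100)
    for (t in seq(0.4, 4, length.out = 10)) {
      d <- abs(continuum_occupancy(cp, y, t) -
                 continuum_occupancy_binomial(cp, y, t))
      expect_lt(max(d), 1e-10)
    }
  }
})

test_that("profile degenerates correctly at t = 0 and left of the support", {
  cp <- continuum_params(12, 18, 0.1, 0.69)
  expect_identical(continuum_occupancy(cp, c(1, 5, 12.04), 2), c(0, 0, 0))
  y_in <- c(12.15, 15, 17.95)
  expect_equal(continuum_occupancy(cp, y_in, 0), rep(1, 3))
  expect_equal(continuum_occupancy(cp, c(18.3, 25), 0), c(0, 0))
  # upper bound below lower bound gives an empty event
  expect_identical(continuum_occupancy_binomial(cp, 11, 3), 0)
})

test_that("normal approximation hits its anchor points and its spacing-to-zero limit", {
  cp <- continuum_params(12, 18, 0.01, 0.69)
  t <- 1.5
  p <- exp(-0.69 * t)
  y0 <- 12 * exp(0.69 * t)
  k <- floor(y0 / cp$delta)
  u_hi <- (min(18 / y0, 1) - p) / sqrt(p * (1 - p)) * sqrt(k - 1)
  expect_equal(normal_approx(cp, y0, t), p * (pnorm(u_hi) - 0.5),
               tolerance = 1e-12)

  # interior height tends to exp(-lambda t) as delta shrinks
  cp_fine <- continuum_params(12, 18, 1e-6, 0.69)
  y_mid <- 15 * exp(0.69 * t)
  expect_equal(normal_approx(cp_fine, y_mid, t), p, tolerance = 1e-6)

  # the continuity-corrected variant stays close to the literal formula
  expect_lt(abs(normal_approx(cp, y_mid, t) -
                  normal_approx(cp, y_mid, t, correction = TRUE)), 5e-3)
  expect_error(normal_approx(cp, 15, 0), "positive")
})

test_that("limiting profile: five cases, half-height breakpoints, exact mass", {
  a <- 12; b <- 18; lambda <- 0.69; t <- 2
  h <- exp(-lambda * t)
  lo <- a * exp(lambda * t); hi <- b * exp(lambda * t)
  expect_identical(limiting_profile(lo / 2, t, a, b, lambda), 0)
  expect_equal(limiting_profile(lo, t, a, b, lambda), h / 2)
  expect_equal(limiting_profile((lo + hi) / 2, t, a, b, lambda), h)
  expect_equal(limiting_profile(hi, t, a, b, lambda), h / 2)
  expect_identical(limiting_profile(hi * 1.01, t, a, b, lambda), 0)

  # mass b - a at several times, by exact piecewise quadrature
  for (tt in c(0.5, 2, 5)) {
    br <- c(1e-9, a * exp(lambda * tt), b * exp(lambda * tt),
            b * exp(lambda * tt) + 50)
    mass <- segment_integral(function(y)
      limiting_profile(y, tt, a, b, lambda), br)
    expect_lt(abs(mass - (b - a)), 1e-12)
  }
})

test_that("scaled mass: degenerate values, conservation, and the point-mass limit", {
  cp <- continuum_params(12, 18, 0.1, 0.69)
  mp <- as_model_params(cp)
  st0 <- make_initial_state(mp)
  expect_identical(mass_statistic(cp, 12.05, st0), 0)
  expect_equal(mass_statistic(cp, 18, st0), 0.1 * (mp$s - mp$r))
  expect_equal(mass_statistic(cp, 1e9, st0), 0.1 * (mp$s - mp$r))
  expect_error(mass_statistic(cp, 11, st0), "exceed")

  # conservation per realization at any time
  sim <- simulate_proliferation(mp, 2, seed = 61, events = FALSE)
  expect_equal(mass_statistic(cp, 1e9, sim$state), 0.1 * (mp$s - mp$r))

  # LLN: mean mass at an interior point approaches y e^{-lambda t} - a
  t <- 1; y <- 30
  limit <- y * exp(-0.69 * t) - 12
  cpf <- continuum_params(12, 18, 0.02, 0.69)
  mpf <- as_model_params(cpf)
  set.seed(62)
  ms <- vapply(seq_len(300), function(i)
    mass_statistic(cpf, y,
                   simulate_proliferation(mpf, t, events = FALSE)$state),
    numeric(1))
  expect_lt(abs(mean(ms) - limit), 0.05)
})

test_that("CLT standardization centres and scales as printed", {
  cp <- continuum_params(12, 18, 0.1, 0.69)
  t <- 2; y <- 60
  p <- exp(-0.69 * t)
  centre <- 0.1 * (floor(y * p / 0.1) - floor(12 / 0.1))
  expect_equal(clt_standardize(cp, y, t, centre), 0)
  sc <- 0.1 * sqrt((p - p^2) * floor(y / 0.1))
  expect_gt(sc, 0)
  expect_equal(clt_standardize(cp, y, t, centre + sc), 1, tolerance = 1e-12)
  expect_error(clt_standardize(cp, 10, t, 1), "lie in")
  expect_error(clt_standardize(cp, y, 0, 1), "positive")
})

test_that("inter-agent separation collapses as the spacing shrinks", {
  # closed form: Pr(Z_Delta > u) = (1 - e^{-lambda t})^{floor(u/Delta)}
  lambda <- 0.69; t <- 1; u <- 0.5
  surv <- vapply(c(0.5, 0.1, 0.01, 0.001), function(d)
    spacing_survival(floor(u / d), t, lambda), numeric(1))
  expect_true(all(diff(surv) < 0))
  expect_lt(surv[4], 1e-100)

  # empirical check at a moderate spacing
  d <- 0.05
  cp <- continuum_params(12, 18, d, lambda)
  mp <- as_model_params(cp)
  set.seed(63)
  sp <- unlist(lapply(seq_len(100), function(i)
    diff(simulate_proliferation(mp, t, events = FALSE)$state$marked_positions)))
  target <- spacing_survival(floor(0.2 / d), t, lambda)
  emp <- mean(d * sp > 0.2)
  expect_lt(abs(emp - target),
            3.5 * sqrt(target * (1 - target) / length(sp)) + 0.01)
})
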