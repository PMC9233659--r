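test_that("expected occupancy: trivial regimes, oracle values, and the dual-route identity", {
  p <- model_params(0.69, 18, 11, 18)
  expect_identical(expected_occupancy(p, c(3, 11), 2), c(0, 0))
  expect_equal(expected_occupancy(p, 12:18, 0), rep(1, 7))
  expect_equal(expected_occupancy(p, 19:25, 0), rep(0, 7))

  # naive-arithmetic oracle at small k; the series route is relatively
  # exact, the binomial-CDF-difference route is absolutely exact (its
  # relative error degrades in far tails, where the value is ~1e-8)
  for (k in c(12, 15, 20, 40)) for (t in c(0.5, 2)) {
    direct <- sum(vapply(12:min(k, 18), oracle_yule_pmf, numeric(1),
                         k = k, t = t, lambda = 0.69))
    expect_lt(abs(expected_occupancy(p, k, t) - direct), 1e-12)
    expect_equal(expected_occupancy(p, k, t, method = "series"), direct,
                 tolerance = 1e-12)
  }

  # series and binomial routes agree far into continuum scales
  for (t in c(0.5, 1, 2, 4)) {
    k <- unique(c(12:40, round(seq(50, 3000, length.out = 40))))
    expect_lt(max(abs(expected_occupancy(p, k, t, "series") -
                        expected_occupancy(p, k, t, "binomial"))), 1e-10)
  }
  pbig <- model_params(0.69, 18000, 12000, 18000)
  kbig <- round(seq(12001, 3e5, length.out = 25))
  expect_lt(max(abs(expected_occupancy(pbig, kbig, 4, "series") -
                      expected_occupancy(pbig, kbig, 4, "binomial"))),
            1e-10)
})

test_that("occupancy mean and variance match Monte Carlo at a deep site", {
  p <- model_params(0.69, 18, 11, 18)
  k <- 200; t <- 4
  ck <- expected_occupancy(p, k, t)
  vk <- occupancy_variance(p, k, t)
  expect_equal(vk, ck * (1 - ck))
  expect_equal(occupancy_variance(p, 14, 0), 0)

  set.seed(51)
  n <- 1000
  occ <- vapply(seq_len(n), function(i)
    k %in% simulate_proliferation(p, t, events = FALSE)$state$marked_positions,
    logical(1))
  se <- sqrt(ck * (1 - ck) / n)
  expect_lt(abs(mean(occ) - ck), 3.5 * se)
  # sample variance vs C(1-C), delta-method standard error
  se_var <- sqrt((1 - 2 * ck)^2 * ck * (1 - ck) / n +
                   2 * ck^2 * (1 - ck)^2 / (n - 1))
  expect_lt(abs(var(occ) - vk), 3.5 * se_var + 1e-12)
})

test_that("exact profiles conserve the marked mass and peak inside the propagated interval", {
  p <- model_params(0.69, 18, 11, 18)
  pr0 <- occupancy_profile(p, 0)
  expect_equal(pr0$occupancy[pr0$site <= 18], rep(1, 7))

  for (t in c(1, 2, 4)) {
    pr <- occupancy_profile(p, t)
    expect_lt(abs(sum(pr$occupancy) - 7), 1e-8)
    expect_true(all(pr$occupancy >= 0 & pr$occupancy <= 1))
  }

  pr4 <- occupancy_profile(p, 4)
  peak <- pr4$site[which.max(pr4$occupancy)]
  expect_gte(peak, floor(12 * exp(0.69 * 4)))
  expect_lte(peak, ceiling(18 * exp(0.69 * 4)))

  # empty-mark degenerate profile
  pr_empty <- occupancy_profile(model_params(0.69, 10, 4, 4), 1)
  expect_identical(nrow(pr_empty), 0L)
})

test_that("geometric spacing law: closed form and simulated spacings", {
  expect_equal(spacing_pmf(1, t = 1, lambda = 0.69), exp(-0.69),
               tolerance = 1e-14)
  expect_identical(spacing_pmf(0, 1, 0.69), 0)
  expect_equal(sum(spacing_pmf(1:5000, 2, 0.69)), 1, tolerance = 1e-12)
  expect_equal(spacing_survival(0:3, 1, 0.69),
               (1 - exp(-0.69))^(0:3), tolerance = 1e-14)

  g <- gof_spacing(model_params(0.69, 118, 11, 118), t = 4, n_reps = 100,
                   seed = 52)
  expect_gt(g$p_value, 0.01)
  expect_true(g$verdict)
})

test_that("marked-count distribution: dual routes, monotonicity, properness", {
  p <- model_params(0.69, 18, 11, 18)

  expect_identical(marked_count_cdf(p, k = 14, j = 15, t = 2), 1)
  expect_identical(marked_count_cdf(p, k = 40, j = 18, t = 2), 1)
  expect_identical(marked_count_cdf(p, k = 40, j = 14, t = 0), 0)
  expect_identical(marked_count_cdf(p, k = 20, j = 18, t = 0), 1)
  expect_error(marked_count_cdf(p, k = 40, j = 10, t = 2), "j")
  expect_error(marked_count_cdf(p, k = 11, j = 14, t = 2), "k")

  # dual-route agreement across a sweep (also exercised inside "both")
  for (t in c(0.5, 1, 2, 4)) for (k in c(13, 20, 40, 80, 200))
    for (j in 11:17) {
      if (k <= p$r) next
      a <- marked_count_cdf(p, k, j, t, method = "series")
      b <- marked_count_cdf(p, k, j, t, method = "renewal")
      expect_lt(abs(a - b), 1e-10)
    }

  # j = r edge: Pr(M_k <= 0) is the first marked agent's survival
  expect_equal(marked_count_cdf(p, k = 30, j = 11, t = 2),
               1 - yule_cdf(30, 2, 0.69, start = 12), tolerance = 1e-12)

  # monotone: nonincreasing in k, nondecreasing in j
  for (j in c(12, 14, 16)) {
    vals_k <- vapply(13:60, marked_count_cdf, numeric(1), params = p,
                     j = j, t = 2)
    expect_true(all(diff(vals_k) <= 1e-12))
  }
  vals_j <- vapply(11:18, marked_count_cdf, numeric(1), params = p,
                   k = 40, t = 2)
  expect_true(all(diff(vals_j) >= -1e-12))

  # differences over j form a proper distribution of M_k
  k <- 25; t <- 1.5
  cdf <- vapply(11:18, marked_count_cdf, numeric(1), params = p,
                k = k, t = t)
  pmf <- diff(c(0, cdf))
  expect_true(all(pmf >= -1e-12))
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
})

test_that("marked-count distribution matches the simulator", {
  p <- model_params(0.69, 18, 11, 18)
  t <- 2
  set.seed(53)
  n <- 10000
  m40 <- vapply(seq_len(n), function(i) {
    pos <- simulate_proliferation(p, t, events = FALSE)$state$marked_positions
    sum(pos <= 40L)
  }, integer(1))
  for (j in c(12, 14, 16)) {
    f <- marked_count_cdf(p, 40, j, t)
    emp <- mean(m40 <= j - 11)
    expect_lt(abs(emp - f), 3.5 * sqrt(f * (1 - f) / n))
  }
})

test_that("hypergeometric series: closed-form cases, brute-force oracle, explicit failure", {
  expect_identical(hyp2f1_b1(3.2, 1.1, 0), 1)
  expect_equal(hyp2f1_b1(5, 5, 0.4), 1 / 0.6, tolerance = 1e-14)
  expect_equal(hyp2f1_b1(5, 3, 0.3), oracle_2f1(5, 3, 0.3),
               tolerance = 1e-13)
  expect_equal(hyp2f1_b1(41, 27, 0.748), oracle_2f1(41, 27, 0.748, 2000),
               tolerance = 1e-12)
  expect_error(hyp2f1_b1(2, -1, 0.5), "nonpositive")
  expect_error(hyp2f1_b1(2, 3, 1), "0, 1")
  expect_error(hyp2f1_b1(50, 2, 0.99, max_iter = 5), "converge")
})

test_that("expected length doubles when lambda*t is log 2, and matches simulation", {
  expect_identical(expected_length(3, 0, 0.69), 3)
  expect_equal(expected_length(1, 1, 0.69), exp(0.69), tolerance = 1e-14)
  expect_equal(expected_length(5, 1, log(2)), 10, tolerance = 1e-12)

  delta <- 0.1
  p <- model_params(0.69, 60, 0, 60)   # L(0) = 6
  set.seed(54)
  lt <- vapply(seq_len(1000), function(i)
    delta * simulate_proliferation(p, 1, events = FALSE)$state$n_agents,
    numeric(1))
  se <- sd(lt) / sqrt(length(lt))
  expect_lt(abs(mean(lt) - expected_length(6, 1, 0.69)), 3.5 * se)
})

test_that("splitting rate is recovered from simulated spacings", {
  p <- model_params(0.69, 500, 0, 500)
  sim <- simulate_proliferation(p, 2, seed = 55, events = FALSE)
  lam_hat <- fit_spacing_rate(diff(sim$state$marked_positions), 2)
  expect_lt(abs(lam_hat - 0.69) / 0.69, 0.05)
  expect_error(fit_spacing_rate(integer(0), 2), "nonempty")
  expect_error(fit_spacing_rate(c(1, 2), 0), "positive")
})
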