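new_gof_report <- function(test_name, statistic, p_value, n_samples, alpha,
                           seed, params, extra = list()) {
  structure(
    c(list(test_name = test_name, statistic = unname(statistic),
           p_value = unname(p_value), n_samples = n_samples,
           alpha = alpha, verdict = unname(p_value) > alpha, seed = seed,
           params = params), extra),
    class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("GOF: %s\n  statistic = %.4f, p = %.4g, n = %d -> %s (alpha = %g)\n",
              x$test_name, x$statistic, x$p_value, x$n_samples,
              if (x$verdict) "PASS" else "FAIL", x$alpha))
  invisible(x)
}

# Chi-square of observed integer draws against a pmf on {support_min, ...}.
# Deterministic rightward tail accumulation: category bounds grow until the
# expected count of the open tail bin reaches `min_expected`; any interior
# bin below `min_expected` is merged rightward.
.chisq_vs_pmf <- function(obs, pmf, support_min = 1L, min_expected = 5) {
  n <- length(obs)
  kmax <- support_min
  repeat {
    tail_mass <- 1 - sum(pmf(support_min:kmax))
    if (n * tail_mass < min_expected || kmax > support_min + 10000L) break
    kmax <- kmax + 1L
  }
  breaks <- support_min:kmax          # categories: each value, then [kmax, Inf)
  probs <- pmf(breaks)
  probs[length(probs)] <- 1 - sum(probs[-length(probs)])
  counts <- tabulate(pmin(obs, kmax) - support_min + 1L,
                     nbins = length(breaks))
  # merge any light interior bins rightward (deterministic)
  i <- 1L
  while (i < length(probs)) {
    if (n * probs[i] < min_expected) {
      probs[i + 1L] <- probs[i + 1L] + probs[i]
      counts[i + 1L] <- counts[i + 1L] + counts[i]
      probs <- probs[-i]; counts <- counts[-i]
    } else i <- i + 1L
  }
  if (length(probs) < 2L)
    stop("too few chi-square categories; increase the sample size",
         call. = FALSE)
  ht <- suppressWarnings(chisq.test(counts, p = probs))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n = n)
}

#' Monte-Carlo occupancy profile
#'
#' Per-site empirical mean marked occupancy over `n_reps` realizations of
#' either simulator, with standard errors
#' \eqn{\sqrt{\hat p(1-\hat p)/n}}.  The site range is chosen to cover
#' every observed mark.  When `t` is a vector, all snapshot times share a
#' single simulation pass and a list of profiles is returned.
#'
#' @param params A [model_params()] object.
#' @param t Evaluation time(s).
#' @param n_reps Number of realizations (>= 2).
#' @param seed Optional integer seed.
#' @param sim `"coupled"` (the proliferation process) or `"independent"`
#'   (uncoupled Yule-Furry walkers).
#' @return An `occupancy_profile` with columns `site`, `occupancy`, `se`
#'   (or a named list of profiles for vector `t`).
#' @export
mc_occupancy <- function(params, t, n_reps, seed = NULL,
                         sim = c("coupled", "independent")) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t)
  n_reps <- .check_count(n_reps, "n_reps", min = 2L)
  sim <- match.arg(sim)
  .maybe_seed(if (is.null(seed)) params$seed else seed)
  times <- sort(unique(as.numeric(t)))
  marks0 <- if (params$s > params$r)
    seq.int(params$r + 1L, params$s) else integer(0)
  counts <- vector("list", length(times))
  for (i_rep in seq_len(n_reps)) {
    pos <- if (sim == "coupled")
      cpp_simulate_prolif(params$lambda, params$n0, marks0, times,
                          FALSE)$marks
    else
      asplit(cpp_simulate_walks(params$lambda, marks0, times), 2)
    for (i in seq_along(times)) {
      p <- as.integer(pos[[i]])
      if (length(p) == 0L) next
      m <- max(max(p), length(counts[[i]]))
      if (is.null(counts[[i]])) counts[[i]] <- integer(m)
      else if (length(counts[[i]]) < m)
        counts[[i]] <- c(counts[[i]], integer(m - length(counts[[i]])))
      counts[[i]] <- counts[[i]] + tabulate(p, nbins = m)
    }
  }
  profs <- lapply(seq_along(times), function(i) {
    ct <- counts[[i]]
    sites <- seq.int(params$r + 1L, length(ct))
    phat <- ct[sites] / n_reps
    df <- data.frame(site = sites, occupancy = phat,
                     se = sqrt(phat * (1 - phat) / n_reps))
    new_occupancy_profile(df, times[i], "monte_carlo", params,
                          n_reps = n_reps)
  })
  names(profs) <- format(times)
  if (length(profs) == 1L) profs[[1L]] else profs
}

#' Goodness of fit: inter-agent spacing law
#'
#' Pools the `s - r - 1` spacings between adjacent marked agents across
#' realizations of the chosen simulator and tests them against the
#' geometric law by chi-square (tail bins merged rightward to expected
#' counts >= 5), plus a lag-1 independence chi-square on adjacent spacing
#' pairs (each spacing coarsened to `{1}, {2}, {3+}`).  Under the coupled
#' process both should pass; under independent walkers the spacings are
#' differences of independent processes (possibly nonpositive) and fail
#' detectably — a designed negative control.
#'
#' @inheritParams mc_occupancy
#' @param alpha Test level.
#' @return A `gof_report`; the headline statistic/p-value is the marginal
#'   chi-square, with `independence_statistic` / `independence_p_value`
#'   attached, and the verdict requires both to exceed `alpha`.
#' @export
gof_spacing <- function(params, t, n_reps, seed = NULL, alpha = 0.01,
                        sim = c("coupled", "independent")) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t)
  sim <- match.arg(sim)
  if (params$s - params$r < 2L)
    stop("need at least two marked agents to form spacings", call. = FALSE)
  n_reps <- .check_count(n_reps, "n_reps", min = 2L)
  .maybe_seed(if (is.null(seed)) params$seed else seed)
  sp <- vector("list", n_reps)
  marks0 <- seq.int(params$r + 1L, params$s)
  for (i_rep in seq_len(n_reps)) {
    pos <- if (sim == "coupled")
      as.integer(cpp_simulate_prolif(params$lambda, params$n0, marks0, t,
                                     FALSE)$marks[[1L]])
    else as.integer(cpp_simulate_walks(params$lambda, marks0, t))
    sp[[i_rep]] <- diff(pos)
  }
  pooled <- unlist(sp)
  if (any(pooled < 1)) {
    # spacings outside the geometric support (possible for independent
    # walkers): the law is rejected outright
    marg <- list(statistic = Inf, p_value = 0, n = length(pooled))
  } else {
    marg <- .chisq_vs_pmf(pooled, function(k)
      spacing_pmf(k, t, params$lambda))
  }
  # lag-1 independence on within-realization adjacent pairs
  pair_a <- unlist(lapply(sp, function(z)
    if (length(z) >= 2L) z[-length(z)] else integer(0)))
  pair_b <- unlist(lapply(sp, function(z)
    if (length(z) >= 2L) z[-1L] else integer(0)))
  indep <- list(statistic = NA_real_, p_value = NA_real_)
  if (length(pair_a) >= 50L) {
    cut3 <- function(z) pmin(pmax(z, 1L), 3L)
    ht <- suppressWarnings(chisq.test(table(cut3(pair_a), cut3(pair_b))))
    indep <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  verdict_p <- min(marg$p_value, indep$p_value, na.rm = TRUE)
  report <- new_gof_report(
    sprintf("spacing law (%s simulator)", sim),
    marg$statistic, marg$p_value, length(pooled), alpha, seed,
    params = list(lambda = params$lambda, n0 = params$n0, r = params$r,
                  s = params$s, t = t, n_reps = n_reps, sim = sim),
    extra = list(independence_statistic = indep$statistic,
                 independence_p_value = indep$p_value))
  report$verdict <- verdict_p > alpha
  report
}

#' Goodness of fit: central limit law of the scaled mass
#'
#' Simulates the coupled process under the continuum mapping, forms the
#' scaled mass left of `y` ([mass_statistic()]), standardises it
#' ([clt_standardize()]), and applies a Kolmogorov-Smirnov test against
#' the standard normal distribution.  The normal limit is a
#' spacing-to-zero statement: at coarse spacing the test is expected to
#' fail, which is itself informative.
#'
#' @param cp A [continuum_params()] object.
#' @param y Position in the propagated support.
#' @param t Time (> 0).
#' @inheritParams mc_occupancy
#' @param alpha Test level.
#' @return A `gof_report` with the KS statistic; `mean_z` and `sd_z` of
#'   the standardised sample are attached.
#' @export
gof_clt <- function(cp, y, t, n_reps, seed = NULL, alpha = 0.01) {
  stopifnot(inherits(cp, "continuum_params"))
  n_reps <- .check_count(n_reps, "n_reps", min = 2L)
  .maybe_seed(seed)
  mp <- as_model_params(cp)
  marks0 <- seq.int(mp$r + 1L, mp$s)
  k <- floor(y / cp$delta)
  z <- vapply(seq_len(n_reps), function(i) {
    pos <- cpp_simulate_prolif(mp$lambda, mp$n0, marks0, t, FALSE)$marks[[1L]]
    cp$delta * sum(pos <= k)
  }, numeric(1))
  z <- clt_standardize(cp, y, t, z)
  ht <- suppressWarnings(ks.test(z, "pnorm"))
  new_gof_report(
    "CLT of scaled marked mass", ht$statistic, ht$p.value, n_reps, alpha,
    seed,
    params = list(a = cp$a, b = cp$b, delta = cp$delta,
                  lambda = cp$lambda, y = y, t = t, n_reps = n_reps),
    extra = list(mean_z = mean(z), sd_z = sd(z)))
}

#' Goodness of fit: Yule-Furry marginal law
#'
#' Chi-square of sampled end states (from either path sampler) against
#' the negative-binomial transition law [yule_pmf()], with rightward tail
#' binning to expected counts >= 5.
#'
#' @param t Time.
#' @param lambda Splitting rate.
#' @param start Initial state.
#' @inheritParams mc_occupancy
#' @param alpha Test level.
#' @param sampler `"sequential"` (holding-time view) or `"superposition"`
#'   (site-attached Poisson streams).
#' @return A `gof_report`; `mean_state` and the closed-form mean
#'   `start * exp(lambda * t)` are attached.
#' @export
gof_yule_marginal <- function(t, lambda, start = 1L, n_reps, seed = NULL,
                              alpha = 0.01,
                              sampler = c("sequential", "superposition")) {
  .check_rate(lambda)
  .check_time(t)
  start <- .check_count(start, "start")
  n_reps <- .check_count(n_reps, "n_reps", min = 2L)
  sampler <- match.arg(sampler)
  .maybe_seed(seed)
  ends <- if (sampler == "sequential") {
    as.integer(cpp_simulate_walks(lambda, rep.int(start, n_reps), t))
  } else {
    vapply(seq_len(n_reps), function(i)
      sample_yule_superposition(t, lambda, start)$end_state, integer(1))
  }
  res <- .chisq_vs_pmf(ends, function(k) yule_pmf(k, t, lambda, start),
                       support_min = start)
  new_gof_report(
    sprintf("Yule-Furry marginal (%s sampler)", sampler),
    res$statistic, res$p_value, n_reps, alpha, seed,
    params = list(lambda = lambda, start = start, t = t, n_reps = n_reps,
                  sampler = sampler),
    extra = list(mean_state = mean(ends),
                 mean_exact = start * exp(lambda * t)))
}

#' @importFrom stats sd
NULL
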