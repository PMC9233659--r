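#' Exact expected site occupancy
#'
#' The probability that site `k` holds a marked agent at time `t`.  Because
#' each marked agent moves marginally as a Yule-Furry process from its
#' start site `j` (and the expectation is unaffected by the coupling
#' between agents),
#' \deqn{C_k(t) = \sum_{j=r+1}^{\min(k,s)} \binom{k-1}{k-j}
#'       e^{-j\lambda t}(1 - e^{-\lambda t})^{k-j}.}
#'
#' Two independent evaluation routes are provided and are required to
#' agree (the package's main defence against silent numerical error at
#' continuum scales, where `k` reaches 10^5):
#' \describe{
#'   \item{`"series"`}{the defining sum, each term through
#'     [stats::dnbinom()] in log space, accumulated by log-sum-exp;}
#'   \item{`"binomial"`}{the closed form
#'     \eqn{e^{-\lambda t}\Pr(r \le B \le \min(s,k)-1)} with
#'     \eqn{B \sim \mathrm{Binomial}(k-1, e^{-\lambda t})}, via stable
#'     binomial-CDF differences.}
#' }
#'
#' @param params A [model_params()] object.
#' @param k Site index (vectorised).
#' @param t Time.
#' @param method `"binomial"` (default; O(1) per site) or `"series"`.
#' @return Values in `[0, 1]`; 0 for `k <= r`.
#' @examples
#' p <- model_params(0.69, 18, 11, 18)
#' expected_occupancy(p, 20, t = 1)
#' @export
expected_occupancy <- function(params, k, t,
                               method = c("binomial", "series")) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t)
  method <- match.arg(method)
  k <- floor(k)
  r <- params$r; s <- params$s; lambda <- params$lambda
  p <- exp(-lambda * t)
  out <- numeric(length(k))
  ok <- k > r & k >= 1
  if (!any(ok)) return(out)
  kk <- k[ok]
  if (method == "binomial") {
    val <- p * (pbinom(pmin(s, kk) - 1, kk - 1, p) - pbinom(r - 1, kk - 1, p))
    out[ok] <- pmax(0, val)
  } else {
    out[ok] <- vapply(kk, function(ki) {
      j <- seq.int(r + 1, min(ki, s))
      if (length(j) == 0L) return(0)
      exp(.logsumexp(dnbinom(ki - j, size = j, prob = p, log = TRUE)))
    }, numeric(1))
  }
  pmin(out, 1)
}

#' Occupancy variance
#'
#' Site occupancy is a 0/1 indicator, so its variance is
#' `C_k(t) * (1 - C_k(t))`.
#'
#' @inheritParams expected_occupancy
#' @export
occupancy_variance <- function(params, k, t) {
  ck <- expected_occupancy(params, k, t)
  ck * (1 - ck)
}

#' Inter-agent spacing law
#'
#' Under the coupled proliferation process the gaps between *adjacent
#' marked agents* at time `t` are independent and identically geometric on
#' `{1, 2, ...}`:
#' \deqn{\Pr(Z = k) = e^{-\lambda t}(1 - e^{-\lambda t})^{k-1},}
#' so \eqn{\Pr(Z > m) = (1 - e^{-\lambda t})^m}.  Note the support starts
#' at 1 (adjacent agents are at least one site apart); [stats::dgeom()]'s
#' count-of-failures convention is shifted accordingly.  Values `k < 1`
#' return 0 by convention.
#'
#' @param k Spacing value (integer >= 1; vectorised).
#' @param m Threshold (integer >= 0; vectorised).
#' @param t Time (> 0 for a nondegenerate law).
#' @param lambda Splitting rate.
#' @return Probabilities.
#' @examples
#' spacing_pmf(1, t = 1, lambda = 0.69)  # exp(-0.69)
#' @export
spacing_pmf <- function(k, t, lambda) {
  .check_rate(lambda)
  .check_time(t)
  p <- exp(-lambda * t)
  out <- numeric(length(k))
  ok <- k >= 1 & k == floor(k)
  out[ok] <- dgeom(k[ok] - 1, p)
  out
}

#' @rdname spacing_pmf
#' @export
spacing_survival <- function(m, t, lambda) {
  .check_rate(lambda)
  .check_time(t)
  if (any(m < 0)) stop("`m` must be nonnegative", call. = FALSE)
  (-expm1(-lambda * t))^floor(m)
}

#' Gauss hypergeometric series 2F1(a, 1; c; z)
#'
#' Direct series evaluation of \eqn{{}_2F_1(a, 1; c; z) = \sum_{n \ge 0}
#' \frac{(a)_n}{(c)_n} z^n} by term-ratio recursion
#' (`term * (a+n)/(c+n) * z`), stopping when a term falls below
#' `1e-16` times the partial sum.  Convergence is geometric at rate `z`
#' once `n` dominates `a - c`, but slows as `a z / c` approaches 1;
#' exceeding `max_iter` is an explicit error, never a silent truncation.
#'
#' @param a,c Parameters; `c` must not be a nonpositive integer.
#' @param z Argument in `[0, 1)`.
#' @param max_iter Iteration budget.
#' @return The (scalar) series value.
#' @examples
#' hyp2f1_b1(5, 5, 0.4)  # = 1 / (1 - 0.4)
#' @export
hyp2f1_b1 <- function(a, c, z, max_iter = 1e6) {
  stopifnot(length(a) == 1L, length(c) == 1L, length(z) == 1L)
  if (c <= 0 && c == floor(c))
    stop("`c` must not be a nonpositive integer", call. = FALSE)
  if (z < 0 || z >= 1)
    stop("`z` must lie in [0, 1)", call. = FALSE)
  if (z == 0) return(1)
  term <- 1
  acc <- 1
  for (n in 0:max_iter) {
    term <- term * (a + n) / (c + n) * z
    acc <- acc + term
    if (abs(term) < 1e-16 * abs(acc)) return(acc)
  }
  stop("hyp2f1_b1: series did not converge within `max_iter` terms",
       call. = FALSE)
}

#' Distribution of the marked mass left of a site
#'
#' `M_k(t)` counts the marked agents at sites `r+1..k`.  For
#' \eqn{r \le j < s} and `k > j`,
#' \deqn{\Pr(M_k(t) \le j - r) = \binom{k}{j} e^{-(j+1)\lambda t}
#'   (1-e^{-\lambda t})^{k-j}\, {}_2F_1(k+1, 1; k-j+1; 1-e^{-\lambda t}),}
#' and 1 when `k <= j` (or `j >= s`, since there are only `s - r` marks).
#' Equivalently, the event is that the `(j-r+1)`-st marked agent — whose
#' start site is `j + 1` and whose marginal law is Yule-Furry — has not yet
#' reached site `k`:
#' \deqn{\Pr(M_k(t) \le j - r) = \Pr(Y(t) > k \mid Y(0) = j+1).}
#' Both routes are computed by default and must agree to `1e-10`
#' (`method = "both"`); a disagreement is an error, never silently
#' reconciled.
#'
#' The hypergeometric form is often printed with prefactor
#' \eqn{e^{-j\lambda t}}; that normalisation exceeds 1 (term-by-term the
#' series sums to \eqn{\Pr(Y(t) > k \mid Y(0)=j+1) e^{\lambda t}}), so the
#' extra factor \eqn{e^{-\lambda t}} used here is required for a proper
#' distribution, as the renewal route and simulation confirm.
#'
#' @inheritParams expected_occupancy
#' @param j Level, `j >= r` (scalar).  `j = r` queries
#'   \eqn{\Pr(M_k(t) \le 0)}.
#' @param k Site, `k > r` (scalar).
#' @param method `"both"` (dual-route with cross-check), `"series"`, or
#'   `"renewal"`.
#' @return \eqn{\Pr(M_k(t) \le j - r)}.
#' @examples
#' p <- model_params(0.69, 18, 11, 18)
#' marked_count_cdf(p, k = 40, j = 14, t = 2)
#' @export
marked_count_cdf <- function(params, k, j, t,
                             method = c("both", "series", "renewal")) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t)
  method <- match.arg(method)
  k <- .check_count(k, "k")
  j <- .check_count(j, "j", min = 0L)
  r <- params$r; s <- params$s; lambda <- params$lambda
  if (j < r) stop("`j` must be at least `r`", call. = FALSE)
  if (k <= r) stop("`k` must exceed `r`", call. = FALSE)
  if (k <= j || j >= s) return(1)
  p <- exp(-lambda * t)
  renewal <- function()
    pnbinom(k - (j + 1), size = j + 1, prob = p, lower.tail = FALSE)
  series <- function() {
    if (t == 0) return(0)  # all marks still at their start sites
    q <- -expm1(-lambda * t)
    lpref <- lchoose(k, j) - (j + 1) * lambda * t +
      (k - j) * .log1mexp(lambda * t)
    exp(lpref + log(hyp2f1_b1(k + 1, k - j + 1, q)))
  }
  switch(method,
    renewal = renewal(),
    series = series(),
    both = {
      a <- series(); b <- renewal()
      if (abs(a - b) > 1e-10)
        stop(sprintf(
          "marked_count_cdf: series (%.15g) and renewal (%.15g) routes disagree",
          a, b), call. = FALSE)
      b
    })
}

#' Expected domain length
#'
#' With `L(t) = delta * N(t)`, the expected length satisfies
#' `dE[L]/dt = lambda E[L]`, so `E[L(t)] = L0 * exp(lambda * t)`.
#'
#' @param L0 Initial length (> 0).
#' @param t Time.
#' @param lambda Splitting rate.
#' @export
expected_length <- function(L0, t, lambda) {
  .check_rate(lambda)
  .check_time(t)
  if (any(L0 <= 0)) stop("`L0` must be positive", call. = FALSE)
  L0 * exp(lambda * t)
}

new_occupancy_profile <- function(df, time, source, params,
                                  n_reps = NULL) {
  structure(df, class = c("occupancy_profile", "data.frame"),
            time = time, source = source, params = params, n_reps = n_reps)
}

#' Exact occupancy profile over a site range
#'
#' Vectorised assembly of [expected_occupancy()] and
#' [occupancy_variance()].  With `sites = NULL` the range auto-extends
#' from site `r+1` until the truncated tail mass (bounded by the rightmost
#' agent's Yule-Furry survival) is below `1e-10`, so the profile carries
#' essentially the whole conserved mass `s - r`.
#'
#' @inheritParams expected_occupancy
#' @param sites Integer site range, or `NULL` for the full range.
#' @return An `occupancy_profile`: data frame with columns `site`,
#'   `occupancy`, `variance`; attributes `time`, `source = "exact"`,
#'   `params`.
#' @examples
#' pr <- occupancy_profile(model_params(0.69, 18, 11, 18), t = 1)
#' sum(pr$occupancy)  # ~ 7, the number of marked agents
#' @export
occupancy_profile <- function(params, t, sites = NULL,
                              method = c("binomial", "series")) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t)
  method <- match.arg(method)
  r <- params$r; s <- params$s
  if (s == r) {
    df <- data.frame(site = integer(0), occupancy = numeric(0),
                     variance = numeric(0))
    return(new_occupancy_profile(df, t, "exact", params))
  }
  if (is.null(sites)) {
    p <- exp(-params$lambda * t)
    # tail mass beyond K is at most (s - r) * Pr(Y_s > K)
    kmax <- s + qnbinom(1e-12 / (s - r), size = s, prob = p,
                        lower.tail = FALSE) + 1L
    sites <- seq.int(r + 1L, kmax)
  } else {
    sites <- as.integer(sites)
  }
  ck <- expected_occupancy(params, sites, t, method = method)
  df <- data.frame(site = sites, occupancy = ck, variance = ck * (1 - ck))
  new_occupancy_profile(df, t, "exact", params)
}

#' @export
print.occupancy_profile <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("Occupancy profile (%s) at t = %g: %d sites, mass %.6f\n",
              src, attr(x, "time"), nrow(x), sum(x$occupancy)))
  if (identical(src, "monte_carlo"))
    cat(sprintf("  %d realizations\n", attr(x, "n_reps")))
  invisible(x)
}

#' @export
plot.occupancy_profile <- function(x, ...) {
  plot(x$site, x$occupancy, type = "s", xlab = "site k",
       ylab = expression(C[k](t)), ...)
  invisible(x)
}

#' Splitting-rate estimate from observed spacings
#'
#' Maximum-likelihood fit of the geometric spacing law: with success
#' parameter \eqn{p = e^{-\lambda t}} and spacings supported on
#' `{1, 2, ...}`, the MLE is \eqn{\hat p = 1/\bar Z}, giving
#' \eqn{\hat\lambda = -\log(\hat p)/t}.
#'
#' @param spacings Observed gaps between adjacent marked agents (>= 1).
#' @param t Observation time (> 0).
#' @return The estimate \eqn{\hat\lambda}.
#' @export
fit_spacing_rate <- function(spacings, t) {
  .check_time(t)
  if (t == 0) stop("`t` must be positive", call. = FALSE)
  if (length(spacings) == 0L || any(spacings < 1))
    stop("`spacings` must be a nonempty vector of values >= 1",
         call. = FALSE)
  p_hat <- 1 / mean(spacings)
  -log(p_hat) / t
}
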