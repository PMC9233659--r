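#' Yule-Furry transition probabilities
#'
#' A Yule-Furry (pure linear birth) process with splitting rate `lambda`
#' jumps from state `k` to `k + 1` at rate `lambda * k`.  Started in state
#' `j` at time 0, its position at time `t` is negative-binomially
#' distributed: the probability of being in state `k >= j` is
#' \deqn{p_{jk}(t) = \binom{k-1}{k-j} e^{-j\lambda t}
#'       (1 - e^{-\lambda t})^{k-j},}
#' and 0 for `k < j`.  Evaluation goes through [stats::dnbinom()] /
#' [stats::pnbinom()], i.e. log-gamma arithmetic and the regularized
#' incomplete beta function, so both functions are accurate for `k` well
#' beyond 10^6 (needed when continuum experiments map positions to site
#' indices of order `1/delta`).
#'
#' @param k Integer site index (vectorised).
#' @param t Time (single nonnegative number).
#' @param lambda Splitting rate, per unit time (> 0).
#' @param start Initial state `j >= 1`.
#' @return `yule_pmf` returns \eqn{\Pr(Y(t) = k)}; `yule_cdf` returns
#'   \eqn{\Pr(Y(t) \le k)}.
#' @examples
#' yule_pmf(3, t = 1, lambda = 0.69, start = 2)
#' yule_cdf(10, t = 1, lambda = 0.69)
#' @export
yule_pmf <- function(k, t, lambda, start = 1L) {
  .check_rate(lambda)
  .check_time(t)
  start <- .check_count(start, "start")
  out <- numeric(length(k))
  ok <- k >= start & k == floor(k)
  if (any(ok))
    out[ok] <- dnbinom(k[ok] - start, size = start, prob = exp(-lambda * t))
  out
}

#' @rdname yule_pmf
#' @export
yule_cdf <- function(k, t, lambda, start = 1L) {
  .check_rate(lambda)
  .check_time(t)
  start <- .check_count(start, "start")
  out <- numeric(length(k))
  ok <- k >= start
  if (any(ok))
    out[ok] <- pnbinom(floor(k[ok]) - start, size = start,
                       prob = exp(-lambda * t))
  out
}

new_yule_path <- function(jump_times, end_time, start, lambda, method) {
  structure(
    list(jump_times = jump_times, end_time = end_time,
         end_state = start + length(jump_times),
         start = start, lambda = lambda, method = method),
    class = "yule_path")
}

#' Sample a Yule-Furry path
#'
#' Two distributionally equivalent samplers for the full path of a
#' Yule-Furry process up to a horizon.
#'
#' `sample_yule_sequential()` uses the holding-time view: in state `k` the
#' process waits an Exp(`lambda * k`) time, then jumps to `k + 1`.
#'
#' `sample_yule_superposition()` uses the site-attached Poisson-stream view:
#' an independent rate-`lambda` Poisson stream sits at every integer site,
#' and the particle at position `k` jumps at any event in a stream with
#' index `<= k`.  Streams are instantiated lazily as the particle climbs
#' (stream `k` is realised from the moment the particle first reaches `k`,
#' which by memorylessness gives the correct law), so the unbounded site
#' index costs nothing.  Coupling many walkers through *shared* streams is
#' exactly the proliferation process; see [simulate_proliferation()].
#'
#' @param t_end Horizon (>= 0).
#' @param lambda Splitting rate (> 0).
#' @param start Initial state (>= 1).
#' @param seed Optional integer seed, applied via [set.seed()].
#' @return A `yule_path`: list with `jump_times` (strictly increasing times
#'   at which the state increments), `end_time`, `end_state`, `start`,
#'   `lambda`, `method`.
#' @examples
#' p <- sample_yule_sequential(2, lambda = 0.69, seed = 1)
#' p$end_state == p$start + length(p$jump_times)
#' @export
sample_yule_sequential <- function(t_end, lambda, start = 1L, seed = NULL) {
  .check_rate(lambda)
  .check_time(t_end, "t_end")
  start <- .check_count(start, "start")
  .maybe_seed(seed)
  t <- 0
  k <- start
  jumps <- numeric(0)
  repeat {
    t_next <- t + rexp(1L, lambda * k)
    if (t_next > t_end) break
    t <- t_next
    k <- k + 1L
    jumps <- c(jumps, t)
  }
  new_yule_path(jumps, t_end, start, lambda, "sequential")
}

#' @rdname sample_yule_sequential
#' @export
sample_yule_superposition <- function(t_end, lambda, start = 1L, seed = NULL) {
  .check_rate(lambda)
  .check_time(t_end, "t_end")
  start <- .check_count(start, "start")
  .maybe_seed(seed)
  k <- start
  # next event time of each active stream 1..k (streams live from time 0)
  nxt <- rexp(start, lambda)
  jumps <- numeric(0)
  repeat {
    i <- which.min(nxt)
    tj <- nxt[i]
    if (tj > t_end) break
    k <- k + 1L
    jumps <- c(jumps, tj)
    nxt[i] <- tj + rexp(1L, lambda)
    nxt <- c(nxt, tj + rexp(1L, lambda))  # stream k, realised lazily
  }
  new_yule_path(jumps, t_end, start, lambda, "superposition")
}

#' Draw Yule-Furry end states
#'
#' Convenience sampler for the marginal position at a fixed time: `n`
#' independent sequential paths, returning only the final states.
#'
#' @param n Number of draws.
#' @param t Time.
#' @inheritParams sample_yule_sequential
#' @return Integer vector of length `n`.
#' @examples
#' mean(ryule(500, t = 1, lambda = 0.69, seed = 1))  # near exp(0.69)
#' @export
ryule <- function(n, t, lambda, start = 1L, seed = NULL) {
  .check_rate(lambda)
  .check_time(t)
  start <- .check_count(start, "start")
  n <- .check_count(n, "n")
  .maybe_seed(seed)
  if (t == 0) return(rep.int(start, n))
  as.integer(cpp_simulate_walks(lambda, rep.int(start, n), t))
}

#' @export
print.yule_path <- function(x, ...) {
  cat(sprintf(
    "Yule-Furry path (%s sampler): start %d -> state %d at t = %g (%d jumps)\n",
    x$method, x$start, x$end_state, x$end_time, length(x$jump_times)))
  invisible(x)
}
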