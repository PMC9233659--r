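#' Continuum parameterisation
#'
#' The continuum view places an initial particle mass on the interval
#' `(a, b]`: with lattice spacing `delta`, the marked sites are
#' `floor(a/delta) + 1, ..., floor(b/delta)` and a position `y` maps to
#' site `k = floor(y/delta)`.  The floor-mapped site bounds are normative;
#' when `floor(b/delta) - floor(a/delta)` differs (by one, for awkward
#' `delta`) from `floor((b-a)/delta)`, the floors win, because the
#' occupancy formulas are stated in terms of them.
#'
#' @param a,b Interval endpoints, `0 < a < b`.
#' @param delta Lattice spacing (> 0).
#' @param lambda Splitting rate (> 0).
#' @return A `continuum_params` object.
#' @examples
#' cp <- continuum_params(12, 18, delta = 0.1, lambda = 0.69)
#' as_model_params(cp)
#' @export
continuum_params <- function(a, b, delta, lambda) {
  .check_rate(lambda)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > a,
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            delta > 0)
  structure(list(a = a, b = b, delta = delta, lambda = lambda),
            class = "continuum_params")
}

#' @export
print.continuum_params <- function(x, ...) {
  mp <- as_model_params(x)
  cat(sprintf(
    "Continuum setup: mass on (%g, %g], delta = %g, lambda = %g\n",
    x$a, x$b, x$delta, x$lambda))
  cat(sprintf("  lattice mapping: marked sites %d..%d (%d agents)\n",
              mp$r + 1L, mp$s, mp$s - mp$r))
  invisible(x)
}

#' @rdname continuum_params
#' @param cp A `continuum_params` object.
#' @return `as_model_params()` returns the corresponding [model_params()]
#'   with `r` \eqn{= \lfloor a/\delta\rfloor}, `s`
#'   \eqn{= \lfloor b/\delta\rfloor} and `n0 = s`.
#' @export
as_model_params <- function(cp) {
  stopifnot(inherits(cp, "continuum_params"))
  r <- floor(cp$a / cp$delta)
  s <- floor(cp$b / cp$delta)
  model_params(cp$lambda, n0 = s, r = r, s = s)
}

.ksite <- function(cp, y) {
  if (any(y <= 0)) stop("`y` must be positive", call. = FALSE)
  floor(y / cp$delta)
}

#' Discrete occupancy profile at a continuum position
#'
#' `continuum_occupancy()` evaluates the expected rectangle height
#' `C_delta(y, t)` — the expected occupancy of site `floor(y/delta)` —
#' by delegating to [expected_occupancy()] under the floor mapping
#' (`"series"` route by default, so that comparison with the binomial form
#' is a genuinely independent cross-check).  It is piecewise constant in
#' `y` with breakpoints at multiples of `delta`.
#'
#' `continuum_occupancy_binomial()` evaluates the equivalent closed form
#' \deqn{C_\Delta(y,t) = e^{-\lambda t}\,\Pr(\lfloor a/\Delta\rfloor \le S
#'   \le \min(\lfloor b/\Delta\rfloor, \lfloor y/\Delta\rfloor) - 1),}
#' with \eqn{S \sim \mathrm{Binomial}(\lfloor y/\Delta\rfloor - 1,
#' e^{-\lambda t})}, via stable binomial-CDF differences.
#'
#' @param cp A [continuum_params()] object.
#' @param y Position (> 0; vectorised).
#' @param t Time.
#' @param method Evaluation route passed to [expected_occupancy()].
#' @return Values in `[0, 1]`.
#' @export
continuum_occupancy <- function(cp, y, t, method = c("series", "binomial")) {
  stopifnot(inherits(cp, "continuum_params"))
  method <- match.arg(method)
  expected_occupancy(as_model_params(cp), .ksite(cp, y), t, method = method)
}

#' @rdname continuum_occupancy
#' @export
continuum_occupancy_binomial <- function(cp, y, t) {
  stopifnot(inherits(cp, "continuum_params"))
  .check_time(t)
  k <- .ksite(cp, y)
  r <- floor(cp$a / cp$delta)
  s <- floor(cp$b / cp$delta)
  p <- exp(-cp$lambda * t)
  hi <- pmin(s, k) - 1
  out <- numeric(length(k))
  ok <- hi >= r & k >= 1
  if (any(ok))
    out[ok] <- p * (pbinom(hi[ok], k[ok] - 1, p) -
                      pbinom(r - 1, k[ok] - 1, p))
  pmin(pmax(out, 0), 1)
}

#' Normal approximation to the discrete profile
#'
#' Applying the normal approximation to the binomial variable in the
#' closed-form profile gives
#' \deqn{C_\Delta(y,t) \approx e^{-\lambda t}\left[\Phi(u_+) -
#'   \Phi(u_-)\right],}
#' with
#' \eqn{u_- = \frac{a/y - e^{-\lambda t}}{\sqrt{e^{-\lambda t}
#' (1-e^{-\lambda t})}}\sqrt{\lfloor y/\Delta\rfloor - 1}} and \eqn{u_+}
#' the same with `min(b/y, 1)` in place of `a/y`.  The default follows
#' this formula literally, with no continuity correction; set
#' `correction = TRUE` for a half-integer-corrected variant (exact
#' binomial standardisation with `+/- 0.5` on the site bounds), provided
#' for investigation only.
#'
#' @inheritParams continuum_occupancy
#' @param correction Apply a continuity correction? Default `FALSE`.
#' @export
normal_approx <- function(cp, y, t, correction = FALSE) {
  stopifnot(inherits(cp, "continuum_params"))
  .check_time(t)
  if (t == 0) stop("`t` must be positive", call. = FALSE)
  k <- .ksite(cp, y)
  p <- exp(-cp$lambda * t)
  sd0 <- sqrt(p * (1 - p))
  if (correction) {
    r <- floor(cp$a / cp$delta)
    s <- floor(cp$b / cp$delta)
    mu <- (k - 1) * p
    sg <- sqrt((k - 1)) * sd0
    u_lo <- (r - 0.5 - mu) / sg
    u_hi <- (pmin(s, k) - 0.5 - mu) / sg
  } else {
    fac <- sqrt(k - 1)
    u_lo <- (cp$a / y - p) / sd0 * fac
    u_hi <- (pmin(cp$b / y, 1) - p) / sd0 * fac
  }
  pmax(0, p * (pnorm(u_hi) - pnorm(u_lo)))
}

#' Limiting occupancy profile
#'
#' As the spacing shrinks to zero the profile tends to a square wave of
#' height \eqn{e^{-\lambda t}} on \eqn{(a e^{\lambda t}, b e^{\lambda t})},
#' taking half that height exactly at the two endpoints and 0 outside.
#' Membership of a breakpoint is decided up to a relative tolerance of
#' `1e-12` (the half-height cases are analytically exact but
#' float-fragile).  The profile integrates to `b - a` for every `t` and is
#' a weak solution of the first-order transport equation; see
#' [transport_solution()].
#'
#' @param y Position (> 0; vectorised).
#' @param t Time (> 0).
#' @param a,b Initial interval, `0 < a < b`.
#' @param lambda Splitting rate.
#' @export
limiting_profile <- function(y, t, a, b, lambda) {
  .check_rate(lambda)
  .check_time(t)
  if (any(y <= 0)) stop("`y` must be positive", call. = FALSE)
  h <- exp(-lambda * t)
  lo <- a * exp(lambda * t)
  hi <- b * exp(lambda * t)
  tol <- 1e-12 * pmax(1, y)
  out <- numeric(length(y))
  out[y > lo & y < hi] <- h
  out[abs(y - lo) <= tol | abs(y - hi) <= tol] <- h / 2
  out
}

#' Scaled marked mass left of a position
#'
#' The mass statistic `M_delta(y, t) = delta * M_k(t)` with
#' `k = floor(y/delta)`: the lattice spacing times the number of marked
#' agents at or left of site `k` in a simulated state.  As `delta` shrinks
#' it obeys a law of large numbers (point mass at
#' \eqn{y e^{-\lambda t} - a} for `y` inside the propagated support) and a
#' central limit theorem; see [clt_standardize()].
#'
#' @param cp A [continuum_params()] object.
#' @param y Position, `y > a`.
#' @param state A `lattice_state` (from [simulate_proliferation()]) or
#'   `walk_state`.
#' @return The mass value `delta * #\{marked positions <= floor(y/delta)\}`.
#' @export
mass_statistic <- function(cp, y, state) {
  stopifnot(inherits(cp, "continuum_params"))
  if (any(y <= cp$a)) stop("`y` must exceed `a`", call. = FALSE)
  pos <- if (inherits(state, "lattice_state")) state$marked_positions
         else state$positions
  vapply(y, function(yy) cp$delta * sum(pos <= floor(yy / cp$delta)),
         numeric(1))
}

#' Central-limit standardisation of the scaled mass
#'
#' For `y` in the propagated support \eqn{(a e^{\lambda t},
#' b e^{\lambda t}]}, the standardised mass
#' \deqn{\frac{M_\Delta(y,t) - \Delta(\lfloor y e^{-\lambda t}/\Delta
#'   \rfloor - \lfloor a/\Delta\rfloor)}{\Delta\sqrt{(e^{-\lambda t} -
#'   e^{-2\lambda t})\lfloor y/\Delta\rfloor}}}
#' converges in law to standard normal as the spacing shrinks.  This
#' helper applies exactly that centering and scaling.
#'
#' @inheritParams mass_statistic
#' @param t Time (> 0).
#' @param mass Mass value(s) from [mass_statistic()] (vectorised).
#' @return z-score(s).
#' @export
clt_standardize <- function(cp, y, t, mass) {
  stopifnot(inherits(cp, "continuum_params"))
  .check_time(t)
  if (t == 0) stop("`t` must be positive", call. = FALSE)
  if (length(y) != 1L) stop("`y` must be a single position", call. = FALSE)
  p <- exp(-cp$lambda * t)
  if (y <= cp$a / p || y > cp$b / p)
    stop("`y` must lie in (a*exp(lambda*t), b*exp(lambda*t)]",
         call. = FALSE)
  d <- cp$delta
  centre <- d * (floor(y * p / d) - floor(cp$a / d))
  scale <- d * sqrt((p - p^2) * floor(y / d))
  (mass - centre) / scale
}
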