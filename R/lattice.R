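#' Model parameters for the proliferation process
#'
#' Configuration of the discrete lattice model: agents occupy sites
#' `1..n0`; the contiguous block of sites `r+1, ..., s` carries marked
#' agents (`s - r` of them), all others are unmarked.  Proliferation events
#' arrive at total rate `lambda * N(t)` with the event site uniform on the
#' occupied sites; an unmarked agent is inserted at the site and every
#' agent at or right of it shifts one place up.  Marks are conserved:
#' events move them, never create or destroy them.
#'
#' @param lambda Splitting rate per agent (> 0).
#' @param n0 Initial number of agents `N(0) >= 1`.
#' @param r,s Marked block bounds: marked sites are `r+1..s`, with
#'   \eqn{0 \le r \le s \le n_0}.  Equal `r` and `s` give a valid
#'   empty-mark model.
#' @param seed Optional integer; default seed used by the simulators when
#'   their own `seed` argument is left `NULL`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(lambda = 0.69, n0 = 118, r = 11, s = 118)  # 107 marks
#' @export
model_params <- function(lambda, n0, r, s, seed = NULL) {
  .check_rate(lambda)
  n0 <- .check_count(n0, "n0")
  r <- .check_count(r, "r", min = 0L)
  s <- .check_count(s, "s", min = 0L)
  if (r > s) stop("`r` must not exceed `s`", call. = FALSE)
  if (s > n0) stop("`s` must not exceed `n0`", call. = FALSE)
  if (!is.null(seed)) seed <- .check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(lambda = lambda, n0 = n0, r = r, s = s, seed = seed),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Proliferation model: lambda = %g, N(0) = %d, %d marked agents at sites %s\n",
    x$lambda, x$n0, x$s - x$r,
    if (x$s > x$r) sprintf("%d..%d", x$r + 1L, x$s) else "(none)"))
  invisible(x)
}

new_lattice_state <- function(time, n_agents, marked_positions) {
  structure(list(time = time, n_agents = n_agents,
                 marked_positions = as.integer(marked_positions)),
            class = "lattice_state")
}

#' Initial lattice state
#'
#' @param params A [model_params()] object.
#' @return A `lattice_state`: list with `time = 0`, `n_agents = n0` and
#'   `marked_positions = (r+1, ..., s)` (strictly increasing).
#' @examples
#' st <- make_initial_state(model_params(0.69, n0 = 11, r = 3, s = 8))
#' st$marked_positions  # sites 4..8
#' @export
make_initial_state <- function(params) {
  stopifnot(inherits(params, "model_params"))
  marks <- if (params$s > params$r)
    seq.int(params$r + 1L, params$s) else integer(0)
  new_lattice_state(0, params$n0, marks)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("Lattice state at t = %g: N = %d, %d marked agents\n",
              x$time, x$n_agents, length(x$marked_positions)))
  invisible(x)
}

#' Apply one proliferation event
#'
#' Inserts an unmarked agent at `site`: the agent count increments and
#' every marked position `p >= site` becomes `p + 1`; positions left of the
#' site are untouched.
#'
#' @param state A `lattice_state`.
#' @param site Event site, in `1..state$n_agents`.
#' @param time Optional event time recorded on the returned state
#'   (defaults to the state's current time).
#' @return The updated `lattice_state`.
#' @examples
#' st <- make_initial_state(model_params(0.69, 11, 3, 8))
#' apply_event(st, 8)$marked_positions  # 4 5 6 7 9
#' @export
apply_event <- function(state, site, time = state$time) {
  stopifnot(inherits(state, "lattice_state"))
  site <- .check_count(site, "site")
  if (site > state$n_agents)
    stop("`site` exceeds the current number of agents", call. = FALSE)
  marks <- state$marked_positions
  shift <- marks >= site
  marks[shift] <- marks[shift] + 1L
  new_lattice_state(time, state$n_agents + 1L, marks)
}

#' Marked-occupancy indicator
#'
#' @param state A `lattice_state`.
#' @param k Site index (vectorised).
#' @return 0/1 integer vector: 1 where site `k` holds a marked agent.
#' @export
occupancy_indicator <- function(state, k) {
  stopifnot(inherits(state, "lattice_state"))
  as.integer(k %in% state$marked_positions)
}

.snap_times <- function(t_end, snapshots) {
  if (is.null(snapshots)) snapshots <- t_end
  snapshots <- sort(unique(as.numeric(snapshots)))
  .check_time(snapshots, "snapshots")
  if (length(snapshots) == 0L || max(snapshots) != t_end)
    snapshots <- c(snapshots, t_end)
  snapshots
}

#' Simulate the proliferation process
#'
#' Exact event-driven (Gillespie) dynamics: waiting times are
#' Exp(`lambda * N`), the event site is uniform on the occupied sites, and
#' [apply_event()] semantics govern the state change.  Events with time
#' `<= t_end` are applied (half-open horizon convention).  The event log is
#' complete and replayable: pushing it back through [apply_event()]
#' reproduces the final state exactly.
#'
#' The state kept (and returned) is the marked-position vector plus the
#' agent count, not the full 0/1 site vector: every observable of interest
#' is a function of these, and memory stays proportional to the number of
#' marks while `N(t)` grows like `e^(lambda t)`.
#'
#' @param params A [model_params()] object.
#' @param t_end Horizon (>= 0).
#' @param seed Optional integer seed (falls back to `params$seed`).
#' @param snapshots Optional times at which intermediate states are
#'   recorded; the horizon is always included.
#' @param events Keep the event log? (Set `FALSE` for large Monte-Carlo
#'   loops.)
#' @return List with `state` (the final `lattice_state`), `states` (one
#'   `lattice_state` per snapshot time) and, when `events = TRUE`,
#'   `events`: a data frame with columns `index`, `time`, `site`,
#'   `n_after`.
#' @examples
#' sim <- simulate_proliferation(model_params(0.69, 6, 0, 6), 1, seed = 1)
#' sim$state$n_agents == 6 + nrow(sim$events)
#' @export
simulate_proliferation <- function(params, t_end, seed = NULL,
                                   snapshots = NULL, events = TRUE) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t_end, "t_end")
  .maybe_seed(if (is.null(seed)) params$seed else seed)
  times <- .snap_times(t_end, snapshots)
  marks0 <- if (params$s > params$r)
    seq.int(params$r + 1L, params$s) else integer(0)
  raw <- cpp_simulate_prolif(params$lambda, params$n0, marks0, times,
                             isTRUE(events))
  states <- lapply(seq_along(times), function(i)
    new_lattice_state(times[i], raw$n[i], raw$marks[[i]]))
  names(states) <- format(times)
  out <- list(state = states[[length(states)]], states = states)
  if (isTRUE(events)) out$events <- raw$events
  out
}

#' Simulate independent Yule-Furry walkers
#'
#' The uncoupled comparison model: each marked agent evolves as an
#' *independent* Yule-Furry process from its start site (holding time
#' Exp(`lambda * position`)).  Marginally each walker has the same law as
#' in the coupled proliferation process, so per-site expected occupancy
#' agrees; jointly the laws differ (walkers may collide or swap order, and
#' inter-walker spacings are not independent geometric).  Positions are
#' returned in walker order and are not guaranteed distinct or sorted.
#'
#' @inheritParams simulate_proliferation
#' @return List with `positions` (integer vector, one per marked agent, at
#'   `t_end`), `states` (a list with one positions vector per snapshot
#'   time), `starts` and `time`.
#' @export
simulate_independent_walks <- function(params, t_end, seed = NULL,
                                       snapshots = NULL) {
  stopifnot(inherits(params, "model_params"))
  .check_time(t_end, "t_end")
  .maybe_seed(if (is.null(seed)) params$seed else seed)
  times <- .snap_times(t_end, snapshots)
  starts <- if (params$s > params$r)
    seq.int(params$r + 1L, params$s) else integer(0)
  pos <- cpp_simulate_walks(params$lambda, starts, times)
  states <- lapply(seq_along(times), function(i) pos[, i])
  names(states) <- format(times)
  structure(list(positions = states[[length(states)]], states = states,
                 starts = starts, time = t_end),
            class = "walk_state")
}

#' @export
print.walk_state <- function(x, ...) {
  cat(sprintf("Independent walkers at t = %g: %d marked agents\n",
              x$time, length(x$positions)))
  invisible(x)
}
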