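#' Read and write event logs
#'
#' Event logs are CSV files with the fixed schema
#' `index,time,site,n_after` (one row per proliferation event, times
#' strictly increasing).  Round-trips are lossless at full double
#' precision.
#'
#' @param events Event-log data frame (as returned by
#'   [simulate_proliferation()]).
#' @param path File path.
#' @return `read_event_log()` returns the data frame.
#' @export
write_event_log <- function(events, path) {
  stopifnot(is.data.frame(events),
            identical(names(events), c("index", "time", "site", "n_after")))
  write.csv(format(events, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- read.csv(path, colClasses = c(index = "integer", time = "numeric",
                                      site = "integer",
                                      n_after = "integer"))
  if (!identical(names(df), c("index", "time", "site", "n_after")))
    stop("not an event-log CSV", call. = FALSE)
  df
}

#' Read and write occupancy profiles
#'
#' Profiles serialize to CSV with schema `site,c_exact,variance` (exact
#' profiles) or `site,c_mc,se` (Monte-Carlo profiles); which one applies
#' is recorded by the column names and restored on read.
#'
#' @param profile An `occupancy_profile`.
#' @param path File path.
#' @return `read_profile()` returns the `occupancy_profile` (the `time`
#'   attribute is not stored in the CSV and comes back as `NA`unless
#'   supplied).
#' @param time Evaluation time to attach on read (optional).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "occupancy_profile"))
  df <- as.data.frame(profile)
  if (identical(attr(profile, "source"), "exact")) {
    names(df) <- c("site", "c_exact", "variance")
  } else {
    names(df) <- c("site", "c_mc", "se")
  }
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, time = NA_real_) {
  df <- read.csv(path)
  if (identical(names(df), c("site", "c_exact", "variance"))) {
    out <- data.frame(site = as.integer(df$site), occupancy = df$c_exact,
                      variance = df$variance)
    new_occupancy_profile(out, time, "exact", NULL)
  } else if (identical(names(df), c("site", "c_mc", "se"))) {
    out <- data.frame(site = as.integer(df$site), occupancy = df$c_mc,
                      se = df$se)
    new_occupancy_profile(out, time, "monte_carlo", NULL)
  } else stop("not a profile CSV", call. = FALSE)
}

#' Write a continuum comparison table
#'
#' Fixed schema `y,c_delta,c_binomial,c_normal,c_limit`: the discrete
#' profile, its binomial closed form, the normal approximation and the
#' limiting square wave on a y-grid.
#'
#' @param cp A [continuum_params()] object.
#' @param y Positions.
#' @param t Time.
#' @param path File path.
#' @return The table, invisibly (also written to `path` when non-NULL).
#' @export
continuum_table <- function(cp, y, t, path = NULL) {
  df <- data.frame(
    y = y,
    c_delta = continuum_occupancy(cp, y, t),
    c_binomial = continuum_occupancy_binomial(cp, y, t),
    c_normal = normal_approx(cp, y, t),
    c_limit = limiting_profile(y, t, cp$a, cp$b, cp$lambda))
  if (!is.null(path))
    write.csv(format(df, digits = 17, trim = TRUE), path,
              row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write PDE snapshots
#'
#' Long-format CSV with schema `x,c,t`, one block per snapshot time.
#'
#' @param sol A `pde_solution`.
#' @param path File path.
#' @export
write_pde_solution <- function(sol, path) {
  stopifnot(inherits(sol, "pde_solution"))
  df <- do.call(rbind, lapply(seq_along(sol$times), function(i)
    data.frame(x = sol$x, c = sol$field[, i], t = sol$times[i])))
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize goodness-of-fit reports
#'
#' Reports carry full provenance (parameters and seed), so re-running the
#' generating function with the stored values reproduces statistic and
#' p-value exactly.
#'
#' @param reports A `gof_report` or list of them.
#' @param path JSON file path.
#' @return `read_gof_reports()` returns a list of `gof_report`s.
#' @export
write_gof_reports <- function(reports, path) {
  if (inherits(reports, "gof_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "gof_report")))
  payload <- lapply(reports, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_gof_reports
#' @export
read_gof_reports <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(x) structure(x, class = "gof_report"))
}

#' Read a run configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON configuration with optional blocks
#' `model` (lambda, n0, r, s), `continuum` (a, b, delta, lambda), `pde`
#' and `validation`, plus top-level `seed` and `out_dir`.  Only
#' light-touch validation is applied here; block contents are checked by
#' the constructors they feed.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON", call. = FALSE)
  if (!is.list(cfg)) stop("malformed config", call. = FALSE)
  cfg
}
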