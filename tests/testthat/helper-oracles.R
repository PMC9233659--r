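# Independent oracles, deliberately naive: plain-arithmetic formulas and a
# pure-R event-by-event simulator that shares no code with the package's
# C++ path.

oracle_yule_pmf <- function(k, t, lambda, j) {
  if (k < j) return(0)
  choose(k - 1, k - j) * exp(-j * lambda * t) * (1 - exp(-lambda * t))^(k - j)
}

# brute-force 2F1(a, 1; c; z): straightforward n_terms-term summation
oracle_2f1 <- function(a, c, z, n_terms = 400) {
  n <- 0:(n_terms - 1)
  # (a)_n / (c)_n via cumulative products
  terms <- c(1, cumprod((a + n) / (c + n) * z))
  sum(terms)
}

# pure-R coupled proliferation simulator
oracle_sim <- function(lambda, n0, r, s, t_end) {
  marks <- if (s > r) seq.int(r + 1L, s) else integer(0)
  N <- n0
  t <- 0
  repeat {
    dt <- rexp(1L, lambda * N)
    if (t + dt > t_end) break
    t <- t + dt
    site <- sample.int(N, 1L)
    marks[marks >= site] <- marks[marks >= site] + 1L
    N <- N + 1L
  }
  list(marks = marks, n = N)
}

# chi-square of integer draws against a pmf, own binning (values capped
# into a tail bin so every expected count is at least 5)
oracle_chisq_pmf <- function(obs, probs_fun, support_min, n_bins) {
  lv <- support_min:(support_min + n_bins - 1L)
  pr <- probs_fun(lv)
  pr[n_bins] <- 1 - sum(pr[-n_bins])
  counts <- tabulate(pmin(obs, max(lv)) - support_min + 1L, nbins = n_bins)
  keep <- length(obs) * pr >= 5
  if (all(keep)) return(suppressWarnings(chisq.test(counts, p = pr)))
  suppressWarnings(chisq.test(c(counts[keep], sum(counts[!keep])),
                              p = c(pr[keep], sum(pr[!keep]))))
}

# exact integral of a piecewise-constant profile with known breakpoints:
# sum of value-at-midpoint times segment width
segment_integral <- function(f, breaks) {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sum(f(mids) * diff(breaks))
}
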