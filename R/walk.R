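#' Monte Carlo reaction times on a network with an imperfect target
#'
#' Event-driven continuous-time simulation: at each site the walker waits an
#' exponential time with rate `nu_i = w * degree(i)`, then jumps to a
#' uniformly chosen neighbour.  On each arrival at the target a Bernoulli
#' trial with success probability `p` is drawn; on success the reaction
#' completes at the end of that residence, so the reaction time includes the
#' residence time on the reactive site at every visit.  Starting *at* the
#' target counts as an arrival.
#'
#' @param net an [rxn_network].
#' @param p per-visit reaction probability in (0, 1].
#' @param n_walkers number of independent walkers.
#' @param start site index (or vector of indices sampled uniformly per
#'   walker).  Ignored when `start_r` is given.
#' @param start_r start at a uniformly chosen site at this chemical distance
#'   from the target.
#' @param t_max censoring horizon; defaults to `50 * N / nu_0`, far beyond
#'   the global mean timescale.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return a tibble of class `rxn_samples` with columns `walker_id`, `time`,
#'   `censored`; the configuration is attached as attribute `config`.
#' @export
sample_reaction_times <- function(net, p, n_walkers, start = NULL,
                                  start_r = NULL, t_max = NULL, seed = NULL) {
  if (p <= 0 || p > 1) stop("reaction probability p must be in (0, 1]")
  n_walkers <- as.integer(n_walkers)
  stopifnot(n_walkers >= 1)
  if (!is.null(seed)) set.seed(seed)
  nu0 <- net$rate * net$degree[net$target]
  if (is.null(t_max)) t_max <- 50 * net$n_sites / nu0
  stopifnot(t_max > 0)
  if (!is.null(start_r)) start <- sites_at_distance(net, start_r)
  if (is.null(start)) stop("one of start or start_r must be given")
  stopifnot(all(start >= 1), all(start <= net$n_sites))
  starts <- if (length(start) == 1L) rep.int(start, n_walkers)
            else start[sample.int(length(start), n_walkers, replace = TRUE)]
  csr <- adjacency_csr(net)
  res <- cpp_sample_reaction_times(csr$offsets, csr$neigh, net$rate,
                                   net$target - 1L, starts - 1L, p, t_max)
  out <- tibble(walker_id = seq_len(n_walkers), time = res$time,
                censored = res$censored)
  cens_frac <- mean(out$censored)
  if (cens_frac > 0.01) {
    warning(sprintf("censored fraction %.1f%% exceeds 1%%; increase t_max",
                    100 * cens_frac))
  }
  new_rxn_samples(out, list(kind = "reaction", p = p, start = start,
                            start_r = start_r, t_max = t_max, seed = seed,
                            n_sites = net$n_sites, nu0 = nu0))
}

#' Monte Carlo first return times to the target
#'
#' Each sample starts just after a departure from the target: the walker is
#' placed on a uniformly chosen neighbour and the time until the next arrival
#' at the target, including the residence on arrival, is recorded.  By the
#' Kac theorem the mean is exactly `N / nu_0` for the uniform stationary
#' distribution realized by these jump rates.
#'
#' @inheritParams sample_reaction_times
#' @param n number of samples.
#' @return a tibble of class `rxn_samples`.
#' @export
sample_return_times <- function(net, n, seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(net)
  times <- cpp_sample_return_times(csr$offsets, csr$neigh, net$rate,
                                   net$target - 1L, n)
  out <- tibble(walker_id = seq_len(n), time = times, censored = FALSE)
  new_rxn_samples(out, list(kind = "return", seed = seed,
                            n_sites = net$n_sites,
                            nu0 = net$rate * net$degree[net$target]))
}

new_rxn_samples <- function(x, config) {
  structure(x, class = c("rxn_samples", class(tibble())), config = config)
}

#' @export
glance.rxn_samples <- function(x, ...) {
  unc <- x$time[!x$censored]
  tibble(n = nrow(x), n_censored = sum(x$censored),
         mean = mean(unc), se = sd(unc) / sqrt(length(unc)))
}

#' Sample mean and standard error of uncensored reaction times
#'
#' @param samples an `rxn_samples` tibble.
#' @return a one-row tibble with columns `mean`, `se`, `n`.  Errors if any
#'   sample is censored (the mean is undefined under censoring).
#' @export
estimate_mean <- function(samples) {
  if (nrow(samples) == 0L) stop("empty sample set")
  if (any(samples$censored)) {
    stop("censored samples present: the sample mean is undefined")
  }
  n <- nrow(samples)
  tibble(mean = mean(samples$time),
         se = if (n > 1L) sd(samples$time) / sqrt(n) else 0,
         n = n)
}

#' Empirical survival curve with Wilson confidence intervals
#'
#' `S(t)` is the fraction of walkers whose reaction time exceeds `t`;
#' censored walkers count as survivors up to the censoring horizon, and the
#' grid is truncated there.  Pointwise 95% Wilson intervals are attached.
#'
#' @param samples an `rxn_samples` tibble.
#' @param t_grid evaluation times; defaults to a log-spaced grid over the
#'   sample range.
#' @param conf confidence level for the Wilson intervals.
#' @return a tibble of class `rxn_survival` with columns `t`, `S`, `ci_lo`,
#'   `ci_hi`, `halfwidth`, `n`.
#' @export
estimate_survival <- function(samples, t_grid = NULL, conf = 0.95) {
  if (nrow(samples) == 0L) stop("empty sample set")
  if (sum(!samples$censored) < 30L) {
    stop("need at least 30 uncensored samples for a survival estimate")
  }
  n <- nrow(samples)
  if (is.null(t_grid)) {
    hi <- max(samples$time)
    lo <- max(min(samples$time), hi * 1e-4)
    t_grid <- c(0, exp(seq(log(lo), log(hi), length.out = 120)))
  }
  if (any(samples$censored)) t_grid <- t_grid[t_grid <= min(samples$time[samples$censored])]
  surv <- vapply(t_grid, function(t) mean(samples$time > t), numeric(1))
  z <- qnorm(1 - (1 - conf) / 2)
  centre <- (surv + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(surv * (1 - surv) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  new_rxn_survival(tibble(t = t_grid, S = surv,
                          ci_lo = pmax(0, centre - half),
                          ci_hi = pmin(1, centre + half),
                          halfwidth = half, n = n),
                   source = "monte-carlo")
}

new_rxn_survival <- function(x, source = "unknown", extra = list()) {
  structure(x, class = c("rxn_survival", class(tibble())),
            source = source, extra = extra)
}

#' Empirical occupation check of the uniform stationary distribution
#'
#' Simulates one long trajectory without any target and returns per-site
#' occupation-time fractions, which converge to `1/N` for every site.
#'
#' @param net an [rxn_network].
#' @param t_total total simulated time.
#' @param start start site.
#' @param seed optional seed.
#' @return tibble with columns `site`, `fraction`.
#' @export
occupation_fractions <- function(net, t_total, start = net$target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(net)
  occ <- cpp_occupation_times(csr$offsets, csr$neigh, net$rate, start - 1L,
                              t_total)
  tibble(site = seq_len(net$n_sites), fraction = occ / sum(occ))
}
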