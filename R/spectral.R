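#' Exact finite-network solvers
#'
#' The walk with an imperfect target is an absorbing continuous-time Markov
#' chain: from the target, a departure leads to the absorbing (reacted)
#' state with probability `p` and to each neighbour with probability
#' `(1-p)/degree`.  The transient generator `Q_p` therefore equals the walk
#' generator except that the target row's off-diagonal entries are scaled by
#' `1-p`, leaving a probability leak `p * nu_0` in that row.  Mean
#' absorption times solve `Q_p T = -1`; Laplace transforms are resolvents;
#' survival functions come from the spectral decomposition of `Q_p`.
#'
#' @name spectral
NULL

# sparse transient generator of the absorbing reaction chain
transient_generator <- function(net, p) {
  stopifnot(p > 0, p <= 1)
  N <- net$n_sites
  w <- net$rate
  e <- net$edges
  vals <- rep(w, 2L * nrow(e))
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  vals[from == net$target] <- w * (1 - p)
  Matrix::sparseMatrix(i = c(from, seq_len(N)), j = c(to, seq_len(N)),
                       x = c(vals, -w * net$degree), dims = c(N, N))
}

#' Exact mean first-passage time by linear solve
#'
#' Mean time to complete a perfect reaction (`p = 1`), i.e. the first
#' passage time to the target including the residence on arrival.  Starting
#' at the target gives `1 / nu_0` (its own residence).
#'
#' @param net an [rxn_network].
#' @param start site index or vector of sites (a vector returns the
#'   uniform average over those starts).
#' @return mean first-passage time (scalar).
#' @export
exact_mean_fpt <- function(net, start) {
  exact_mean_reaction_time(net, p = 1, start = start)
}

#' Exact mean reaction time by linear solve
#'
#' Solves `Q_p T = -1` for the absorbing chain.  Satisfies the renewal
#' decomposition `T = tau_r + ((1-p)/p) N / nu_0` exactly.
#'
#' @inheritParams exact_mean_fpt
#' @param p per-visit reaction probability in (0, 1].
#' @return mean reaction time averaged uniformly over `start`.
#' @export
exact_mean_reaction_time <- function(net, p, start) {
  stopifnot(all(start >= 1), all(start <= net$n_sites))
  if (net$n_sites > 1e5) stop("network too large for the direct solver")
  Q <- transient_generator(net, p)
  T_all <- Matrix::solve(Q, rep(-1, net$n_sites))
  mean(as.numeric(T_all)[start])
}

#' Mean reaction time from every start site
#' @inheritParams exact_mean_reaction_time
#' @return tibble with columns `site`, `mrt`.
#' @export
exact_mrt_profile <- function(net, p = 1) {
  Q <- transient_generator(net, p)
  tibble(site = seq_len(net$n_sites),
         mrt = as.numeric(Matrix::solve(Q, rep(-1, net$n_sites))))
}

#' Global mean reaction time
#'
#' Uniform average of the exact mean reaction time over all start sites;
#' `p = 1` gives the global mean first-passage time.
#'
#' @inheritParams exact_mean_reaction_time
#' @return scalar.
#' @export
global_mean <- function(net, p = 1) {
  exact_mean_reaction_time(net, p, seq_len(net$n_sites))
}

#' Laplace transform of the reaction-time distribution
#'
#' `reaction_laplace` evaluates `E[exp(-s T)]` directly from the resolvent
#' of the absorbing chain: `f = (sI - Q_p)^{-1} a` with the absorption
#' inflow `a = p * nu_0` at the target.  `fpt_laplace` is the `p = 1` case
#' and `return_laplace` averages `fpt_laplace` over the target's neighbours
#' (the first-return-time transform).  `reaction_laplace_renewal` composes
#' the renewal identity
#' `F(s) = p F*(s) / (1 - (1-p) F1*(s))`
#' from the two transforms; it agrees with the direct resolvent to solver
#' precision.
#'
#' @inheritParams exact_mean_reaction_time
#' @param s Laplace variable, `s >= 0` (vectorized).
#' @return numeric vector of transform values in (0, 1].
#' @export
reaction_laplace <- function(net, start, p, s) {
  stopifnot(all(s >= 0), p > 0, p <= 1)
  Q <- transient_generator(net, p)
  N <- net$n_sites
  a <- rep(0, N)
  a[net$target] <- p * net$rate * net$degree[net$target]
  vapply(s, function(si) {
    f <- Matrix::solve(Matrix::Diagonal(N, si) - Q, a)
    mean(as.numeric(f)[start])
  }, numeric(1))
}

#' @rdname reaction_laplace
#' @export
fpt_laplace <- function(net, start, s) reaction_laplace(net, start, p = 1, s = s)

#' @rdname reaction_laplace
#' @export
return_laplace <- function(net, s) {
  nb <- neighbours_of(net, net$target)
  fpt_laplace(net, nb, s)
}

#' @rdname reaction_laplace
#' @export
reaction_laplace_renewal <- function(net, start, p, s) {
  Fstar <- fpt_laplace(net, start, s)
  F1 <- return_laplace(net, s)
  p * Fstar / (1 - (1 - p) * F1)
}

neighbours_of <- function(net, site) {
  e <- net$edges
  c(e[e[, 1] == site, 2], e[e[, 2] == site, 1])
}

#' Spectral decomposition of the reaction-time distribution
#'
#' Returns rates `lambda_k > 0` and weights `w_k` such that the survival
#' probability from `start` (uniformly averaged if a vector) is
#' `S(t) = sum_k w_k exp(-lambda_k t)`.  For `p < 1` the transient
#' generator is symmetrized by the similarity transform built from the
#' measure `m_i = 1` (`m_target = 1/(1-p)`) under which the chain is
#' reversible; for `p = 1` the target-deleted block (symmetric) gives the
#' arrival-time spectrum and the final residence (an independent
#' exponential of rate `nu_0`) is convolved in analytically.
#'
#' @inheritParams exact_mean_reaction_time
#' @return list with components `rate`, `weight`.
#' @export
reaction_spectrum <- function(net, p, start) {
  N <- net$n_sites
  if (N > 1e4) stop("dense eigendecomposition guard: N must be <= 1e4")
  stopifnot(all(start >= 1), all(start <= N), p > 0, p <= 1)
  nu0 <- net$rate * net$degree[net$target]
  if (p < 1) {
    Q <- as.matrix(transient_generator(net, p))
    m <- rep(1, N); m[net$target] <- 1 / (1 - p)
    sm <- sqrt(m)
    Sy <- Q * outer(sm, 1 / sm)
    Sy <- (Sy + t(Sy)) / 2
    ed <- eigen(Sy, symmetric = TRUE)
    U <- ed$vectors
    v <- as.numeric(crossprod(U, sm))            # modes vs the all-ones exit
    u <- colMeans(U[start, , drop = FALSE] / sm[start])
    list(rate = -ed$values, weight = u * v)
  } else {
    if (all(start == net$target)) {
      return(list(rate = nu0, weight = 1))
    }
    keep <- setdiff(seq_len(N), net$target)
    Q <- as.matrix(transient_generator(net, 1))[keep, keep]
    Q <- (Q + t(Q)) / 2                          # symmetric by construction
    ed <- eigen(Q, symmetric = TRUE)
    mu <- -ed$values
    U <- ed$vectors
    pos <- match(setdiff(start, net$target), keep)
    b <- colMeans(U[pos, , drop = FALSE]) * colSums(U) *
      length(pos) / length(start)
    # convolve the arrival-time mixture with the Exp(nu0) final residence
    mu[abs(mu - nu0) < 1e-9] <- nu0 * (1 + 1e-8)
    w_mu <- b * nu0 / (nu0 - mu)
    w_nu <- mean(start == net$target) - sum(b * mu / (nu0 - mu))
    list(rate = c(mu, nu0), weight = c(w_mu, w_nu))
  }
}

#' Exact survival probability from the spectral decomposition
#'
#' @inheritParams exact_mean_reaction_time
#' @param t_grid evaluation times.
#' @return a tibble of class `rxn_survival` (`halfwidth = 0`).
#' @export
exact_survival <- function(net, start, p, t_grid) {
  sp <- reaction_spectrum(net, p, start)
  S <- as.numeric(exp(-outer(t_grid, sp$rate)) %*% sp$weight)
  S <- pmin(1, pmax(0, S))
  new_rxn_survival(tibble(t = t_grid, S = S, ci_lo = S, ci_hi = S,
                          halfwidth = 0, n = Inf),
                   source = "spectral",
                   extra = list(p = p, start = start))
}

#' Asymptotic tail of the exact survival function
#'
#' Slowest decay mode: `S(t) ~ amplitude * exp(-rate * t)`.
#'
#' @inheritParams exact_mean_reaction_time
#' @return list with `rate` and `amplitude`.
#' @export
survival_tail <- function(net, p, start) {
  sp <- reaction_spectrum(net, p, start)
  keep <- abs(sp$weight) > 1e-12
  k <- which.min(sp$rate[keep])
  list(rate = sp$rate[keep][k], amplitude = sp$weight[keep][k])
}

#' Moments of the reaction time from the spectral decomposition
#' @inheritParams exact_mean_reaction_time
#' @param order moment order.
#' @return scalar `E[T^order]`.
#' @export
exact_moment <- function(net, p, start, order = 1) {
  sp <- reaction_spectrum(net, p, start)
  factorial(order) * sum(sp$weight / sp$rate^order)
}
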