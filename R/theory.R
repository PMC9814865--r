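#' Asymptotic theory of imperfect reaction kinetics
#'
#' Large-volume asymptotics for scale-invariant walks with an imperfect
#' target: the Kac mean return time, the two-term compact mean reaction
#' time (diffusion-controlled + reaction-controlled), the crossover length
#' separating those regimes, the universal compact survival function
#' `Phi_nu`, and the exponential noncompact asymptotics.
#'
#' @name theory
NULL

#' Kac mean return time
#'
#' For the uniform stationary distribution the mean first return time to the
#' target is exactly `N / nu_0`, independent of the network structure.
#'
#' @param N number of sites.
#' @param nu0 target exit rate.
#' @return mean return time.
#' @export
kac_return_time <- function(N, nu0) {
  stopifnot(N >= 1, nu0 > 0)
  N / nu0
}

#' Compact mean reaction time (two-term asymptotic)
#'
#' For compact walks (`d_w > d_f`) the mean reaction time from chemical
#' distance `r` is asymptotically
#' `N r^(d_w - d_f) / nu_0  +  N (1-p) / (p nu_0)`:
#' a diffusion-controlled (DC) transport term plus a reaction-controlled
#' (RC) term counting the `(1-p)/p` extra return excursions.
#'
#' @param r chemical distance (vectorized), `r >= 1`.
#' @param N number of sites.
#' @param nu0 target exit rate.
#' @param p reaction probability in (0, 1].
#' @param exps a [exponents_for()] object; must be compact.
#' @return tibble with columns `r`, `dc`, `rc`, `mrt`.
#' @export
mrt_compact <- function(r, N, nu0, p, exps) {
  if (!exps$compact) stop("mrt_compact requires compact exponents (d_w > d_f)")
  stopifnot(all(r >= 1), p > 0, p <= 1, N >= 1, nu0 > 0)
  dc <- N * r^(exps$d_w - exps$d_f) / nu0
  rc <- N * (1 - p) / (p * nu0)
  tibble(r = r, dc = dc, rc = rc, mrt = dc + rc)
}

#' Crossover length between RC and DC regimes
#'
#' Distance at which the reaction-controlled and diffusion-controlled terms
#' balance: `l_c = ((1-p)/p)^(1/(d_w-d_f))`.  Zero at `p = 1`.
#'
#' @inheritParams mrt_compact
#' @export
crossover_length <- function(p, exps) {
  if (!exps$compact) stop("crossover_length requires compact exponents")
  stopifnot(p > 0, p <= 1)
  ((1 - p) / p)^(1 / (exps$d_w - exps$d_f))
}

#' Reactivity threshold for the exponential regime
#'
#' The broadly distributed (first-passage-like) reaction-time statistics
#' persist down to `p* = N^(1 - d_w/d_f)`, the reactivity at which the
#' crossover length reaches the system size; `p*` vanishes as `N` grows.
#'
#' @inheritParams mrt_compact
#' @export
reactivity_threshold <- function(N, exps) {
  if (!exps$compact) stop("reactivity_threshold requires compact exponents")
  stopifnot(N >= 1)
  N^(1 - exps$d_w / exps$d_f)
}

# cache of Bessel-zero tables, keyed by nu
.phi_cache <- new.env(parent = emptyenv())

#' Zeros of the Bessel function J_{-nu}
#'
#' First `K` positive zeros, located by bracketed root search between
#' consecutive sign changes; brackets are seeded by the McMahon asymptotic
#' spacing (about pi).  For `nu = 1/2` the zeros are `(k + 1/2) pi`
#' exactly (`J_{-1/2}(x)` is proportional to `cos(x)/sqrt(x)`).
#'
#' @param nu order parameter in (0, 1).
#' @param K number of zeros.
#' @return increasing positive numeric vector of length `K`.
#' @export
phi_zeros <- function(nu, K) {
  stopifnot(nu > 0, nu < 1, K >= 1)
  key <- sprintf("%.15g", nu)
  cached <- .phi_cache[[key]]
  if (!is.null(cached) && length(cached$zeros) >= K) {
    return(cached$zeros[seq_len(K)])
  }
  f <- function(x) besselJ(x, -nu)
  # sign-change scan: zeros are interlaced with spacing -> pi
  zeros <- numeric(K)
  step <- 0.05
  x <- step
  fx <- f(x)
  found <- 0L
  while (found < K) {
    # after the first few zeros, jump near the McMahon prediction
    if (found >= 2L) {
      nxt <- 2 * zeros[found] - zeros[found - 1L]
      lo <- nxt - 0.45 * pi
      if (lo > x) { x <- lo; fx <- f(x) }
      step <- 0.2
    }
    repeat {
      x2 <- x + step
      fx2 <- f(x2)
      if (is.finite(fx) && is.finite(fx2) && fx * fx2 < 0) {
        found <- found + 1L
        zeros[found] <- uniroot(f, c(x, x2), tol = 1e-14)$root
        x <- x2; fx <- fx2
        break
      }
      x <- x2; fx <- fx2
    }
  }
  .phi_cache[[key]] <- list(zeros = zeros)
  zeros
}

# series coefficients of the universal function, one per zero
phi_coefficients <- function(nu, K) {
  al <- phi_zeros(nu, K)
  pref <- gamma(nu) * 2^(2 * nu) * nu^2 / (gamma(2 - nu) * (1 + nu))
  coef <- besselJ(al, nu) * al^(1 - 2 * nu) * pref / besselJ(al, 1 - nu)
  list(zeros = al, coef = coef, rate = al^2 * nu / (2 * (1 - nu^2)))
}

#' Universal compact survival function Phi_nu
#'
#' Series over the zeros `alpha_k` of `J_{-nu}`:
#' `Phi_nu(theta) = sum_k c_k exp(-alpha_k^2 nu theta / (2 (1 - nu^2)))`
#' with
#' `c_k = J_nu(alpha_k) alpha_k^(1-2 nu) Gamma(nu) 2^(2 nu) nu^2 /
#'        (J_{1-nu}(alpha_k) Gamma(2-nu) (1+nu))`.
#' `Phi_nu` integrates to one and is the universal shape of the rescaled
#' survival probability for compact transport, with `nu = d_f / d_w`.
#' The truncation `K` is chosen adaptively so the last term is below
#' `1e-10` of the partial sum (`K >= 50` always; the series converges
#' slowly as `theta -> 0`, where the asymptotic form is not meant to be
#' used anyway).
#'
#' @param theta rescaled time `t / tau_G`, `theta >= 0` (vectorized).
#' @param nu `d_f / d_w` in (0, 1).
#' @param K series truncation; `NULL` for adaptive.
#' @return `Phi_nu(theta)` values.
#' @export
phi_universal <- function(theta, nu, K = NULL) {
  stopifnot(nu > 0, nu < 1, all(theta >= 0))
  if (is.null(K)) {
    # terms decay like exp(-rate_k * theta); rate_k ~ (k pi)^2 nu / (2(1-nu^2))
    th <- max(min(theta[theta > 0], Inf), 1e-8)
    K <- max(50, ceiling(sqrt(2 * (1 - nu^2) * 46 / (nu * th)) / pi) + 5)
  }
  pc <- phi_coefficients(nu, K)
  as.numeric(exp(-outer(theta, pc$rate)) %*% pc$coef)
}

#' Integral of Phi_nu over (0, Inf)
#'
#' Term-by-term analytic integral `sum_k c_k / rate_k`, with the slowly
#' converging tail (`~ k^(-1-2 nu)`) summed via its large-order asymptotic
#' form and a midpoint Euler-Maclaurin estimate.  Equals 1 (Phi_nu is a
#' probability density of the rescaled time).
#'
#' @inheritParams phi_universal
#' @param K number of explicit terms.
#' @return the integral.
#' @export
phi_integral <- function(nu, K = 8000) {
  pc <- phi_coefficients(nu, K)
  main <- sum(pc$coef / pc$rate)
  # asymptotic term: c_k / rate_k ~ C * alpha_k^(-1-2nu), alpha_k ~ (k+b) pi
  pref <- gamma(nu) * 2^(2 * nu) * nu^2 / (gamma(2 - nu) * (1 + nu))
  Cas <- sin(nu * pi) * pref * 2 * (1 - nu^2) / nu
  b <- 3 / 4 - nu / 2
  # sum_{k=K}^Inf C ((k+b) pi)^(-1-2nu), zero index starting at 0
  tail <- Cas * pi^(-1 - 2 * nu) * (K - 0.5 + b)^(-2 * nu) / (2 * nu)
  main + tail
}

#' Rescaled survival prediction, compact case
#'
#' `S(t) ~ (mean_T / tau_G) * Phi_nu(t / tau_G)`: the reactivity enters
#' only through the prefactor `mean_T`, so rescaled curves for any `(r, p)`
#' collapse onto `Phi_nu`.  Asymptotic in the large-volume limit; not
#' clipped to values below one (it is not accurate for `t << tau_G`).
#'
#' @param t time (vectorized).
#' @param mean_T mean reaction time from the chosen start.
#' @param tau_G global mean first-passage time (p = 1), which sets the
#'   time scale.
#' @param nu `d_f / d_w`.
#' @return predicted survival values.
#' @export
survival_compact_theory <- function(t, mean_T, tau_G, nu) {
  stopifnot(mean_T > 0, tau_G > 0)
  (mean_T / tau_G) * phi_universal(t / tau_G, nu)
}

#' Rescaled survival prediction, noncompact case
#'
#' `S(t) = (mean_Tr / mean_TG) * exp(-t / mean_TG)`.  The prefactor is
#' below one: the missing mass at `t -> 0` accounts for trajectories that
#' find the target without exploring the confining volume.  Integrates to
#' `mean_Tr` exactly.
#'
#' @param t time (vectorized).
#' @param mean_Tr mean reaction time from the start of interest.
#' @param mean_TG global mean reaction time.
#' @return predicted survival values.
#' @export
survival_noncompact_theory <- function(t, mean_Tr, mean_TG) {
  stopifnot(mean_Tr > 0, mean_TG > 0)
  if (mean_Tr > mean_TG * (1 + 1e-9)) {
    stop("mean_Tr must not exceed mean_TG (prefactor must be <= 1)")
  }
  (mean_Tr / mean_TG) * exp(-t / mean_TG)
}

#' Asymptotic first-passage density, noncompact case
#'
#' `(1 - mean_tau_r / tau_G) delta(t) + (mean_tau_r / tau_G^2) exp(-t / tau_G)`:
#' an atom at zero (trajectories that hit the target before exploring the
#' volume) plus an exponential bulk.  Returned as the atom weight and the
#' continuous density function; total mass 1, first moment `mean_tau_r`.
#'
#' @param mean_tau_r mean first-passage time from the start of interest.
#' @param tau_G global mean first-passage time.
#' @return list with `atom` (weight at 0) and `density` (function of t).
#' @export
fpt_density_noncompact <- function(mean_tau_r, tau_G) {
  stopifnot(mean_tau_r > 0, tau_G > 0)
  if (mean_tau_r > tau_G * (1 + 1e-9)) stop("mean_tau_r must not exceed tau_G")
  list(atom = 1 - mean_tau_r / tau_G,
       density = function(t) (mean_tau_r / tau_G^2) * exp(-t / tau_G))
}
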