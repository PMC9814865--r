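#' Closed-form mean reaction times for diffusion with a spherical imperfect
#' target
#'
#' A Brownian particle (diffusivity `D`) in a large confining volume `V`
#' reacts with a spherical target of radius `a` at the origin, under two
#' models of imperfect reactivity: a penetrable *sink* region with uniform
#' killing rate `k` (dimensionless strength `K = k a^2 / D`), or an
#' impenetrable surface with *Robin* (partially reactive) boundary
#' conditions of reactivity `kappa`.  In the large-volume limit the mean
#' reaction time grows linearly with `V` and the shape-independent ratio
#' `Phi(r) = <T(r)>/V` has closed forms in `d = 1, 2, 3`.  All outputs are
#' in units of `a^2/D` per unit volume `a^d` when `a = D = 1`.
#'
#' @name continuum
NULL

#' Surface area of the unit sphere in d dimensions
#' @param d dimension (1, 2 or 3).
#' @keywords internal
sphere_surface <- function(d) c(2, 2 * pi, 4 * pi)[d]

#' @rdname sphere_surface
#' @keywords internal
sphere_volume <- function(d) c(2, pi, 4 * pi / 3)[d]

#' Mean reaction time per unit volume, sink model
#'
#' `Phi(r) = <T>/V` outside a penetrable spherical sink of radius `a` and
#' killing rate `k`, for a start at radial distance `r >= a`:
#' \describe{
#' \item{d = 1}{`(1/D) (r/2 + (a/2) (cosh(sK)/(sK sinh(sK)) - 1))`}
#' \item{d = 2}{`(1/D) (ln(r/a)/(2 pi) + I0(sK)/(2 pi sK I1(sK)))`}
#' \item{d = 3}{`(1/D) (-1/(4 pi r) + sK/(4 pi a (sK - tanh(sK))))`}
#' }
#' with `sK = sqrt(K)`, `K = k a^2 / D`.
#'
#' @param r start radius, `r >= a` (vectorized).
#' @param d dimension, 1, 2 or 3.
#' @param k sink killing rate, `k > 0`.
#' @param a target radius.
#' @param D diffusivity.
#' @return `<T>/V` values.
#' @export
mrt_sink <- function(r, d, k, a = 1, D = 1) {
  stopifnot(d %in% 1:3, a > 0, D > 0)
  if (any(k <= 0)) stop("sink rate k must be > 0 (k = 0 never reacts)")
  if (any(r < a)) stop("mrt_sink is defined outside the sink region (r >= a)")
  sK <- sqrt(k * a^2 / D)
  # overflow-safe forms: cosh/sinh via tanh, Bessel ratio via scaled I
  if (d == 1) (r / 2 + (a / 2) * (1 / (sK * tanh(sK)) - 1)) / D
  else if (d == 2) (log(r / a) / (2 * pi) +
                    besselI(sK, 0, expon.scaled = TRUE) /
                      (2 * pi * sK * besselI(sK, 1, expon.scaled = TRUE))) / D
  else (-1 / (4 * pi * r) + sK / (4 * pi * a * (sK - tanh(sK)))) / D
}

#' Mean reaction time per unit volume, Robin (surface reactivity) model
#'
#' `Phi(r) = <T>/V` outside an impenetrable spherical target of radius `a`
#' with surface reactivity `kappa`:
#' \describe{
#' \item{d = 1}{`(r-a)/(2D) + 1/(2 kappa)`}
#' \item{d = 2}{`ln(r/a)/(2 pi D) + 1/(2 pi a kappa)`}
#' \item{d = 3}{`1/(4 pi D a) - 1/(4 pi D r) + 1/(4 pi a^2 kappa)`}
#' }
#' In `d = 3` the `r -> Inf` value is the inverse Collins-Kimball effective
#' rate, `1/(4 pi D a) + 1/(4 pi a^2 kappa)`.
#'
#' @param r start radius, `r >= a` (vectorized).
#' @param d dimension, 1, 2 or 3.
#' @param kappa surface reactivity, `kappa > 0`.
#' @param a target radius.
#' @param D diffusivity.
#' @return `<T>/V` values.
#' @export
mrt_robin <- function(r, d, kappa, a = 1, D = 1) {
  stopifnot(d %in% 1:3, a > 0, D > 0)
  if (any(kappa <= 0)) stop("surface reactivity kappa must be > 0")
  if (any(r < a)) stop("start radius must satisfy r >= a")
  if (d == 1) (r - a) / (2 * D) + 1 / (2 * kappa)
  else if (d == 2) log(r / a) / (2 * pi * D) + 1 / (2 * pi * a * kappa)
  else 1 / (4 * pi * D * a) - 1 / (4 * pi * D * r) + 1 / (4 * pi * a^2 * kappa)
}

#' Reaction-controlled time at contact
#'
#' `<T>/V` evaluated at `r = a`, the pure reaction-controlled part.  For
#' surface reactivity it scales as `kappa^-1` exactly; for the sink model
#' it scales as `k^(-1/2)` at strong absorption (`K >> 1`), because most
#' reaction events then occur within a small penetration length of the
#' target surface.
#'
#' @param d dimension.
#' @param model `"sink"` or `"robin"`.
#' @param k,kappa reactivity of the chosen model (vectorized).
#' @param a target radius.
#' @param D diffusivity.
#' @return `<T>/V` at `r = a`.
#' @export
rc_time <- function(d, model = c("sink", "robin"), k = NULL, kappa = NULL,
                    a = 1, D = 1) {
  model <- match.arg(model)
  if (model == "sink") mrt_sink(a, d, k, a, D)
  else mrt_robin(a, d, kappa, a, D)
}

#' Residual check of the backward boundary-value problem
#'
#' Verifies that a candidate `Phi(r)` (as returned by [mrt_sink()] or
#' [mrt_robin()]) satisfies the defining radial boundary-value problem:
#' the stationary backward equation `(D Lap_r - k(r)) Phi = 0` (sink) or
#' `D Lap_r Phi = 0` with the Robin condition `D Phi'(a) = kappa Phi(a)`,
#' together with the normalization `integral of reactivity * Phi` over the
#' target equal to 1.  For the sink model the interior (`r < a`) piece is
#' reconstructed as the bounded solution of the same ODE matched to the
#' candidate by continuity at `a`; derivative continuity is then part of
#' the residual.
#'
#' @param phi function of `r` returning the candidate `<T>/V` for `r >= a`.
#' @param d dimension, 1, 2 or 3.
#' @param model `"sink"` or `"robin"`.
#' @param k,kappa reactivity of the chosen model.
#' @param a target radius.
#' @param D diffusivity.
#' @param r_max outer extent of the finite-difference grid.
#' @param n_grid number of grid points (at least 1000).
#' @return list with componentwise residuals `ode` (max scaled second-order
#'   finite-difference residual of the radial ODE), `boundary` (Robin or
#'   C1-matching condition), `normalization` (deviation of the reactivity
#'   integral from 1), and their maximum `max`.
#' @export
bvp_residual <- function(phi, d, model = c("sink", "robin"), k = NULL,
                         kappa = NULL, a = 1, D = 1, r_max = 50 * a,
                         n_grid = 4000) {
  model <- match.arg(model)
  stopifnot(d %in% 1:3)
  if (n_grid < 1000) stop("n_grid must be >= 1000 for a reliable residual")
  lap_res <- function(f, r, h, kill) {
    # fourth-order central-difference residual of D (f'' + (d-1)/r f') = kill f
    n <- length(f)
    i <- 3:(n - 2)
    fp <- (-f[i + 2] + 8 * f[i + 1] - 8 * f[i - 1] + f[i - 2]) / (12 * h)
    fpp <- (-f[i + 2] + 16 * f[i + 1] - 30 * f[i] + 16 * f[i - 1] -
              f[i - 2]) / (12 * h^2)
    max(abs(D * (fpp + (d - 1) / r[i] * fp) - kill * f[i]))
  }
  h <- (r_max - a) / n_grid
  r_out <- seq(a, r_max, by = h)
  f_out <- phi(r_out)
  ode_out <- lap_res(f_out, r_out, h, 0)
  # fourth-order one-sided derivative at the target surface
  dphi_a <- sum(c(-25, 48, -36, 16, -3) * phi(a + h * 0:4)) / (12 * h)
  if (model == "robin") {
    boundary <- abs(D * dphi_a - kappa * phi(a))
    normalization <- abs(kappa * phi(a) * sphere_surface(d) * a^(d - 1) - 1)
    ode <- ode_out
  } else {
    q <- sqrt(k / D)
    g <- switch(d,
                function(r) cosh(q * r),
                function(r) besselI(q * r, 0),
                function(r) ifelse(r == 0, q, sinh(q * r) / r))
    A <- phi(a) / g(a)
    hin <- a / n_grid
    r_in <- seq(hin / 2, a - hin / 2, by = hin)  # avoid the r = 0 coordinate singularity
    f_in <- A * g(r_in)
    ode_in <- lap_res(f_in, r_in, hin, k)
    dg_a <- switch(d,
                   q * sinh(q * a),
                   q * besselI(q * a, 1),
                   (q * cosh(q * a) * a - sinh(q * a)) / a^2)
    boundary <- abs(A * dg_a - dphi_a)         # C1 matching at the sink edge
    igrand <- function(r) k * A * g(r) * sphere_surface(d) * r^(d - 1)
    normalization <- abs(integrate(igrand, 0, a, rel.tol = 1e-10)$value - 1)
    ode <- max(ode_out, ode_in)
  }
  out <- list(ode = ode, boundary = boundary, normalization = normalization)
  out$max <- max(unlist(out))
  out
}
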