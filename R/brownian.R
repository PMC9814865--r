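#' Confining domains for Brownian dynamics
#'
#' Star-shaped domains specified in polar coordinates by
#' `r(theta) = R f(theta)`:
#' `f_A = 1.6 (1 + 0.5 cos^2 theta)` (anisotropic) and
#' `f_B = 1.6 (1 + 0.1 sin theta + 0.3 sin 3 theta)` (with protrusions),
#' plus the ball `f = 1`.  In 3D the domain is the solid of revolution of
#' the 2D curve about the vertical axis.  The spherical target of radius
#' `a` sits at the origin (the star centre), strictly inside every shape.
#'
#' @param shape `"ball"`, `"A"` or `"B"`.
#' @param R size scale (length).
#' @param dim 2 or 3.
#' @return an object of class `rxn_domain`.
#' @export
domain_spec <- function(shape = c("ball", "A", "B"), R, dim = 3) {
  shape <- match.arg(shape)
  stopifnot(R > 0, dim %in% 2:3)
  structure(list(shape = shape, R = R, dim = as.integer(dim),
                 shape_id = match(shape, c("ball", "A", "B")) - 1L),
            class = "rxn_domain")
}

#' @export
print.rxn_domain <- function(x, ...) {
  cat(sprintf("<rxn_domain> shape %s, R = %g, %dD (volume %.4g)\n",
              x$shape, x$R, x$dim, domain_volume(x)))
  invisible(x)
}

domain_f <- function(domain, theta) {
  switch(domain$shape,
         ball = rep(1, length(theta)),
         A = 1.6 * (1 + 0.5 * cos(theta)^2),
         B = 1.6 * (1 + 0.1 * sin(theta) + 0.3 * sin(3 * theta)))
}

#' Domain volume (area in 2D)
#'
#' In 2D `V = (1/2) integral R^2 f(theta)^2 dtheta`; in 3D the revolution
#' volume `V = (2 pi / 3) integral R^3 f(pi/2 - Theta)^3 sin(Theta) dTheta`.
#'
#' @param domain an [rxn_domain].
#' @export
domain_volume <- function(domain) {
  R <- domain$R
  if (domain$dim == 2) {
    integrate(function(th) 0.5 * (R * domain_f(domain, th))^2,
              -pi, pi, rel.tol = 1e-10)$value
  } else {
    integrate(function(Th) {
      (2 * pi / 3) * (R * domain_f(domain, pi / 2 - Th))^3 * sin(Th)
    }, 0, pi, rel.tol = 1e-10)$value
  }
}

#' Point-in-domain test
#'
#' @param domain an [rxn_domain].
#' @param x numeric matrix of positions (one row per point) or a single
#'   position vector.
#' @return logical vector.
#' @export
inside_domain <- function(domain, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == domain$dim, all(is.finite(x)))
  cpp_inside_domain(domain$shape_id, domain$dim, domain$R, x)
}

#' Specular reflection at the domain boundary
#'
#' Reflects the overshooting part of the segment `from -> to` across the
#' tangent plane at the boundary crossing (located by bisection on the
#' boundary level function).  If the reflected point still falls outside
#' (a sharp concave spot), the move is rejected and `from` is returned.
#' An isotropic (radial-mirror) shortcut is *not* used: on slanted
#' boundary patches it biases the walker inward and visibly distorts the
#' stationary distribution.
#'
#' @param domain an [rxn_domain].
#' @param from current position (inside).
#' @param to proposed position.
#' @return a position inside the domain.
#' @export
reflect_boundary <- function(domain, from, to) {
  if (inside_domain(domain, to)) return(to)
  cpp_reflect_specular(domain$shape_id, domain$dim, domain$R,
                       as.numeric(from), as.numeric(to))
}

#' Brownian reaction times with an imperfect spherical target
#'
#' Euler scheme with Gaussian increments of standard deviation
#' `sqrt(2 D dt)` per axis.  The outer boundary reflects (radial mirror).
#' Sink model: the target sphere is penetrable and the walker reacts with
#' probability `1 - exp(-k dt)` per step spent inside.  Robin model: the
#' sphere is impenetrable; each attempted crossing is reflected and reacts
#' with probability `kappa sqrt(pi dt / D)`, the standard
#' `O(sqrt(dt))`-accurate surface-reaction rule.  `model = "absorbing"`
#' reacts on first contact (used for perfect-reaction references).
#'
#' @param domain an [rxn_domain].
#' @param a target radius.
#' @param model `"sink"`, `"robin"` or `"absorbing"`.
#' @param k,kappa reactivity of the chosen model.
#' @param start numeric position vector, or a matrix with one row per
#'   walker, or `"uniform"` for uniform starts in the domain outside the
#'   target (rejection sampling).
#' @param n_walkers number of walkers.
#' @param D diffusivity.
#' @param dt time step (default `1e-4 a^2/D`).
#' @param t_max censoring horizon.
#' @param seed optional seed.
#' @return an `rxn_samples` tibble.
#' @export
sample_reaction_times_bd <- function(domain, a, model = c("sink", "robin",
                                                          "absorbing"),
                                     k = NULL, kappa = NULL, start,
                                     n_walkers, D = 1, dt = 1e-4 * a^2 / D,
                                     t_max = Inf, seed = NULL) {
  model <- match.arg(model)
  stopifnot(a > 0, D > 0, dt > 0, n_walkers >= 1)
  if (!is.null(seed)) set.seed(seed)
  model_id <- c(sink = 0L, robin = 1L, absorbing = 2L)[[model]]
  rate <- switch(model, sink = k, robin = kappa, absorbing = 0)
  if (model == "sink") {
    if (is.null(k) || k <= 0) stop("sink model needs k > 0")
    if (k * dt > 0.5) stop("dt too large: k * dt must be <= 0.5")
  }
  if (model == "robin") {
    if (is.null(kappa) || kappa <= 0) stop("robin model needs kappa > 0")
    if (kappa * sqrt(pi * dt / D) > 0.5) {
      stop("dt too large: the reaction probability per reflection exceeds 0.5")
    }
  }
  if (is.character(start) && start == "uniform") {
    starts <- sample_uniform_positions(domain, n_walkers,
                                       exclude_radius = if (model == "sink") 0 else a)
  } else {
    if (is.null(dim(start))) start <- matrix(start, nrow = 1)
    stopifnot(ncol(start) == domain$dim)
    if (!all(inside_domain(domain, start))) stop("start position outside domain")
    if (model != "sink" && any(sqrt(rowSums(start^2)) < a)) {
      stop("start position inside the impenetrable target")
    }
    starts <- start[rep_len(seq_len(nrow(start)), n_walkers), , drop = FALSE]
  }
  res <- cpp_brownian_times(domain$shape_id, domain$dim, domain$R, a,
                            model_id, rate, D, dt, starts, t_max)
  out <- tibble(walker_id = seq_len(n_walkers), time = res$time,
                censored = res$censored)
  new_rxn_samples(out, list(kind = "brownian", model = model, a = a,
                            rate = rate, D = D, dt = dt, t_max = t_max,
                            domain = domain))
}

sample_uniform_positions <- function(domain, n, exclude_radius = 0) {
  R <- domain$R
  box <- R * 1.6 * 1.5
  out <- matrix(0, 0, domain$dim)
  while (nrow(out) < n) {
    cand <- matrix(runif(2 * n * domain$dim, -box, box), ncol = domain$dim)
    ok <- inside_domain(domain, cand)
    if (exclude_radius > 0) ok <- ok & sqrt(rowSums(cand^2)) >= exclude_radius
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Mean reaction time over a grid of start positions
#'
#' @inheritParams sample_reaction_times_bd
#' @param start_grid matrix of start positions (one per row).
#' @param n_walkers walkers per start position.
#' @return tibble with columns `start_r` (distance from the target centre),
#'   one row per start, plus `mean`, `se`, `n`.
#' @export
estimate_mrt_field <- function(domain, a, model, k = NULL, kappa = NULL,
                               start_grid, n_walkers, D = 1,
                               dt = 1e-4 * a^2 / D, t_max = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(start_grid)), function(i) {
    s <- sample_reaction_times_bd(domain, a, model, k = k, kappa = kappa,
                                  start = start_grid[i, , drop = FALSE],
                                  n_walkers = n_walkers, D = D, dt = dt,
                                  t_max = t_max)
    est <- estimate_mean(s)
    tibble(start_r = sqrt(sum(start_grid[i, ]^2)), mean = est$mean,
           se = est$se, n = est$n)
  })
  do.call(rbind, rows)
}

#' Radial finite-difference oracle for the mean reaction time in a ball
#'
#' Independent numerical solution of the backward equation
#' `D (T'' + (d-1)/r T') - k(r) T = -1` in a reflecting ball of radius
#' `R_outer`, with either a penetrable sink (`k(r) = k` for `r < a`) or an
#' impenetrable Robin target (`D T'(a) = kappa T(a)`).  Second-order
#' finite differences on a uniform staggered grid; used as the exact
#' reference for the Brownian simulator and for finite-volume checks of
#' the closed-form `<T>/V`.
#'
#' @param d dimension (1, 2 or 3).
#' @param model `"sink"` or `"robin"`.
#' @param k,kappa reactivity.
#' @param a target radius.
#' @param R_outer reflecting outer radius.
#' @param D diffusivity.
#' @param n_grid grid resolution.
#' @return list with `r` (grid), `T` (mean time), `interp` (function of r),
#'   and `global_mean` (volume average of T over the accessible region).
#' @export
mrt_radial_fd <- function(d, model = c("sink", "robin"), k = NULL,
                          kappa = NULL, a = 1, R_outer, D = 1,
                          n_grid = 20000) {
  model <- match.arg(model)
  stopifnot(d %in% 1:3, R_outer > a)
  r_lo <- if (model == "robin") a else 0
  h <- (R_outer - r_lo) / n_grid
  r <- r_lo + (seq_len(n_grid) - 0.5) * h     # cell centres
  kill <- if (model == "sink") ifelse(r < a, k, 0) else rep(0, n_grid)
  # flux-conservative discretization: (1/r^(d-1)) d/dr (r^(d-1) D dT/dr)
  r_face <- r_lo + seq(0, n_grid) * h
  w_face <- D * r_face^(d - 1) / h
  lower <- w_face[2:n_grid]
  main <- numeric(n_grid)
  i <- seq_len(n_grid)
  geom <- r[i]^(d - 1) * h
  main <- -(w_face[i] + w_face[i + 1]) - kill * geom
  # reflecting faces: zero flux at both ends by dropping the face weight
  main[1] <- main[1] + w_face[1]
  main[n_grid] <- main[n_grid] + w_face[n_grid + 1]
  rhs <- -geom
  if (model == "robin") {
    # Robin flux at the inner face: D T'(a) = kappa T(a); eliminate the
    # ghost value using T(a) ~ T_1 - (h/2) T'(a)
    wrob <- D * r_face[1]^(d - 1) * kappa / (D + kappa * h / 2)
    main[1] <- main[1] - wrob
  }
  M <- Matrix::bandSparse(n_grid, n_grid, k = c(-1, 0, 1),
                          diagonals = list(lower, main, lower))
  T_r <- as.numeric(Matrix::solve(M, rhs))
  vol_w <- sphere_surface(d) * r^(d - 1) * h
  list(r = r, T = T_r,
       interp = approxfun(r, T_r, rule = 2),
       global_mean = sum(T_r * vol_w) / sum(vol_w))
}
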