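test_that("domain geometry predicates behave as star-shaped sets", {
  for (shape in c("ball", "A", "B")) for (dim in 2:3) {
    dom <- domain_spec(shape, R = 4, dim = dim)
    expect_true(inside_domain(dom, rep(0, dim)))
    # points far beyond 2 R f(theta) are outside
    set.seed(1)
    dirs <- matrix(rnorm(20 * dim), ncol = dim)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    expect_true(all(!inside_domain(dom, dirs * 2 * 4 * 2.5)))
  }
  # ball volume is exact; star-shaped volumes exceed the inscribed ball
  expect_equal(domain_volume(domain_spec("ball", 2, 3)), 4 / 3 * pi * 8,
               tolerance = 1e-8)
  expect_equal(domain_volume(domain_spec("ball", 2, 2)), 4 * pi,
               tolerance = 1e-8)
  expect_gt(domain_volume(domain_spec("A", 2, 3)), 4 / 3 * pi * (1.6 * 2)^3)
})

test_that("boundary reflection is a distance-preserving local mirror", {
  dom <- domain_spec("ball", R = 5, dim = 3)
  from <- c(0, 0, 4.9)
  to <- c(0, 0, 5.06)
  ref <- reflect_boundary(dom, from, to)
  expect_equal(ref, c(0, 0, 4.94))              # mirrored across r = 5
  expect_true(inside_domain(dom, ref))
  inside <- c(0.3, 0.2, 1)
  expect_equal(reflect_boundary(dom, from, inside), inside)
})

test_that("zero reactivity never reacts and absorbing reacts quickly", {
  dom <- domain_spec("ball", R = 3, dim = 2)
  s <- sample_reaction_times_bd(dom, a = 0.5, model = "sink", k = 1e-12,
                                start = c(0, 2), n_walkers = 30, dt = 1e-3,
                                t_max = 3, seed = 2)
  expect_true(all(s$censored))
  s <- sample_reaction_times_bd(dom, a = 0.5, model = "absorbing",
                                start = c(0, 1), n_walkers = 200, dt = 1e-4,
                                t_max = 500, seed = 3)
  expect_true(!any(s$censored))
  expect_true(all(s$time > 0))
})

test_that("oversized time steps are refused", {
  dom <- domain_spec("ball", R = 3, dim = 3)
  expect_error(sample_reaction_times_bd(dom, a = 1, model = "robin",
                                        kappa = 100, start = c(0, 0, 2),
                                        n_walkers = 1, dt = 1e-3),
               "dt too large")
  expect_error(sample_reaction_times_bd(dom, a = 1, model = "sink", k = 1e4,
                                        start = c(0, 0, 2), n_walkers = 1,
                                        dt = 1e-3),
               "dt too large")
  expect_error(sample_reaction_times_bd(dom, a = 1, model = "robin",
                                        kappa = 1, start = c(0, 0, 0.5),
                                        n_walkers = 1, dt = 1e-5),
               "inside the")
})

test_that("radial FD oracle matches the analytic finite-ball Robin solution", {
  b <- 8; a <- 1; kap <- 0.7; D <- 1
  fd <- mrt_radial_fd(3, "robin", kappa = kap, a = a, R_outer = b,
                      n_grid = 8000)
  T_exact <- function(r) {
    (b^3 - a^3) / (3 * a^2 * kap) + (a^2 - r^2) / (6 * D) +
      (b^3 / 3) * (1 / a - 1 / r) / D
  }
  rs <- c(1.5, 3, 6)
  expect_equal(fd$interp(rs), T_exact(rs), tolerance = 1e-5)
  # large-volume limit approaches the closed-form <T>/V
  V <- 4 / 3 * pi * (20^3 - 1)
  fd20 <- mrt_radial_fd(3, "robin", kappa = kap, a = 1, R_outer = 20,
                        n_grid = 20000)
  expect_lt(abs(fd20$interp(5) / (V * mrt_robin(5, 3, kappa = kap)) - 1),
            0.01)
})

test_that("Brownian MRT increases with start distance and matches the oracle", {
  dom <- domain_spec("ball", R = 6, dim = 3)
  grid <- rbind(c(0, 0, 2), c(0, 0, 4.5))
  fld <- estimate_mrt_field(dom, a = 1, model = "robin", kappa = 1,
                            start_grid = grid, n_walkers = 250, dt = 4e-4,
                            seed = 4)
  expect_true(fld$mean[2] > fld$mean[1])
  fd <- mrt_radial_fd(3, "robin", kappa = 1, a = 1, R_outer = 6,
                      n_grid = 5000)
  expect_lt(abs(fld$mean[1] - fd$interp(2)), 3 * fld$se[1] + 0.03 * fd$interp(2))
  expect_lt(abs(fld$mean[2] - fd$interp(4.5)),
            3 * fld$se[2] + 0.03 * fd$interp(4.5))
})
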