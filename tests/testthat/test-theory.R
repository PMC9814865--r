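test_that("Kac return time formula and scaling", {
  expect_equal(kac_return_time(100, 2), 50)
  expect_equal(kac_return_time(2, 1), 2)       # two-site chain value
  expect_equal(kac_return_time(64, 3), 2 * kac_return_time(32, 3))
  expect_error(kac_return_time(0, 1))
  expect_error(kac_return_time(10, -1))
})

test_that("compact MRT decomposition and crossover length are consistent", {
  ex <- exponents_for("vicsek", f = 6)          # d_w - d_f = 1
  out <- mrt_compact(1:5, N = 2401, nu0 = 6, p = 1, exps = ex)
  expect_equal(out$rc, rep(0, 5))               # p = 1: DC only
  expect_equal(out$mrt, 2401 * (1:5) / 6)

  # DC term at r = 1 equals the Kac return time (alpha = 1/nu0 calibration)
  expect_equal(mrt_compact(1, 2401, 6, 0.5, ex)$dc, kac_return_time(2401, 6))

  # at r = l_c the two terms balance
  p <- 0.05
  lc <- crossover_length(p, ex)
  expect_equal(lc, 19)
  at_lc <- mrt_compact(lc, 2401, 6, p, ex)
  expect_equal(at_lc$dc, at_lc$rc)
  expect_equal(crossover_length(1, ex), 0)
  expect_equal(crossover_length(0.5, exponents_for("dual_sierpinski")), 1)

  noncom <- exponents_for("vicsek", f = 6, d_f = 3, d_w = 2)
  expect_error(mrt_compact(2, 100, 1, 0.5, noncom), "compact")
  expect_error(crossover_length(0.5, noncom), "compact")
})

test_that("reactivity threshold matches the crossover-at-system-size picture", {
  ex <- exponents_for("dual_sierpinski")
  expect_equal(reactivity_threshold(100, exponents_for("vicsek", f = 6,
                                                       d_f = 2, d_w = 4)),
               0.01)                            # d_w/d_f = 2, N = 100
  Ns <- 3^(4:8)
  ps <- vapply(Ns, reactivity_threshold, numeric(1), exps = ex)
  expect_true(all(diff(ps) < 0))
  # l_c(p*) tracks the linear size R = N^(1/d_f) up to an N-free factor
  ratio <- vapply(Ns, function(N) {
    crossover_length(reactivity_threshold(N, ex), ex) / N^(1 / ex$d_f)
  }, numeric(1))
  expect_lt(max(abs(log(ratio / ratio[1]))), 0.25)
})

test_that("zeros of J_{-nu} match the nu = 1/2 closed form and bracketing", {
  z <- phi_zeros(0.5, 25)
  expect_equal(z, (seq_len(25) - 0.5) * pi, tolerance = 1e-10)
  for (nu in c(0.3, log(7) / log(21), 0.683)) {
    z <- phi_zeros(nu, 40)
    expect_true(all(diff(z) > 0))
    expect_true(all(abs(besselJ(z, -nu)) < 1e-10))
  }
})

test_that("Phi_nu is a unit-mass density with the predicted tail slope", {
  for (nu in c(0.3, 0.5, log(7) / log(21), log(3) / log(5))) {
    expect_lt(abs(phi_integral(nu) - 1), 1e-6)
    expect_true(all(phi_universal(c(0.1, 1, 3), nu) > 0))
  }
  # large-theta decay is governed by the first zero
  nu <- log(3) / log(5)
  a0 <- phi_zeros(nu, 1)
  th <- c(4, 5)
  slope <- diff(log(phi_universal(th, nu))) / diff(th)
  expect_equal(slope, -a0^2 * nu / (2 * (1 - nu^2)), tolerance = 1e-6)
})

test_that("compact survival prediction scales correctly with p", {
  nu <- 0.68
  t <- c(0.5, 1, 2)
  s1 <- survival_compact_theory(t, mean_T = 10, tau_G = 4, nu = nu)
  s2 <- survival_compact_theory(t, mean_T = 30, tau_G = 4, nu = nu)
  expect_equal(s2 / s1, rep(3, 3))             # p enters only via the prefactor
  # integral of S equals the mean
  igr <- integrate(function(x) survival_compact_theory(x, 10, 4, nu),
                   1e-4, Inf, rel.tol = 1e-7)
  expect_equal(igr$value, 10, tolerance = 1e-3)
})

test_that("noncompact asymptotics have exponential structure and unit mass", {
  expect_equal(survival_noncompact_theory(0, 3, 12), 0.25)
  igr <- integrate(function(t) survival_noncompact_theory(t, 3, 12), 0, Inf)
  expect_equal(igr$value, 3, tolerance = 1e-6)
  expect_error(survival_noncompact_theory(1, 13, 12), "exceed")

  fd <- fpt_density_noncompact(3, 12)
  expect_equal(fd$atom, 0.75)
  expect_equal(fpt_density_noncompact(12, 12)$atom, 0)
  mass <- fd$atom + integrate(fd$density, 0, Inf)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  m1 <- integrate(function(t) t * fd$density(t), 0, Inf)$value
  expect_equal(m1, 3, tolerance = 1e-6)
})
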