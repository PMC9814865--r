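test_that("exact mean times reproduce the two-site closed forms", {
  ch <- two_site_chain()
  expect_equal(exact_mean_fpt(ch, 2), 2, tolerance = 1e-12)
  expect_equal(exact_mean_fpt(ch, 1), 1, tolerance = 1e-12)   # 1/nu0
  expect_equal(exact_mean_reaction_time(ch, 0.25, 2), 8, tolerance = 1e-12)
  expect_equal(exact_mean_reaction_time(ch, 1, 2),
               exact_mean_fpt(ch, 2))
  expect_equal(global_mean(ch, 1), 1.5, tolerance = 1e-12)
})

test_that("renewal decomposition holds to solver precision on random graphs", {
  set.seed(77)
  for (rep in 1:10) {
    net <- random_connected_graph(sample(5:50, 1))
    N <- net$n_sites
    nu0 <- site_exit_rates(net)[net$target]
    start <- sample(setdiff(seq_len(N), net$target), 1)
    tau <- exact_mean_fpt(net, start)
    for (p in c(0.05, 0.5)) {
      lhs <- exact_mean_reaction_time(net, p, start)
      rhs <- tau + (1 - p) / p * N / nu0
      expect_lt(abs(lhs - rhs) / rhs, 1e-9)
    }
    # global version of the same identity
    expect_lt(abs(global_mean(net, 0.3) -
                    (global_mean(net, 1) + (1 - 0.3) / 0.3 * N / nu0)) /
                global_mean(net, 0.3), 1e-9)
  }
})

test_that("Laplace transforms are correct and consistent with moments", {
  ch <- two_site_chain()
  s <- c(0, 0.3, 1, 4)
  expect_equal(fpt_laplace(ch, 2, s), 1 / (1 + s)^2, tolerance = 1e-12)
  expect_equal(reaction_laplace(ch, 2, 0.6, 0), 1, tolerance = 1e-12)

  net <- build_dual_sierpinski(3)
  st <- sites_at_distance(net, 3)
  # -d/ds at 0 equals the exact mean (finite differences)
  h <- 1e-5
  for (p in c(0.3, 1)) {
    der <- (reaction_laplace(net, st, p, h) -
              reaction_laplace(net, st, p, 0)) / h
    expect_equal(-der, exact_mean_reaction_time(net, p, st), tolerance = 1e-3)
  }
})

test_that("renewal identity: resolvent equals the transform composition", {
  set.seed(123)
  for (rep in 1:6) {
    net <- random_connected_graph(sample(5:50, 1))
    start <- sample(seq_len(net$n_sites), 1)
    for (p in c(0.05, 0.5, 1)) {
      s <- c(0.01, 0.1, 1, 10)
      direct <- reaction_laplace(net, start, p, s)
      composed <- reaction_laplace_renewal(net, start, p, s)
      expect_lt(max(abs(direct - composed) / direct), 1e-9)
    }
  }
})

test_that("spectral survival matches closed forms and integrates to the mean", {
  ch <- two_site_chain()
  tg <- seq(0, 8, length.out = 50)
  # the degenerate-rate convolution branch carries ~1e-8 cancellation error
  expect_equal(exact_survival(ch, 2, 1, tg)$S, (1 + tg) * exp(-tg),
               tolerance = 1e-6)

  set.seed(9)
  net <- random_connected_graph(30)
  for (p in c(0.15, 1)) {
    st <- sample(seq_len(net$n_sites), 2)
    sp <- reaction_spectrum(net, p, st)
    mean_from_spectrum <- sum(sp$weight / sp$rate)
    expect_equal(mean_from_spectrum, exact_mean_reaction_time(net, p, st),
                 tolerance = 1e-6)
    # S(0) = 1
    expect_equal(sum(sp$weight), 1, tolerance = 1e-9)
  }
})

test_that("spectral survival agrees with Monte Carlo within its bands", {
  net <- build_vicsek(4, 2)
  s <- sample_reaction_times(net, 0.3, 8e3, start_r = 2, seed = 55)
  tg <- seq(1, 600, length.out = 40)
  sv <- estimate_survival(s, tg)
  ex <- exact_survival(net, sites_at_distance(net, 2), 0.3, tg)
  expect_true(mean(abs(sv$S - ex$S) <= sv$halfwidth + 0.005) > 0.9)
})

test_that("second moments grow with generation on a compact fractal", {
  # fluctuation ratio <T^2>/<T>^2 increases with system size at fixed p
  ratios <- vapply(2:4, function(g) {
    net <- build_dual_sierpinski(g)
    st <- sites_at_distance(net, 2)
    m1 <- exact_moment(net, 0.1, st, 1)
    m2 <- exact_moment(net, 0.1, st, 2)
    m2 / m1^2
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("Talbot inversion recovers known transforms and survival curves", {
  # F(s) = 1/(1+s)^2  <->  t e^{-t}
  tg <- c(0.3, 1, 2.5)
  inv <- invert_laplace_talbot(function(s) 1 / (1 + s)^2, tg)
  expect_equal(inv, tg * exp(-tg), tolerance = 1e-8)

  net <- build_dual_sierpinski(3)
  st <- sites_at_distance(net, 3)
  tg <- c(20, 60, 150)
  tal <- survival_talbot(net, st, 0.4, tg)
  eig <- exact_survival(net, st, 0.4, tg)
  expect_equal(tal$S, eig$S, tolerance = 1e-7)
})
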