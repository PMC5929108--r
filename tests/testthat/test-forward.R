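# predicted CSD, cross-covariance, functional connectivity, kernels

test_that("scalar OU process has the Lorentzian closed form", {
  a <- 0.7
  al <- 1.3
  A <- effective_connectivity(matrix(-a, 1, 1))
  f <- c(0.01, 0.05, 0.2)
  g <- predicted_csd(A, fluctuation_params(al, 0), hemo = NULL,
                     grid = frequency_grid(f), obs_noise = NULL)
  w <- 2 * pi * f
  expect_equal(Re(g$values[, 1, 1]), al / (a^2 + w^2), tolerance = 1e-12)
  expect_equal(max(abs(Im(g$values))), 0)
})

test_that("decoupled identical nodes have exactly zero cross-spectra", {
  A <- effective_connectivity(diag(-0.5, 4), tiny_regions(4))
  g <- predicted_csd(A, grid = default_frequency_grid())
  for (k in seq_along(g$grid$frequencies)) {
    s <- g$values[k, , ]
    expect_equal(max(Mod(s[row(s) != col(s)])), 0)
  }
})

test_that("spectral integration matches the Lyapunov stationary covariance", {
  # beta = 0, unit observation kernel: the integral of the predicted CSD
  # over frequency must equal the solution of A S + S A' + alpha I = 0
  for (n in c(2, 3, 5, 10)) {
    A <- random_stable_A(n, seed = 100 + n)
    g <- predicted_csd(effective_connectivity(A, check = FALSE),
                       fluctuation_params(1, 0), hemo = NULL,
                       grid = wide_grid(), obs_noise = NULL)
    C0 <- csd_to_cross_covariance(g, lags = 0)$values[1, , ]
    S <- lyapunov_cov(A, 1)
    expect_lt(norm(C0 - S, "F") / norm(S, "F"), 0.01)
  }
})

test_that("every predicted slice is Hermitian and positive semidefinite", {
  A <- effective_connectivity(random_stable_A(5, seed = 7), check = FALSE)
  g <- predicted_csd(A, fluctuation_params(1, 1),
                     grid = default_frequency_grid())
  for (k in seq(1, 64, by = 9)) {
    s <- g$values[k, , ]
    expect_lt(max(Mod(s - Conj(t(s)))), 1e-12 * max(Mod(s)))
    expect_gt(min(Re(eigen(s, only.values = TRUE)$values)),
              -1e-8 * max(Mod(s)))
  }
})

test_that("Lorentzian cross-covariance decays as exp(-a |tau|)", {
  a <- 0.8
  al <- 2
  A <- effective_connectivity(matrix(-a, 1, 1))
  g <- predicted_csd(A, fluctuation_params(al, 0), hemo = NULL,
                     grid = wide_grid(), obs_noise = NULL)
  cc <- csd_to_cross_covariance(g, lags = c(0, 1, 2))
  expect_equal(cc$values[, 1, 1], al / (2 * a) * exp(-a * c(0, 1, 2)),
               tolerance = 0.02)
})

test_that("cross-covariance honours the time-reversal identity", {
  A <- effective_connectivity(random_stable_A(3, seed = 5), check = FALSE)
  g <- predicted_csd(A, grid = default_frequency_grid())
  cc <- csd_to_cross_covariance(g, lags = seq(-8, 8, by = 2))
  nlag <- length(cc$lags)
  for (li in seq_len(nlag)) {
    rev_li <- nlag + 1 - li
    expect_equal(cc$values[li, , ], t(cc$values[rev_li, , ]),
                 tolerance = 1e-12)
  }
})

test_that("a flat spectrum concentrates covariance at lag zero", {
  g <- csd(array(1 + 0i, c(2000, 1, 1)),
           frequency_grid(seq(0.001, 2, length.out = 2000)))
  cc <- csd_to_cross_covariance(g, lags = c(0, 4, 8))
  expect_lt(abs(cc$values[2, 1, 1]) / cc$values[1, 1, 1], 0.05)
  expect_lt(abs(cc$values[3, 1, 1]) / cc$values[1, 1, 1], 0.05)
})

test_that("lags beyond the aliasing limit are rejected", {
  g <- predicted_csd(effective_connectivity(matrix(-1, 1, 1)),
                     grid = default_frequency_grid())
  expect_error(csd_to_cross_covariance(g, lags = 1000), "aliasing")
})

test_that("decoupled nodes give identity functional connectivity", {
  A <- effective_connectivity(diag(c(-0.4, -0.6, -0.8)), tiny_regions(3))
  g <- predicted_csd(A, grid = frequency_grid(seq(0.002, 4, length.out = 1000)))
  fc <- functional_connectivity(g)
  expect_equal(unname(fc$values), diag(3), tolerance = 1e-12)
})

test_that("model FC of the default template is anticorrelated across blocks", {
  A <- make_template_A()
  g <- predicted_csd(A, grid = frequency_grid(seq(0.002, 2,
                                                  length.out = 1500)))
  fc <- functional_connectivity(g)
  B <- block_means(fc$values, load_region_fixture()$network)
  expect_lt(B["cDN", "SN"], 0)
  expect_lt(B["cDN", "DAN"], 0)
  expect_gt(B["cDN", "cDN"], 0)
  expect_gt(B["SN", "SN"], 0)
  expect_gt(B["DAN", "DAN"], 0)
  expect_gt(B["SN", "DAN"], 0)
})

test_that("model FC agrees with the empirical correlation of a long run", {
  # white endogenous noise: a mixing process whose sample correlations
  # converge at root-T (1/f drive makes single-run correlations too
  # variable for a tight entrywise check; its spectrum is tested above).
  # The model grid stops at the sampling Nyquist so noise bandwidths match.
  reg <- tiny_regions(3)
  Am <- matrix(c(-0.5, -0.2, 0.25, 0.3, -0.5, 0, 0, 0.15, -0.5), 3, 3)
  A <- effective_connectivity(Am, reg)
  wh <- fluctuation_params(1, 0)
  fc_model <- functional_connectivity(
    predicted_csd(A, fluct = wh,
                  grid = frequency_grid(seq(1e-4, 0.5, length.out = 3000))))
  ts <- simulate_bold(A, fluct = wh, T = 8192, dt = 1, seed = 21)
  fc_emp <- empirical_fc(ts)
  expect_lt(max(abs(fc_model$values - fc_emp$values)), 0.05)
})

test_that("an asymmetric one-way connection still yields symmetric dense FC", {
  # the degenerate cause->effect mapping: absence of a coupling entry does
  # not imply absence of correlation
  A <- effective_connectivity(rbind(c(-0.5, 0), c(0.4, -0.5)),
                              tiny_regions(2))
  fc <- functional_connectivity(
    predicted_csd(A, grid = frequency_grid(seq(0.001, 2, length.out = 1500))))
  expect_gt(fc$values[1, 2], 0.1)
  expect_equal(fc$values[1, 2], fc$values[2, 1])
})

test_that("connection kernels follow the closed forms", {
  # diagonal coupling: no cross-kernel
  A <- effective_connectivity(diag(c(-0.4, -0.7)), tiny_regions(2))
  k12 <- connection_kernel(A, source = "r1", target = "r2")
  expect_equal(max(abs(k12)), 0)
  # single node: haemodynamic kernel convolved with exp(-a t)
  a <- 0.5
  A1 <- effective_connectivity(matrix(-a, 1, 1))
  tsp <- seq(0, 30, by = 0.5)
  k <- connection_kernel(A1, source = 1, target = 1, tspan = tsp,
                         dt_fine = 0.01)
  tg <- seq(0, 30, by = 0.01)
  oracle <- stats::convolve(exp(-a * tg),
                            rev(hemodynamic_kernel(hemodynamic_params(), tg)),
                            type = "open")[seq_along(tg)] * 0.01
  expect_equal(k, stats::approx(tg, oracle, tsp)$y, tolerance = 1e-3)
})

test_that("kernels of stable systems decay to zero", {
  A <- make_template_A()
  k <- connection_kernel(A, source = "rAI", target = "PCC",
                         tspan = seq(0, 100, by = 0.5))
  expect_lt(max(abs(k[seq(0, 100, by = 0.5) > 60])), 1e-3 * max(abs(k)))
})
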