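# variational Laplace inversion on small systems with exactly known truth

make_synthetic_csd <- function(A, T = 2048, dt = 1, order = 16, seed = 1) {
  ts <- simulate_bold(A, T = T, dt = dt, seed = seed)
  estimate_csd(ts, default_frequency_grid(T, dt), order = order)
}

test_that("data generated at the prior mean leave the posterior near it", {
  reg <- tiny_regions(3)
  pri <- default_priors(reg)
  # forward-predict at the prior mean itself and invert that exact spectrum
  A0 <- effective_connectivity(diag(-0.5, 3), reg)
  g <- predicted_csd(A0, fluctuation_params(1, 1),
                     grid = default_frequency_grid(512, 1))
  post <- invert_spectral_dcm(g, pri)
  free <- pri$var > 0
  z <- abs(post$M[free] - pri$mean[free]) / sqrt(pri$var[free])
  expect_true(all(z < 2))
})

test_that("free energy is monotone over accepted iterations", {
  reg <- tiny_regions(2)
  A <- effective_connectivity(rbind(c(-0.5, 0.2), c(-0.3, -0.5)), reg)
  g <- make_synthetic_csd(A, T = 1024, seed = 3)
  post <- invert_spectral_dcm(g, default_priors(reg))
  expect_true(all(diff(post$Fhist) >= -1e-8))
  expect_true(post$converged)
})

test_that("posterior contracts relative to the prior (information gain)", {
  reg <- tiny_regions(3)
  Am <- matrix(c(-0.5, -0.2, 0.25, 0.3, -0.5, 0, 0, 0.15, -0.5), 3, 3)
  A <- effective_connectivity(Am, reg)
  g <- make_synthetic_csd(A, seed = 17)
  pri <- default_priors(reg)
  post <- invert_spectral_dcm(g, pri)
  free <- pri$var > 0
  expect_true(all(diag(post$Sigma)[free] <= pri$var[free] + 1e-6))
  # fixed parameters stay exactly at the prior
  expect_true(all(post$M[!free] == pri$mean[!free]))
  expect_true(all(diag(post$Sigma)[!free] == 0))
})

test_that("recovery improves with data length on a fixed benchmark", {
  reg <- tiny_regions(3)
  Am <- matrix(c(-0.5, -0.2, 0.25, 0.3, -0.5, 0, 0, 0.15, -0.5), 3, 3)
  A <- effective_connectivity(Am, reg)
  offd <- Am[row(Am) != col(Am)]
  corr_at <- function(T) {
    cs <- vapply(1:3, function(s) {
      g <- make_synthetic_csd(A, T = T, seed = 30 + s)
      post <- invert_spectral_dcm(g, default_priors(reg))
      cor(offd, post$M[startsWith(names(post$M), "A[")])
    }, numeric(1))
    mean(cs)
  }
  cors <- c(corr_at(256), corr_at(1024), corr_at(4096))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.9)
})

test_that("free_energy reproduces the fitted objective and its geometry", {
  reg <- tiny_regions(2)
  A <- effective_connectivity(rbind(c(-0.5, 0.2), c(-0.3, -0.5)), reg)
  g <- make_synthetic_csd(A, T = 1024, seed = 5)
  pri <- default_priors(reg)
  post <- invert_spectral_dcm(g, pri)
  # consistency with the returned optimum
  fe <- free_energy(g, pri, post$M, post$Sigma)
  expect_equal(as.numeric(fe), post$F, tolerance = 1e-6)
  # local optimum: perturbing one coordinate by +5 posterior SD decreases F
  free <- which(pri$var > 0)
  j <- free[1]
  m2 <- post$M
  m2[j] <- m2[j] + 5 * sqrt(post$Sigma[j, j])
  expect_lt(as.numeric(free_energy(g, pri, m2, post$Sigma)), post$F)
  # KL(q||p) = 0 when the candidate is the prior itself
  fe0 <- free_energy(g, pri, pri$mean)
  expect_equal(attr(fe0, "complexity"), 0)
  # fitting beats the prior-only evaluation on informative data
  expect_gt(post$F, as.numeric(fe0))
})
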