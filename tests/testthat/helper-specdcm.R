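# shared fixtures and independent oracles

tiny_regions <- function(n = 3) {
  region_set(paste0("r", seq_len(n)),
             c("n1", "n1", rep("n2", max(0, n - 2)))[seq_len(n)])
}

# random stable coupling matrix: random entries shifted so the spectral
# abscissa sits at -margin
random_stable_A <- function(n, seed, margin = 0.3, scale = 0.3) {
  withr::with_seed(seed, {
    R <- matrix(stats::rnorm(n * n, 0, scale), n, n)
    shift <- max(Re(eigen(R, only.values = TRUE)$values))
    A <- R - (shift + margin) * diag(n)
    diag(A) <- pmin(diag(A), -0.05)
    A
  })
}

# stationary covariance of dx = A x dt + sqrt(alpha) dW by direct solution
# of the Lyapunov equation A S + S A' + alpha I = 0 (vectorised oracle)
lyapunov_cov <- function(A, alpha = 1) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  matrix(solve(K, -alpha * as.vector(diag(n))), n, n)
}

# block means of a matrix by network (row = target, col = source),
# excluding the diagonal within networks
block_means <- function(M, networks) {
  nets <- unique(networks)
  B <- matrix(NA_real_, length(nets), length(nets),
              dimnames = list(nets, nets))
  for (a in nets) for (b in nets) {
    x <- M[networks == a, networks == b, drop = FALSE]
    if (a == b) x <- x[row(x) != col(x)]
    B[a, b] <- mean(x)
  }
  B
}

# wide dense grid for spectral integrals (covariance oracles): dense at low
# frequency (where stable-system spectra concentrate), extended far into the
# tail so the truncated mass is negligible
wide_grid <- function(fmax = 100, nlow = 4000, nhigh = 16000) {
  frequency_grid(c(seq(1e-4, 0.999, length.out = nlow),
                   seq(1, fmax, length.out = nhigh)))
}

# analytic evidence of the conjugate linear-Gaussian model
# y = Z theta + e, e ~ N(0, s2 I), theta ~ N(m0, V0)
conjugate_model <- function(y, Z, s2, m0, V0) {
  n <- length(y)
  S <- s2 * diag(n) + Z %*% V0 %*% t(Z)
  r <- y - Z %*% m0
  logZ <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                    drop(t(r) %*% solve(S, r)))
  Pi <- solve(V0) + crossprod(Z) / s2
  Sg <- solve(Pi)
  mg <- drop(Sg %*% (solve(V0, m0) + crossprod(Z, y) / s2))
  list(logZ = as.numeric(logZ), mean = mg, cov = Sg)
}

# a conjugate regression problem together with its reduced form, for
# checking closed-form model reduction against direct inversion
make_conjugate_case <- function(P, seed, pin = NULL) {
  withr::with_seed(seed, {
    n <- 6 * P
    Z <- matrix(rnorm(n * P), n, P)
    theta <- rnorm(P, 0, 0.4)
    s2 <- 0.5
    y <- drop(Z %*% theta) + rnorm(n, 0, sqrt(s2))
  })
  m0 <- numeric(P)
  V0 <- diag(1 / 16, P)
  full <- conjugate_model(y, Z, 0.5, m0, V0)
  vr <- rep(1 / 16, P)
  if (is.null(pin)) pin <- 1
  vr[pin] <- 1e-8
  red <- conjugate_model(y, Z, 0.5, m0, diag(vr, P))
  list(post = list(M = full$mean, Sigma = full$cov),
       full_prior = list(mean = m0, var = rep(1 / 16, P)),
       red_prior = list(mean = m0, var = vr),
       dF_direct = red$logZ - full$logZ,
       red_mean = red$mean, red_cov = red$cov)
}
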