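# First-level model inversion: variational Laplace (fixed-form Gaussian)
# ascent on a free-energy bound, fitting the predicted cross-spectral
# density to an observed one.

# model spec list consumed by the compiled prediction/Jacobian kernel
model_spec_list <- function(map, omega) {
  bases <- attr(map, "bases")
  hemo <- attr(map, "hemo")
  list(n = attr(map, "n"), omega = omega,
       kappa = hemo$decay, gamma = hemo$feedback,
       stiffness = hemo$stiffness, extraction = hemo$extraction,
       v0 = hemo$v0,
       alpha_v = bases$alpha_v, beta_v = bases$beta_v,
       alpha_e = bases$alpha_e, beta_e = bases$beta_e,
       transit = hemo$transit)
}

# stacked real features of a csd object (Re upper incl diag, Im strict upper)
csd_feature_vector <- function(x) {
  cpp_csd_features(aperm(x$values, c(2, 3, 1)))
}

# per-frequency feature weights: residuals are scaled by the mean diagonal
# magnitude of the data CSD at each frequency, approximating the
# magnitude-proportional sampling error of spectral estimates
csd_feature_weights <- function(x) {
  n <- dim(x$values)[2]
  sk <- vapply(seq_len(dim(x$values)[1]), function(k)
    mean(Re(diag(matrix(x$values[k, , ], n)))), numeric(1))
  sk <- pmax(sk, 1e-8 * max(sk))
  rep(1 / sk, each = n * n)
}

inversion_settings <- function(settings = list()) {
  utils::modifyList(
    list(max_iter = 128L, tol = 0.01, consecutive = 4L, fd_step = 1e-4,
         damp0 = 1e-4, lambda0 = 0,
         lambda_prior_mean = 4, lambda_prior_var = 16),
    settings)
}

# profile optimum of the log-precision hyperparameter given an effective SSE
# (clamped to a wide bracket: a near-perfect fit drives the optimum to the
# upper end rather than to infinity)
opt_lambda <- function(nfeat, sse, s) {
  g <- function(l) nfeat / 2 - exp(l) * sse / 2 -
    (l - s$lambda_prior_mean) / s$lambda_prior_var
  if (g(30) >= 0) return(30)
  if (g(-30) <= 0) return(-30)
  stats::uniroot(g, c(-30, 30), tol = 1e-12)$root
}

# free-energy pieces given weighted residual e, trace term, KL of q against
# the prior restricted to free parameters
fe_pieces <- function(e, trace_term, lambda, d_free, Pi0, Sq, s) {
  nfeat <- length(e)
  sse <- sum(e^2) + trace_term
  accuracy <- -0.5 * exp(lambda) * sse +
    0.5 * nfeat * (lambda - log(2 * pi)) -
    (lambda - s$lambda_prior_mean)^2 / (2 * s$lambda_prior_var)
  ld <- as.numeric(determinant(Pi0 %*% Sq, logarithm = TRUE)$modulus)
  complexity <- 0.5 * (sum(d_free * (Pi0 %*% d_free)) +
                         sum(diag(Pi0 %*% Sq)) - ld - length(d_free))
  list(F = accuracy - complexity, accuracy = accuracy,
       complexity = as.numeric(complexity))
}

#' Invert a spectral model by variational Laplace
#'
#' Estimates the posterior density over coupling, fluctuation and
#' haemodynamic parameters from an observed cross-spectral density.
#' The observation model places independent Gaussians on the stacked real
#' and imaginary CSD entries (weighted per frequency by the magnitude of
#' the data spectrum) with a single shared log-precision hyperparameter
#' estimated alongside. Optimisation is Gauss-Newton ascent on the
#' variational free energy with Levenberg-Marquardt regularisation; steps
#' are only accepted when they increase the free energy, so the returned
#' trajectory is non-decreasing. Derivatives are central finite differences.
#'
#' @param x a [csd()] estimated from data (see [estimate_csd()]).
#' @param priors a [default_priors()] object.
#' @param settings named list overriding `max_iter` (128), `tol` (0.01 on
#'   consecutive free-energy changes), `consecutive` (4), `fd_step` (1e-4),
#'   and the log-precision hyperprior (`lambda_prior_mean` 4,
#'   `lambda_prior_var` 16).
#' @return An object of class `dcm_posterior`: named posterior mean `M`,
#'   covariance `Sigma` (zero rows/columns for fixed parameters), free
#'   energy `F` with `accuracy`/`complexity` components, hyperparameter
#'   `lambda`, convergence flag and the accepted free-energy trajectory.
#' @export
invert_spectral_dcm <- function(x, priors, settings = list()) {
  stopifnot(inherits(x, "csd"), inherits(priors, "dcm_priors"))
  s <- inversion_settings(settings)
  map <- priors$map
  if (attr(map, "n") != dim(x$values)[2])
    stop("priors are dimensioned for ", attr(map, "n"),
         " regions but the CSD has ", dim(x$values)[2])
  omega <- 2 * pi * x$grid$frequencies
  ms <- model_spec_list(map, omega)
  wt <- csd_feature_weights(x)
  yw <- csd_feature_vector(x) * wt
  nfeat <- length(yw)

  free <- which(priors$var > 0)
  Pf <- length(free)
  Pi0 <- diag(1 / priors$var[free], Pf)
  m <- priors$mean
  lambda <- s$lambda0
  damp <- s$damp0
  Fcur <- -Inf
  Fhist <- numeric(0)
  converged <- FALSE
  J <- NULL

  for (it in seq_len(s$max_iter)) {
    J <- cpp_feature_jacobian(m, ms, free, s$fd_step) * wt
    e <- yw - cpp_predict_features(m, ms) * wt
    JtJ <- crossprod(J)
    d_free <- (m - priors$mean)[free]
    fe_at <- function(lam) {
      Sl <- chol_solve(exp(lam) * JtJ + Pi0)
      fe_pieces(e, sum(JtJ * Sl), lam, d_free, Pi0, Sl, s)$F
    }
    # guarded hyperparameter update: adopt the profile optimum only when it
    # does not lower the objective at the current mean (keeps F monotone)
    Sq <- chol_solve(exp(lambda) * JtJ + Pi0)
    lam_new <- opt_lambda(nfeat, sum(e^2) + sum(JtJ * Sq), s)
    if (fe_at(lam_new) >= fe_at(lambda)) lambda <- lam_new
    Fcur <- max(Fcur, fe_at(lambda))
    Fprev <- Fcur

    H <- exp(lambda) * JtJ + Pi0
    grad <- exp(lambda) * crossprod(J, e) - Pi0 %*% (m[free] - priors$mean[free])
    accepted <- FALSE
    for (tries in 1:8) {
      dm <- solve(H + damp * diag(diag(H), Pf), grad)
      mn <- m
      mn[free] <- mn[free] + dm
      en <- yw - cpp_predict_features(mn, ms) * wt
      Sn <- chol_solve(H)
      pieces <- fe_pieces(en, sum(JtJ * Sn), lambda,
                          (mn - priors$mean)[free], Pi0, Sn, s)
      if (pieces$F > Fcur) {
        m <- mn
        Fcur <- pieces$F
        damp <- max(damp / 2, 1e-8)
        accepted <- TRUE
        break
      }
      damp <- damp * 8
    }
    Fhist <- c(Fhist, Fcur)
    if (!accepted && Fcur - Fprev < s$tol && it > 1) {
      converged <- TRUE   # neither a mean step nor the hyperparameter helps
      break
    }
    converged <- it > s$consecutive &&
      all(abs(diff(utils::tail(Fhist, s$consecutive + 1))) < s$tol)
    if (converged) break
  }
  if (!converged)
    warning("free-energy ascent did not converge within ", s$max_iter,
            " iterations; returning best iterate")

  # final consistent evaluation: J at the final mean, (lambda, Sigma) at
  # their joint fixed point, F from the same evaluator used by free_energy()
  J <- cpp_feature_jacobian(m, ms, free, s$fd_step) * wt
  e <- yw - cpp_predict_features(m, ms) * wt
  JtJ <- crossprod(J)
  for (k in 1:64) {
    Sq <- chol_solve(exp(lambda) * JtJ + Pi0)
    lnew <- opt_lambda(nfeat, sum(e^2) + sum(JtJ * Sq), s)
    if (abs(lnew - lambda) < 1e-12) { lambda <- lnew; break }
    lambda <- lnew
  }
  Sq <- chol_solve(exp(lambda) * JtJ + Pi0)
  Sq <- repair_psd(Sq)
  pieces <- fe_pieces(e, sum(JtJ * Sq), lambda,
                      (m - priors$mean)[free], Pi0, Sq, s)

  P <- length(priors$mean)
  Sigma <- matrix(0, P, P, dimnames = list(map$name, map$name))
  Sigma[free, free] <- Sq
  structure(list(M = stats::setNames(m, map$name), Sigma = Sigma,
                 F = pieces$F, accuracy = pieces$accuracy,
                 complexity = pieces$complexity,
                 lambda = lambda, converged = converged,
                 iterations = length(Fhist), Fhist = Fhist,
                 map = map, priors = priors, settings = s),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf(
    "<dcm_posterior> %d parameters, F = %.2f, %d iterations (%sconverged)\n",
    length(x$M), x$F, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Evaluate the variational free energy at a candidate density
#'
#' Returns the same objective [invert_spectral_dcm()] maximises, evaluated
#' at a candidate Gaussian `N(mean, cov)` over the parameters: expected
#' log-likelihood of the weighted CSD features (with the log-precision
#' hyperparameter at its profile optimum) minus the KL divergence from the
#' prior. Deterministic given `(x, priors, mean, cov)`. Evaluated at the
#' prior itself the complexity term is exactly zero.
#'
#' @inheritParams invert_spectral_dcm
#' @param mean candidate parameter means (full-length, named or not).
#' @param cov candidate covariance over all parameters (or the free subset);
#'   defaults to the prior covariance.
#' @param lambda optional fixed log-precision; profile-optimised if `NULL`.
#' @return Scalar free energy with attributes `accuracy`, `complexity`,
#'   `lambda`.
#' @export
free_energy <- function(x, priors, mean, cov = NULL, lambda = NULL,
                        settings = list()) {
  stopifnot(inherits(x, "csd"), inherits(priors, "dcm_priors"))
  s <- inversion_settings(settings)
  map <- priors$map
  omega <- 2 * pi * x$grid$frequencies
  ms <- model_spec_list(map, omega)
  wt <- csd_feature_weights(x)
  yw <- csd_feature_vector(x) * wt
  free <- which(priors$var > 0)
  Pf <- length(free)
  P <- length(priors$mean)
  if (length(mean) != P) stop("`mean` must have length ", P)
  if (is.null(cov)) cov <- diag(priors$var, P)
  cov <- as.matrix(cov)
  Sq <- if (nrow(cov) == P) cov[free, free, drop = FALSE] else cov
  if (nrow(Sq) != Pf) stop("`cov` must cover all or the free parameters")
  Pi0 <- diag(1 / priors$var[free], Pf)
  J <- cpp_feature_jacobian(mean, ms, free, s$fd_step) * wt
  e <- yw - cpp_predict_features(mean, ms) * wt
  JtJ <- crossprod(J)
  trace_term <- sum(JtJ * Sq)
  if (is.null(lambda))
    lambda <- opt_lambda(length(yw), sum(e^2) + trace_term, s)
  pieces <- fe_pieces(e, trace_term, lambda, (mean - priors$mean)[free],
                      Pi0, Sq, s)
  structure(pieces$F, accuracy = pieces$accuracy,
            complexity = pieces$complexity, lambda = lambda)
}

# solve for the inverse of a symmetric positive definite matrix via Cholesky
chol_solve <- function(M) {
  R <- chol((M + t(M)) / 2)
  chol2inv(R)
}

# floor eigenvalues to restore positive semidefiniteness (warns when needed)
repair_psd <- function(S, floor_frac = 1e-12) {
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < 0) {
    warning("posterior covariance had negative eigenvalues; floored")
    fl <- floor_frac * max(eg$values)
    S <- eg$vectors %*% (pmax(eg$values, fl) * t(eg$vectors))
    S <- (S + t(S)) / 2
  }
  S
}
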