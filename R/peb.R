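# Parametric empirical Bayes: a hierarchical Gaussian model in which a
# between-subject design matrix generates the subject-level connectivity
# parameters with additive random effects.

#' Fit a parametric empirical Bayes model over subject posteriors
#'
#' Second-level model `theta_i = (x_i' (x) I) beta + eps_i`,
#' `eps_i ~ N(0, exp(-lambda) Q)`, where `theta_i` is subject `i`'s
#' first-level parameter vector. Each subject enters through its full
#' first-level posterior - both the expected strength of every connection
#' and the associated uncertainty - so precise subjects carry more weight.
#' The between-subject log-precision `lambda` is estimated by maximising
#' the (Laplace) free energy of the hierarchical model; the group-level
#' coefficients `beta` get a Gaussian prior built from the first-level
#' prior for the group-mean column and zero-mean priors for covariates.
#'
#' @param subject_posteriors list of first-level posteriors
#'   ([invert_spectral_dcm()] results, or lists with `M` and `Sigma`).
#' @param X design matrix (subjects x effects); the first column must be the
#'   group mean (all ones). Covariate columns are mean-centred; collinear
#'   designs are rejected with the offending columns named.
#' @param Q between-subject precision components; currently a single
#'   component, defaulting to the identity over the selected parameters.
#' @param settings list: `params` (names or indices of the parameters taken
#'   to the second level; default all `A[...]` and `self[...]` parameters -
#'   the full intrinsic connectivity), `beta_prior_var` (covariate columns;
#'   default 1/64), `lambda_range` (search interval for the between-subject
#'   log-precision, default `c(-8, 8)`), `flat_beta_prior` (if `TRUE`, an
#'   improper flat prior on beta).
#' @return An object of class `peb_result`: `beta` (matrix parameters x
#'   effects), `Sigma_beta`, `lambda`, `F`, `params`, `X`, `map`.
#' @export
peb_fit <- function(subject_posteriors, X = NULL, Q = NULL,
                    settings = list()) {
  s <- utils::modifyList(
    list(params = NULL, beta_prior_var = 1 / 64,
         lambda_range = c(-8, 8), flat_beta_prior = FALSE),
    settings)
  N <- length(subject_posteriors)
  if (N < 1) stop("need at least one subject posterior")
  g1 <- gaussian_parts(subject_posteriors[[1]])
  nm <- names(g1$mean)

  if (is.null(X)) X <- matrix(1, N, 1)
  X <- as.matrix(X)
  if (nrow(X) != N) stop("`X` must have one row per subject")
  if (!all(X[, 1] == 1)) stop("first column of `X` must be the group mean (ones)")
  if (ncol(X) > 1) {
    X[, -1] <- sweep(X[, -1, drop = FALSE], 2,
                     colMeans(X[, -1, drop = FALSE]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
      cn <- colnames(X)
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(if (is.null(cn)) bad else cn[bad], collapse = ", "))
    }
  }
  K <- ncol(X)

  sel <- s$params
  if (is.null(sel)) {
    sel <- if (!is.null(nm))
      which(startsWith(nm, "A[") | startsWith(nm, "self["))
    else seq_along(g1$mean)
  } else if (is.character(sel)) {
    sel <- match(sel, nm)
  }
  p <- length(sel)
  if (!p) stop("no parameters selected for the second level")

  Ms <- lapply(subject_posteriors, function(po) gaussian_parts(po)$mean[sel])
  Ss <- lapply(subject_posteriors, function(po) {
    S <- as.matrix(gaussian_parts(po)$cov)[sel, sel, drop = FALSE]
    # guard against exactly singular first-level covariances
    S + 1e-8 * mean(diag(S)) * diag(p)
  })
  if (is.null(Q)) Q <- diag(p)

  # prior on beta: group-mean column inherits the first-level prior where
  # available; covariates are zero-centred with beta_prior_var
  prior1 <- subject_posteriors[[1]]$priors
  if (!is.null(prior1) && inherits(prior1, "dcm_priors")) {
    b0_mean <- prior1$mean[sel]
    b0_var <- pmax(prior1$var[sel], 1e-8)
  } else {
    b0_mean <- numeric(p)
    b0_var <- rep(1 / 64, p)
  }
  beta0 <- c(b0_mean, rep(0, p * (K - 1)))
  beta0_var <- c(b0_var, rep(s$beta_prior_var, p * (K - 1)))

  fit_given_lambda <- function(lam) {
    Sb <- exp(-lam) * Q
    Si_inv <- lapply(Ss, function(S) chol_solve(S + Sb))
    Pi_b <- matrix(0, K * p, K * p)
    rhs <- numeric(K * p)
    for (i in seq_len(N)) {
      xi <- X[i, ]
      Pi_b <- Pi_b + kronecker(tcrossprod(xi), Si_inv[[i]])
      rhs <- rhs + kronecker(xi, drop(Si_inv[[i]] %*% Ms[[i]]))
    }
    if (!s$flat_beta_prior) {
      Pi_b <- Pi_b + diag(1 / beta0_var, K * p)
      rhs <- rhs + beta0 / beta0_var
    }
    Sigma_b <- chol_solve(Pi_b)
    beta <- drop(Sigma_b %*% rhs)
    # Laplace free energy of the hierarchical model
    Fv <- 0
    for (i in seq_len(N)) {
      ei <- Ms[[i]] - drop(kronecker(t(X[i, ]), diag(p)) %*% beta)
      Fv <- Fv - 0.5 * (logdet_chol2pi(Ss[[i]], Sb) +
                          sum(ei * (Si_inv[[i]] %*% ei)) +
                          sum((kronecker(tcrossprod(X[i, ]), Si_inv[[i]]) *
                                 Sigma_b)))
    }
    if (!s$flat_beta_prior) {
      d <- beta - beta0
      Fv <- Fv - 0.5 * (sum(d^2 / beta0_var) +
                          sum(diag(Sigma_b) / beta0_var) -
                          logdet_chol(Sigma_b) - sum(log(beta0_var)) -
                          K * p)
    } else {
      Fv <- Fv + 0.5 * logdet_chol(Sigma_b) + 0.5 * K * p * log(2 * pi)
    }
    # weak hyperprior on the between-subject log precision
    Fv <- Fv - lam^2 / 32
    list(F = Fv, beta = beta, Sigma_b = Sigma_b)
  }

  opt <- stats::optimize(function(l) fit_given_lambda(l)$F,
                         interval = s$lambda_range, maximum = TRUE,
                         tol = 1e-4)
  lam <- opt$maximum
  fin <- fit_given_lambda(lam)
  beta <- matrix(fin$beta, p, K,
                 dimnames = list(if (!is.null(nm)) nm[sel] else NULL,
                                 colnames(X, do.NULL = FALSE, prefix = "x")))
  structure(list(beta = beta, Sigma_beta = fin$Sigma_b, lambda = lam,
                 F = fin$F, params = sel,
                 param_names = if (!is.null(nm)) nm[sel] else NULL,
                 X = X, N = N,
                 map = subject_posteriors[[1]]$map,
                 prior_mean = beta0[seq_len(p)],
                 prior_var = beta0_var[seq_len(p)]),
            class = "peb_result")
}

logdet_chol2pi <- function(S, Sb) {
  M <- S + Sb
  nrow(M) * log(2 * pi) + logdet_chol(M)
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf(
    "<peb_result> %d subjects, %d parameters x %d effects, lambda = %.2f, F = %.1f\n",
    x$N, nrow(x$beta), ncol(x$beta), x$lambda, x$F))
  invisible(x)
}

#' Group-level posterior from a PEB fit
#'
#' Extracts the posterior over one design-matrix column's effects (by
#' default the group mean) as a Gaussian posterior suitable for
#' [greedy_search()], [bma()], [retention_mask()] and
#' [between_network_average()].
#'
#' @param peb a [peb_fit()] result.
#' @param effect design-matrix column (default 1, the group mean).
#' @return A `dcm_posterior`-like list with `M`, `Sigma`, `map`, and the
#'   implied group-level prior as attribute `prior`.
#' @export
peb_group_posterior <- function(peb, effect = 1) {
  stopifnot(inherits(peb, "peb_result"))
  p <- nrow(peb$beta)
  idx <- (effect - 1) * p + seq_len(p)
  M <- stats::setNames(peb$beta[, effect], rownames(peb$beta))
  Sigma <- peb$Sigma_beta[idx, idx, drop = FALSE]
  dimnames(Sigma) <- list(rownames(peb$beta), rownames(peb$beta))
  prior <- list(mean = stats::setNames(
    if (effect == 1) peb$prior_mean else numeric(p), rownames(peb$beta)),
    var = stats::setNames(peb$prior_var, rownames(peb$beta)))
  out <- list(M = M, Sigma = Sigma, F = peb$F, map = peb$map, priors = prior)
  class(out) <- "dcm_posterior"
  attr(out, "prior") <- prior
  out
}

#' Subject-level posterior implied by the group model
#'
#' Empirical-Bayes shrinkage: combines a subject's first-level posterior
#' with the group-level density as a prior, pulling each subject's
#' parameters toward the group mean in proportion to their first-level
#' uncertainty.
#'
#' @param peb a [peb_fit()] result.
#' @param subject_post the subject's first-level posterior.
#' @param subject index of the subject's row in the design matrix.
#' @return List with `M` and `Sigma` over the PEB parameter subset.
#' @export
peb_subject_posterior <- function(peb, subject_post, subject = 1) {
  g <- gaussian_parts(subject_post)
  sel <- peb$params
  p <- length(sel)
  m <- g$mean[sel]
  S <- as.matrix(g$cov)[sel, sel, drop = FALSE] +
    1e-8 * diag(p)
  mu_g <- drop(kronecker(t(peb$X[subject, ]), diag(p)) %*% as.vector(peb$beta))
  Sb <- exp(-peb$lambda) * diag(p)
  Pi_i <- chol_solve(S)
  Pi_g <- chol_solve(Sb)
  Sig <- chol_solve(Pi_i + Pi_g)
  list(M = drop(Sig %*% (Pi_i %*% m + Pi_g %*% mu_g)), Sigma = Sig,
       group_mean = mu_g)
}
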