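# Bayesian model reduction, greedy model search, Bayesian model averaging
# and the retention (pruning) probabilities derived from them.

# coerce posteriors/priors to plain (mean, cov/var) over the free subset
gaussian_parts <- function(post) {
  if (inherits(post, "dcm_posterior") || (is.list(post) && !is.null(post$M)))
    list(mean = post$M, cov = post$Sigma)
  else if (is.list(post) && !is.null(post$mean))
    list(mean = post$mean,
         cov = if (!is.null(post$cov)) post$cov else diag(post$var))
  else stop("cannot interpret posterior object")
}

prior_parts <- function(prior) {
  if (inherits(prior, "dcm_priors"))
    list(mean = prior$mean, var = prior$var)
  else if (is.list(prior) && !is.null(prior$mean) && !is.null(prior$var))
    list(mean = prior$mean, var = prior$var)
  else stop("priors must provide `mean` and `var`")
}

logdet_chol <- function(M) {
  2 * sum(log(diag(chol((M + t(M)) / 2))))
}

#' Bayesian model reduction
#'
#' Computes, in closed form, the posterior and the change in log-evidence of
#' a model whose priors are a reduced (more precise) version of the full
#' model's priors, from the full model's posterior alone. With posterior
#' precision `P`, full prior precision `P0` and reduced prior precision
#' `Pr`: the reduced posterior precision is `P + Pr - P0`, its mean balances
#' the three information sources, and the evidence change is a ratio of
#' Gaussian normalisation constants. No iteration is involved.
#'
#' @param post a [invert_spectral_dcm()] posterior, or any list with
#'   elements `M` (mean) and `Sigma` (covariance).
#' @param full_prior,reduced_prior [default_priors()] objects or lists with
#'   `mean` and `var`. The reduced prior may only increase precision
#'   (decrease variance) where it differs from the full prior.
#' @return List with `post` (reduced posterior: `M`, `Sigma`) and `dF`
#'   (log-evidence of the reduced model relative to the full one).
#' @export
bmr_reduce <- function(post, full_prior, reduced_prior) {
  g <- gaussian_parts(post)
  p0 <- prior_parts(full_prior)
  pr <- prior_parts(reduced_prior)
  P <- length(g$mean)
  if (length(p0$mean) != P || length(pr$mean) != P)
    stop("posterior and priors must share dimension")
  changed <- which(abs(pr$var - p0$var) > 0 | abs(pr$mean - p0$mean) > 0)
  if (any(pr$var[changed] > p0$var[changed] + 1e-12))
    stop("reduced prior must not be wider than the full prior where changed")
  free <- which(p0$var > 0)
  if (any(pr$var[setdiff(seq_len(P), free)] != 0))
    stop("cannot free a parameter that is fixed in the full prior")
  m <- g$mean[free]
  S <- as.matrix(g$cov)[free, free, drop = FALSE]
  Pi <- chol_solve(S + 1e-12 * mean(diag(S)) * diag(length(free)))
  Pi0 <- diag(1 / p0$var[free], length(free))
  Pir <- diag(1 / pmax(pr$var[free], 1e-10), length(free))
  m0 <- p0$mean[free]
  mr <- pr$mean[free]
  Pired <- Pi + Pir - Pi0
  # validity: the implied reduced posterior must remain a proper density
  ev <- eigen((Pired + t(Pired)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("invalid reduction: reduced posterior precision is not positive definite")
  Sred <- chol_solve(Pired)
  mred <- drop(Sred %*% (Pi %*% m + Pir %*% mr - Pi0 %*% m0))
  dF <- 0.5 * (logdet_chol(Pir) - logdet_chol(Pi0) +
                 logdet_chol(Pi) - logdet_chol(Pired)) -
    0.5 * (sum(mr * (Pir %*% mr)) - sum(m0 * (Pi0 %*% m0)) +
             sum(m * (Pi %*% m)) - sum(mred * (Pired %*% mred)))
  Mfull <- g$mean
  Mfull[free] <- mred
  Sfull <- matrix(0, P, P, dimnames = dimnames(as.matrix(g$cov)))
  Sfull[free, free] <- Sred
  red <- list(M = Mfull, Sigma = Sfull, F = dF,
              map = post$map, priors = reduced_prior)
  class(red) <- "dcm_posterior"
  list(post = red, dF = as.numeric(dF))
}

# reduced prior that pins the given parameters to mean 0, variance 1e-8
pinned_prior <- function(prior, pin) {
  p <- prior_parts(prior)
  p$var[pin] <- 1e-8
  p$mean[pin] <- 0
  p
}

#' Greedy search over reduced models
#'
#' Explores nested models obtained by switching off (pinning to zero)
#' off-diagonal coupling parameters, using [bmr_reduce()] to score every
#' candidate in milliseconds. Each sweep scores all single-parameter
#' prunings of the currently prunable set, jointly applies those that do
#' not decrease the evidence (falling back to the best single pruning if
#' the joint model is worse), and stops when no pruning remains that keeps
#' the evidence from dropping. Self-connections and spectral/haemodynamic
#' parameters are never pruned.
#'
#' @param post a Gaussian posterior (e.g. a PEB group-level posterior).
#' @param prior the corresponding full prior.
#' @param settings list; `prunable` (integer indices or names of prunable
#'   parameters; defaults to all `A[...]` parameters with positive prior
#'   variance) and `max_sweeps` (default 64).
#' @return An object of class `model_scores`: a list of models, each with
#'   `mask` (logical, TRUE = parameter on), `dF` relative to the full
#'   model, and `n_off`; sorted by decreasing evidence. The full posterior
#'   and prior ride along as attributes for use by [bma()].
#' @export
greedy_search <- function(post, prior, settings = list()) {
  s <- utils::modifyList(list(prunable = NULL, max_sweeps = 64L), settings)
  p0 <- prior_parts(prior)
  P <- length(p0$mean)
  nm <- names(p0$mean)
  prunable <- s$prunable
  if (is.null(prunable)) {
    prunable <- if (!is.null(nm)) which(startsWith(nm, "A[") & p0$var > 0)
    else which(p0$var > 0)
  } else if (is.character(prunable)) {
    prunable <- match(prunable, nm)
  }
  prunable <- sort(unique(as.integer(prunable)))

  score_mask <- function(off) {
    if (!length(off)) return(0)
    dF <- bmr_reduce(post, prior, pinned_prior(prior, off))$dF
    if (abs(dF) < 1e-9) 0 else dF   # snap roundoff so exact ties stay ties
  }
  mask_key <- function(off) paste0("m", paste(off, collapse = ","))

  seen <- new.env(parent = emptyenv())
  record <- function(off, dF) {
    assign(mask_key(off), list(off = off, dF = dF), envir = seen)
  }
  record(integer(0), 0)

  current_off <- integer(0)
  on_set <- prunable
  for (sweep in seq_len(s$max_sweeps)) {
    if (!length(on_set)) break
    cand <- vapply(on_set, function(j) {
      off <- sort(c(current_off, j))
      dF <- score_mask(off)
      record(off, dF)
      dF
    }, numeric(1))
    base_dF <- score_mask(current_off)
    gains <- cand - base_dF
    improving <- which(gains >= 0)
    if (!length(improving)) break
    joint_off <- sort(c(current_off, on_set[improving]))
    joint_dF <- score_mask(joint_off)
    record(joint_off, joint_dF)
    best_single <- improving[which.max(gains[improving])]
    if (joint_dF >= cand[best_single]) {
      current_off <- joint_off
    } else {
      current_off <- sort(c(current_off, on_set[best_single]))
    }
    on_set <- setdiff(prunable, current_off)
  }

  models <- lapply(ls(seen), function(k) get(k, envir = seen))
  scores <- lapply(models, function(mo) {
    mask <- rep(TRUE, P)
    mask[mo$off] <- FALSE
    if (!is.null(nm)) names(mask) <- nm
    list(mask = mask, dF = mo$dF, n_off = length(mo$off))
  })
  # ties in evidence favour the more parsimonious model, then key order
  dFv <- vapply(scores, `[[`, numeric(1), "dF")
  noffv <- vapply(scores, `[[`, numeric(1), "n_off")
  keys <- vapply(models, function(mo) mask_key(mo$off), character(1))
  scores <- scores[order(-dFv, -noffv, keys)]
  structure(scores, class = "model_scores", post = post, prior = prior,
            prunable = prunable, accepted = current_off)
}

#' @export
print.model_scores <- function(x, ...) {
  cat(sprintf("<model_scores> %d models scored; best dF = %.2f (%d pruned)\n",
              length(x), x[[1]]$dF, x[[1]]$n_off))
  invisible(x)
}

#' Bayesian model averaging
#'
#' Averages the posteriors of the best `top_k` models (by evidence) with
#' softmax weights `w_k` proportional to `exp(dF_k)`, moment-matching the
#' Gaussian mixture: the averaged covariance inflates by the between-model
#' dispersion of the means.
#'
#' @param scores a [greedy_search()] result.
#' @param top_k number of models to average (default 256).
#' @return A `dcm_posterior`-like object with the averaged `M` and `Sigma`,
#'   plus attributes `weights` and `n_models`.
#' @export
bma <- function(scores, top_k = 256) {
  stopifnot(inherits(scores, "model_scores"), top_k >= 1)
  post <- attr(scores, "post")
  prior <- attr(scores, "prior")
  k <- min(top_k, length(scores))
  use <- scores[seq_len(k)]
  dF <- vapply(use, `[[`, numeric(1), "dF")
  w <- exp(dF - max(dF))
  w <- w / sum(w)
  P <- length(gaussian_parts(post)$mean)
  Mbar <- numeric(P)
  S2 <- matrix(0, P, P)
  for (i in seq_len(k)) {
    off <- which(!use[[i]]$mask)
    red <- if (length(off))
      bmr_reduce(post, prior, pinned_prior(prior, off))$post
    else gaussian_parts(post)
    Mi <- if (!is.null(red$M)) red$M else red$mean
    Si <- if (!is.null(red$Sigma)) red$Sigma else red$cov
    Mbar <- Mbar + w[i] * Mi
    S2 <- S2 + w[i] * (as.matrix(Si) + outer(Mi, Mi))
  }
  Sbar <- S2 - outer(Mbar, Mbar)
  Sbar <- (Sbar + t(Sbar)) / 2
  g <- gaussian_parts(post)
  names(Mbar) <- names(g$mean)
  dimnames(Sbar) <- dimnames(as.matrix(g$cov))
  out <- list(M = Mbar, Sigma = Sbar, F = post$F, map = post$map,
              priors = prior)
  class(out) <- "dcm_posterior"
  attr(out, "weights") <- w
  attr(out, "n_models") <- k
  out
}

#' Retention probabilities after model averaging
#'
#' For every prunable parameter, compares (by [bmr_reduce()]) the model with
#' the parameter free against the model with it switched off, and converts
#' the evidence difference into a posterior probability
#' `p = 1 / (1 + exp(dF_without))`. Parameters are retained when the
#' probability of the model including them exceeds the threshold.
#'
#' @param bma_post a posterior (typically from [bma()]).
#' @param prior the corresponding full prior.
#' @param threshold retention threshold (default 0.95).
#' @param prunable indices or names of prunable parameters (defaults to the
#'   `A[...]` parameters with positive prior variance).
#' @return Data frame with columns `name`, `dF_without`, `prob`, `retained`.
#' @export
retention_mask <- function(bma_post, prior, threshold = 0.95,
                           prunable = NULL) {
  p0 <- prior_parts(prior)
  nm <- names(p0$mean)
  if (is.null(prunable)) {
    prunable <- if (!is.null(nm)) which(startsWith(nm, "A[") & p0$var > 0)
    else which(p0$var > 0)
  } else if (is.character(prunable)) {
    prunable <- match(prunable, nm)
  }
  dF <- vapply(prunable, function(j)
    bmr_reduce(bma_post, prior, pinned_prior(prior, j))$dF, numeric(1))
  prob <- 1 / (1 + exp(dF))
  data.frame(name = if (!is.null(nm)) nm[prunable] else as.character(prunable),
             dF_without = dF, prob = prob,
             retained = prob > threshold,
             stringsAsFactors = FALSE)
}
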