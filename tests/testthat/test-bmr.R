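# Bayesian model reduction against the conjugate linear-Gaussian oracle
# (constructed in helper-specdcm.R), greedy search behaviour, model
# averaging and retention.

test_that("reducing to the full prior is the identity", {
  cs <- make_conjugate_case(4, seed = 1)
  out <- bmr_reduce(cs$post, cs$full_prior, cs$full_prior)
  expect_equal(out$dF, 0, tolerance = 1e-10)
  expect_equal(out$post$M, cs$post$M, tolerance = 1e-10)
  expect_equal(out$post$Sigma, cs$post$Sigma, tolerance = 1e-10)
})

test_that("reduction equals direct conjugate inversion (P = 4 and random P <= 8)", {
  for (case in list(c(4, 2), c(2, 3), c(5, 4), c(8, 5), c(8, 6), c(3, 7))) {
    P <- case[1]
    cs <- make_conjugate_case(P, seed = case[2],
                              pin = sample.int(P, 1 + case[2] %% 2))
    out <- bmr_reduce(cs$post, cs$full_prior, cs$red_prior)
    expect_equal(out$dF, cs$dF_direct, tolerance = 1e-8)
    expect_equal(unname(out$post$M), unname(cs$red_mean), tolerance = 1e-8)
    expect_equal(unname(as.matrix(out$post$Sigma)), unname(cs$red_cov),
                 tolerance = 1e-8)
  }
})

test_that("pinning a clearly nonzero parameter is penalised", {
  P <- 4
  post <- list(M = c(0.9, 0, 0, 0), Sigma = diag(0.02, P))  # |M|/sd ~ 6
  prior <- list(mean = numeric(P), var = rep(1 / 16, P))
  red <- prior
  red$var[1] <- 1e-8
  expect_lt(bmr_reduce(post, prior, red)$dF, 0)
})

test_that("invalid reductions are refused", {
  prior <- list(mean = numeric(3), var = rep(1 / 16, 3))
  wide <- prior
  wide$var[2] <- 1
  post <- list(M = numeric(3), Sigma = diag(1 / 16, 3))
  expect_error(bmr_reduce(post, prior, wide), "wider")
})

nm6 <- sprintf("A[r%d<-r%d]", c(2, 3, 1, 3, 1, 2), c(1, 1, 2, 2, 3, 3))

test_that("greedy search prunes exactly the flat parameters of a null fit", {
  prior <- list(mean = stats::setNames(numeric(6), nm6),
                var = stats::setNames(rep(1 / 64, 6), nm6))
  post <- list(M = prior$mean, Sigma = diag(prior$var))  # posterior = prior
  sc <- greedy_search(post, prior)
  expect_equal(sc[[1]]$n_off, 6)        # evidence favours maximal reduction
  expect_equal(sc[[1]]$dF, 0)
  full <- Filter(function(s) s$n_off == 0, sc)
  expect_equal(full[[1]]$dF, 0)          # full model carries dF = 0 exactly
})

test_that("greedy search retains strong connections and drops absent ones", {
  truth <- c(0.4, 0, -0.35, 0, 0.3, 0)
  withr::with_seed(8, {
    M <- truth + rnorm(6, 0, 0.01)
  })
  post <- list(M = stats::setNames(M, nm6),
               Sigma = diag(rep(0.01^2, 6)))
  prior <- list(mean = stats::setNames(numeric(6), nm6),
                var = stats::setNames(rep(1 / 64, 6), nm6))
  sc <- greedy_search(post, prior)
  best <- sc[[1]]$mask
  expect_true(all(best[truth != 0]))
  expect_true(all(!best[truth == 0]))
  # accepted pruning never drops the evidence below the full model
  expect_gte(sc[[1]]$dF, 0)
})

test_that("a parameter matching its pinned prior is pruned in one sweep", {
  M <- stats::setNames(c(0.5, 0, 0.4, 0.3, -0.2, 0.25), nm6)
  S <- diag(c(0.01, 1e-6, 0.01, 0.01, 0.01, 0.01))
  prior <- list(mean = stats::setNames(numeric(6), nm6),
                var = stats::setNames(rep(1 / 64, 6), nm6))
  sc <- greedy_search(list(M = M, Sigma = S), prior,
                      settings = list(max_sweeps = 1))
  expect_false(sc[[1]]$mask[2])
})

test_that("model averaging reproduces hand-computed moment matching", {
  withr::with_seed(12, {
    M <- stats::setNames(c(0.4, 0.02, -0.3, 0.01, 0.25, -0.02), nm6)
    S <- crossprod(matrix(rnorm(36, 0, 0.05), 6)) + diag(0.005, 6)
  })
  dimnames(S) <- list(nm6, nm6)
  prior <- list(mean = stats::setNames(numeric(6), nm6),
                var = stats::setNames(rep(1 / 64, 6), nm6))
  post <- list(M = M, Sigma = S)
  sc <- greedy_search(post, prior)
  k <- 5
  avg <- bma(sc, top_k = k)
  w <- attr(avg, "weights")
  dF <- vapply(sc[1:k], `[[`, numeric(1), "dF")
  expect_equal(w, exp(dF - max(dF)) / sum(exp(dF - max(dF))),
               tolerance = 1e-12)
  # independent recomputation of the moment-matched mixture
  Ms <- Ss <- list()
  for (i in 1:k) {
    off <- which(!sc[[i]]$mask)
    red <- if (length(off))
      bmr_reduce(post, prior, specdcm:::pinned_prior(prior, off))$post
    else post
    Ms[[i]] <- red$M
    Ss[[i]] <- as.matrix(red$Sigma)
  }
  Mbar <- Reduce(`+`, Map(`*`, w, Ms))
  S2 <- Reduce(`+`, Map(function(wi, Si, Mi) wi * (Si + outer(Mi, Mi)),
                        w, Ss, Ms))
  expect_equal(avg$M, Mbar, tolerance = 1e-12)
  expect_equal(unname(avg$Sigma), unname(S2 - outer(Mbar, Mbar)),
               tolerance = 1e-12)
  # averaging a single model returns that model unchanged
  one <- bma(sc, top_k = 1)
  expect_equal(one$M, Ms[[1]])
  expect_equal(unname(one$Sigma), unname(Ss[[1]]), tolerance = 1e-12)
})

test_that("retention probabilities behave at the two reference points", {
  prior <- list(mean = stats::setNames(numeric(6), nm6),
                var = stats::setNames(rep(1 / 64, 6), nm6))
  # posterior equal to the prior in coordinate 1: p about 0.5
  M <- stats::setNames(c(0, 0.5, 0.4, 0.3, -0.2, 0.25), nm6)
  S <- diag(c(1 / 64, rep(0.01^2, 5)))
  ret <- retention_mask(list(M = M, Sigma = S), prior)
  expect_equal(ret$prob[1], 0.5, tolerance = 0.05)
  expect_false(ret$retained[1])
  # |M|/sd = 6 in the others: retained
  expect_true(all(ret$retained[-1]))
  # permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  ret2 <- retention_mask(list(M = M[perm],
                              Sigma = diag(diag(S)[perm])),
                         list(mean = prior$mean[perm],
                              var = prior$var[perm]))
  expect_equal(ret2$prob, ret$prob[perm], tolerance = 1e-10)
})
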