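# parametric empirical Bayes over directly constructed subject posteriors
# (the full simulate -> invert -> PEB chain is exercised in the acceptance
# suite; here the second-level machinery is tested in isolation)

pnames15 <- function() {
  map <- param_map(load_region_fixture())
  map$name[map$type %in% c("A", "self")]
}

make_subject_posts <- function(N, sd = 0.05, noise = 0.02, seed = 1,
                               diag_cov = TRUE) {
  A0 <- make_template_A()
  map <- param_map(load_region_fixture())
  sel <- map$type %in% c("A", "self")
  nms <- map$name[sel]
  truth <- stats::setNames(numeric(length(nms)), nms)
  ai <- which(map$type[sel] == "A")
  msub <- map[sel, ]
  for (k in ai) truth[k] <- A0$matrix[msub$target[k], msub$source[k]]
  si <- which(map$type[sel] == "self")
  truth[si] <- log(diag(A0$matrix) / -0.5)
  posts <- withr::with_seed(seed, lapply(seq_len(N), function(i) {
    th <- truth
    th[ai] <- th[ai] + rnorm(length(ai), 0, sd)       # between-subject effect
    M <- th + rnorm(length(th), 0, noise)             # first-level noise
    Sigma <- if (diag_cov) diag(noise^2, length(th))
    else crossprod(matrix(rnorm(length(th)^2, 0, noise / 8),
                          length(th))) + diag(noise^2, length(th))
    dimnames(Sigma) <- list(nms, nms)
    list(M = stats::setNames(M, nms), Sigma = Sigma)
  }))
  list(posts = posts, truth = truth, ai = ai)
}

test_that("a single subject with a flat prior is returned unchanged", {
  cs <- make_subject_posts(1)
  peb <- peb_fit(cs$posts, X = matrix(1, 1, 1),
                 settings = list(flat_beta_prior = TRUE))
  expect_equal(unname(peb$beta[, 1]), unname(cs$posts[[1]]$M),
               tolerance = 1e-6)
})

test_that("the group mean recovers the template across subjects", {
  cs <- make_subject_posts(20, seed = 5)
  peb <- peb_fit(cs$posts)
  est <- peb$beta[, 1]
  expect_gt(cor(est[cs$ai], cs$truth[cs$ai]), 0.9)
  # six between-network block-mean signs recovered
  gpost <- peb_group_posterior(peb)
  nv <- between_network_average(gpost, load_region_fixture())
  expect_lt(nv$mean["cDN", "SN"], 0)
  expect_lt(nv$mean["cDN", "DAN"], 0)
  expect_gt(nv$mean["SN", "cDN"], 0)
  expect_gt(nv$mean["DAN", "cDN"], 0)
  expect_gt(nv$mean["SN", "DAN"], 0)
  expect_gt(nv$mean["DAN", "SN"], 0)
})

test_that("a pure-noise covariate barely moves the group means", {
  cs <- make_subject_posts(20, seed = 6)
  peb0 <- peb_fit(cs$posts)
  X <- cbind(1, withr::with_seed(7, rnorm(20)))
  colnames(X) <- c("group_mean", "noise")
  peb1 <- peb_fit(cs$posts, X = X)
  shift <- abs(peb1$beta[, 1] - peb0$beta[, 1]) / sqrt(peb0$prior_var)
  expect_lt(max(shift), 0.3)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  cs <- make_subject_posts(8, seed = 8)
  X <- cbind(1, rep(c(1, -1), 4), rep(c(1, -1), 4))
  colnames(X) <- c("group_mean", "c1", "c2")
  expect_error(peb_fit(cs$posts, X = X), "collinear.*c2")
  expect_error(peb_fit(cs$posts, X = matrix(2, 8, 1)), "ones")
})

test_that("empirical-Bayes shrinkage places subjects between their own
           estimate and the group mean", {
  cs <- make_subject_posts(12, seed = 9, diag_cov = TRUE)
  peb <- peb_fit(cs$posts)
  for (i in c(1, 5, 12)) {
    sp <- peb_subject_posterior(peb, cs$posts[[i]], subject = i)
    m1 <- cs$posts[[i]]$M
    lo <- pmin(m1, sp$group_mean) - 1e-9
    hi <- pmax(m1, sp$group_mean) + 1e-9
    expect_true(all(sp$M >= lo & sp$M <= hi))
  }
})
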