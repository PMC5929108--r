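test_that("contrasts reduce to coordinates and averages", {
  M <- c(1, 1, 0, 0, 0.3, -0.2)
  S <- diag(c(4, 1, 1, 1, 2, 2)) / 10
  post <- list(M = M, Sigma = S)
  # coordinate contrast
  ct <- contrast(post, c(1, 0, 0, 0, 0, 0))
  expect_equal(ct$mu, M[1])
  expect_equal(ct$sigma2, S[1, 1])
  # mean of the first four parameters with P = 6
  avg <- contrast(post, c(0.25, 0.25, 0.25, 0.25, 0, 0))
  expect_equal(avg$mu, mean(M[1:4]))
  # first two against second two
  dif <- contrast(post, c(0.5, 0.5, -0.5, -0.5, 0, 0))
  expect_equal(dif$mu, 1)
})

test_that("contrast moments are linear and variance vanishes on null space", {
  withr::with_seed(3, {
    M <- rnorm(5)
    L <- matrix(rnorm(25), 5)
  })
  S <- crossprod(L)
  S[, 5] <- 0
  S[5, ] <- 0                      # parameter 5 in the null space
  post <- list(M = M, Sigma = S)
  c1 <- rnorm(5)
  c2 <- rnorm(5)
  expect_equal(contrast(post, c1 + c2)$mu,
               contrast(post, c1)$mu + contrast(post, c2)$mu)
  expect_equal(contrast(post, c(0, 0, 0, 0, 1))$sigma2, 0)
  expect_gt(contrast(post, c(1, 0, 0, 0, 0))$sigma2, 0)
})

test_that("between-network averages of a template point mass are exact", {
  A <- make_template_A()
  nv <- between_network_average(A)
  bm <- default_between_means()
  for (a in c("cDN", "SN", "DAN")) for (b in c("cDN", "SN", "DAN"))
    if (a != b) expect_equal(nv$mean[a, b], bm[a, b])
  expect_equal(unname(diag(nv$mean)), rep(0.1, 3))  # within-network strength
})

test_that("between-network averages are invariant to region order", {
  A <- make_template_A()
  reg <- load_region_fixture()
  perm <- c(8, 3, 15, 1, 11, 5, 2, 14, 7, 10, 4, 13, 6, 12, 9)
  Ap <- effective_connectivity(A$matrix[perm, perm],
                               region_set(reg$label[perm],
                                          reg$network[perm]),
                               check = FALSE)
  nv <- between_network_average(A)
  nvp <- between_network_average(Ap)
  expect_equal(nv$mean, nvp$mean)
})

test_that("cell variance of independent parameters is v / count", {
  reg <- tiny_regions(4)   # two regions per network
  map <- param_map(reg)
  v <- 0.04
  post <- list(M = stats::setNames(numeric(nrow(map)), map$name),
               Sigma = diag(v, nrow(map)))
  nv <- between_network_average(post, reg)
  # n1 -> n2: two targets x two sources = 4 connections
  expect_equal(unname(nv$count["n2", "n1"]), 4)
  expect_equal(unname(nv$var["n2", "n1"]), v / 4)
  # within-network cell: the two off-diagonal connections
  expect_equal(unname(nv$count["n1", "n1"]), 2)
  expect_equal(unname(nv$var["n1", "n1"]), v / 2)
})

test_that("hierarchy strength reproduces the worked network arithmetic", {
  nv <- network_averages(rbind(c(NA, -0.13, -0.10),
                               c(0.02, NA, 0.02),
                               c(0.02, 0.03, NA)),
                         networks = c("cDN", "SN", "DAN"))
  hs <- hierarchy_strength(nv)
  expect_equal(unname(hs["SN"]), 0.12)
  expect_equal(unname(hs["DAN"]), 0.07)
  expect_equal(unname(hs["cDN"]), -0.19)
  # mean form halves the two-network sums
  expect_equal(unname(hierarchy_strength(nv, "SN", form = "mean")), 0.06,
               ignore_attr = TRUE)
})

test_that("hierarchy scores vanish for symmetric coupling and ignore labels", {
  nv <- network_averages(matrix(0.05, 3, 3),
                         networks = c("cDN", "SN", "DAN"))
  expect_equal(unname(hierarchy_strength(nv)), rep(0, 3),
               ignore_attr = TRUE)
  # relabelling regions within networks leaves scores unchanged
  A <- make_template_A()
  reg <- load_region_fixture()
  perm <- c(2, 1, 4, 3, 6, 5, 9, 7, 8, 12, 10, 11, 15, 13, 14)  # within nets
  Ap <- effective_connectivity(A$matrix[perm, perm],
                               region_set(reg$label[perm], reg$network[perm]),
                               check = FALSE)
  expect_equal(hierarchy_strength(between_network_average(A)),
               hierarchy_strength(between_network_average(Ap)))
})

test_that("clustering recovers planted two-community structure", {
  B <- rbind(cbind(matrix(0.8, 3, 3), matrix(-0.2, 3, 3)),
             cbind(matrix(-0.2, 3, 3), matrix(0.8, 3, 3)))
  diag(B) <- -0.5
  withr::with_seed(2, B <- B + matrix(rnorm(36, 0, 0.02), 6))
  rownames(B) <- colnames(B) <- paste0("g", 1:6)
  cl <- cluster_regions(B, k = 2)
  expect_equal(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_equal(unname(cl$labels[4:6]), rep(cl$labels[[4]], 3))
  expect_false(cl$labels[[1]] == cl$labels[[4]])
})

test_that("template coupling and its FC cluster into the same two modes", {
  A <- make_template_A()
  reg <- load_region_fixture()
  cl_ec <- cluster_regions(A, k = 2)
  # one mode is exactly the core default network
  cdn <- reg$label[reg$network == "cDN"]
  expect_equal(length(unique(cl_ec$labels[cdn])), 1)
  expect_equal(length(unique(cl_ec$labels[setdiff(reg$label, cdn)])), 1)
  expect_false(cl_ec$labels[[cdn[1]]] == cl_ec$labels[["rAI"]])
  fc <- functional_connectivity(
    predicted_csd(A, grid = frequency_grid(seq(0.002, 2, length.out = 800))))
  cl_fc <- cluster_regions(fc, k = 2)
  expect_equal(compare_partitions(cl_ec, cl_fc), 1)
})

test_that("constant profiles are rejected by name", {
  M <- diag(-0.5, 3)
  rownames(M) <- colnames(M) <- c("a", "b", "c")
  expect_error(cluster_regions(M, k = 2), "zero variance.*")
})

test_that("adjusted Rand index matches its reference implementation", {
  skip_if_not_installed("mclust")
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- rep(1:2, c(8, 7))
  b <- a
  b[3] <- 2    # one region moved
  expect_equal(compare_partitions(a, b),
               mclust::adjustedRandIndex(a, b))
  withr::with_seed(10, {
    for (i in 1:5) {
      x <- sample(1:3, 20, replace = TRUE)
      y <- sample(1:4, 20, replace = TRUE)
      expect_equal(compare_partitions(x, y),
                   mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    }
  })
})

test_that("random partitions have adjusted Rand near zero on average", {
  truth <- rep(1:2, c(8, 7))
  aris <- withr::with_seed(14, vapply(1:100, function(i)
    compare_partitions(truth, sample(1:2, 15, replace = TRUE)),
    numeric(1)))
  expect_lt(abs(mean(aris)), 0.05)
})
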