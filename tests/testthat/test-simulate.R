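test_that("decoupled regions stay empirically uncorrelated", {
  A <- effective_connectivity(diag(-0.5, 3), tiny_regions(3))
  rs <- vapply(1:20, function(s) {
    ts <- simulate_bold(A, T = 1700, dt = 2, seed = 100 + s)
    R <- cor(ts$data)
    mean(abs(R[upper.tri(R)]))
  }, numeric(1))
  expect_lt(mean(rs), 0.15)
})

test_that("simulation is a pure function of its seed", {
  A <- make_template_A()
  t1 <- simulate_bold(A, T = 64, seed = 9)
  t2 <- simulate_bold(A, T = 64, seed = 9)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_bold(A, T = 64, seed = 10)
  expect_false(identical(t1$data, t3$data))
})

test_that("group-mean empirical FC shows the anticorrelation block pattern", {
  co <- generate_cohort(cohort_config(n_subjects = 8L, seed = 33L))
  Rbar <- Reduce(`+`, lapply(co$subjects, function(ts) cor(ts$data))) / 8
  B <- block_means(Rbar, co$regions$network)
  expect_lt(B["cDN", "SN"], 0)
  expect_lt(B["cDN", "DAN"], 0)
  expect_gt(B["cDN", "cDN"], 0)
  expect_gt(B["SN", "SN"], 0)
  expect_gt(B["DAN", "DAN"], 0)
})

test_that("simulated series are mean-centred with the declared shape", {
  ts <- simulate_bold(make_template_A(), T = 96, dt = 2, seed = 2)
  expect_equal(dim(ts$data), c(96, 15))
  expect_equal(ts$dt, 2)
  expect_lt(max(abs(colMeans(ts$data))), 1e-10)
})

test_that("integration failures advise a smaller step", {
  fast <- effective_connectivity(matrix(-40, 1, 1),
                                 region_set("a", "x"))
  expect_error(simulate_bold(fast, T = 64, seed = 1, dt_sim = 0.1),
               "dt_sim")
  expect_error(simulate_bold(make_template_A(), T = 64, seed = 1,
                             burn_in = 10), "60")
})

test_that("cohorts regenerate bit-identically and record their truth", {
  cfg <- cohort_config(n_subjects = 3L, T = 64L, seed = 5L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(lapply(c1$subjects, `[[`, "data"),
                   lapply(c2$subjects, `[[`, "data"))
  expect_identical(lapply(c1$truth, `[[`, "matrix"),
                   lapply(c2$truth, `[[`, "matrix"))
  # truths differ from the template in the off-diagonals only
  for (tr in c1$truth) {
    expect_equal(diag(tr$matrix), diag(c1$template$matrix))
    expect_false(identical(tr$matrix, c1$template$matrix))
  }
})

test_that("a single noiseless subject equals the template exactly", {
  co <- generate_cohort(cohort_config(n_subjects = 1L, subject_sd = 0,
                                      T = 64L, seed = 1L))
  expect_identical(co$truth[[1]]$matrix, co$template$matrix)
})

test_that("unknown configuration keys are rejected by name", {
  expect_error(cohort_config(n_sujets = 4), "n_sujets")
  expect_error(generate_cohort(list(subject_count = 2)), "subject_count")
  expect_error(generate_cohort(list(template = list(within = 1))), "within")
})
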