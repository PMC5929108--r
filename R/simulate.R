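#' Subject time series
#'
#' A sampled multi-region BOLD series: a `T x n` matrix with one column per
#' region, a sampling interval `dt` (seconds), and region labels. The
#' packaged defaults mirror a 6-minute resting-state acquisition at
#' TR = 2 s with the first volumes discarded: 170 retained volumes.
#'
#' @param data numeric `T x n` matrix.
#' @param dt sampling interval in seconds.
#' @param regions a [region_set()] or character labels, one per column.
#' @return An object of class `subject_ts`.
#' @export
subject_ts <- function(data, dt, regions = NULL) {
  data <- as.matrix(data)
  if (dt <= 0) stop("`dt` must be positive")
  if (anyNA(data)) stop("time series must not contain missing values")
  if (nrow(data) < 2 * ncol(data))
    stop("need at least 2n samples for n regions (got T = ", nrow(data),
         ", n = ", ncol(data), ")")
  if (is.null(regions)) {
    labs <- colnames(data)
    if (is.null(labs)) labs <- paste0("R", seq_len(ncol(data)))
    regions <- region_set(labs, rep("net1", ncol(data)))
  } else {
    regions <- as_region_set(regions)
  }
  if (nrow(regions) != ncol(data))
    stop("region set size does not match number of columns")
  colnames(data) <- regions$label
  structure(list(data = data, dt = dt, regions = regions),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %d volumes x %d regions, dt = %g s (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$dt,
              nrow(x$data) * x$dt / 60))
  invisible(x)
}

#' Simulate BOLD from effective connectivity
#'
#' Forward-simulates the full generative chain: power-law endogenous
#' fluctuations drive the linear neuronal state equation `dx/dt = A x + v`
#' (Euler integration on a fine grid), each region's activity is convolved
#' with the linearised haemodynamic kernel, the result is sampled at the
#' scanner interval `dt`, observation noise is added, a burn-in is
#' discarded, and columns are mean-centred.
#'
#' @param A an [effective_connectivity()] (must be stable).
#' @param fluct endogenous [fluctuation_params()].
#' @param hemo a [hemodynamic_params()].
#' @param T number of output volumes.
#' @param dt output sampling interval (s).
#' @param obs_noise observation-noise [fluctuation_params()] (white by
#'   default; its `alpha` is a spectral density, so the per-sample noise
#'   standard deviation is `sqrt(alpha / dt)`).
#' @param seed integer seed.
#' @param dt_sim integration step (s); must resolve the fastest eigenvalue.
#' @param burn_in burn-in discarded before sampling, in seconds (>= 60).
#' @return A [subject_ts()].
#' @export
simulate_bold <- function(A, fluct = fluctuation_params(),
                          hemo = hemodynamic_params(),
                          T = 170, dt = 2,
                          obs_noise = fluctuation_params(0.005, 0),
                          seed = 1, dt_sim = 0.1, burn_in = 64) {
  Am <- ec_matrix(A)
  assert_stable(Am)
  if (burn_in < 60) stop("`burn_in` must be at least 60 s")
  n <- nrow(Am)
  kspan <- 32                       # haemodynamic kernel support, s
  total <- burn_in + T * dt + kspan
  Ns <- 2^ceiling(log2(total / dt_sim))
  # spectral synthesis gives densities alpha*omega^-beta scaled by dt; the
  # 1/sqrt(dt_sim) restores the continuous-time density for the integrator
  v <- generate_fluctuations(n, Ns, dt_sim, fluct, seed) / sqrt(dt_sim)
  x <- cpp_euler(Am, v, dt_sim)
  if (!all(is.finite(x)))
    stop("numerical overflow while integrating the state equation; ",
         "use a smaller `dt_sim` (currently ", dt_sim, " s)")
  kern <- hemodynamic_kernel(hemo, seq(0, kspan, by = dt_sim))
  y <- apply(x, 2, function(col)
    stats::convolve(col, rev(kern), type = "open")[seq_along(col)] * dt_sim)
  idx <- seq(round(burn_in / dt_sim) + 1, by = round(dt / dt_sim),
             length.out = T)
  yo <- y[idx, , drop = FALSE]
  if (obs_noise$alpha > 0) {
    # observation noise of spectral density alpha*omega^-beta at interval dt
    e <- gen_powerlaw(n, T, dt, obs_noise, seed + 500000L)
    yo <- yo + e / sqrt(dt)
  }
  yo <- scale(yo, center = TRUE, scale = FALSE)
  attr(yo, "scaled:center") <- NULL
  subject_ts(yo, dt, ec_regions(A))
}

#' Generate a cohort of synthetic subjects
#'
#' Draws per-subject coupling matrices around a group template and
#' forward-simulates each subject's BOLD series. The whole cohort is a pure
#' function of the configuration and the master seed (subject `i` uses seed
#' `seed + i`), so regeneration is bit-identical.
#'
#' @param config a list with elements (all optional, defaults shown by
#'   [cohort_config()]): `regions`, `template` (list `between_means`,
#'   `within_strength`, `self_strength`), `n_subjects`, `subject_sd`,
#'   `T`, `dt`, `dt_sim`, `burn_in`, `fluct`, `obs_noise`, `hemo`, `seed`.
#'   Unknown keys are rejected.
#' @return An object of class `cohort`: list with `subjects` (list of
#'   [subject_ts()]), `truth` (list of [effective_connectivity()]),
#'   `template`, `regions`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  regions <- config$regions
  template <- make_template_A(regions,
                              config$template$between_means,
                              config$template$within_strength,
                              config$template$self_strength)
  subjects <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    seed_i <- config$seed + i
    Ai <- if (config$subject_sd > 0)
      sample_subject_A(template, config$subject_sd, seed_i)
    else template
    truth[[i]] <- Ai
    subjects[[i]] <- simulate_bold(Ai, config$fluct, config$hemo,
                                   T = config$T, dt = config$dt,
                                   obs_noise = config$obs_noise,
                                   seed = seed_i + 100000L,
                                   dt_sim = config$dt_sim,
                                   burn_in = config$burn_in)
  }
  names(subjects) <- names(truth) <- sprintf("sub-%02d", seq_along(subjects))
  structure(list(subjects = subjects, truth = truth, template = template,
                 regions = regions, config = config),
            class = "cohort")
}

#' @rdname generate_cohort
#' @param ... named overrides of the default configuration.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    regions = load_region_fixture(),
    template = list(between_means = default_between_means(),
                    within_strength = 0.1,
                    self_strength = -0.8),
    n_subjects = 20L,
    subject_sd = 0.05,
    T = 170L,
    dt = 2,
    dt_sim = 0.1,
    burn_in = 64,
    fluct = fluctuation_params(1, 1),
    obs_noise = fluctuation_params(0.005, 0),
    hemo = hemodynamic_params(),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown cohort configuration key(s): ",
         paste(unknown, collapse = ", "))
  # a region_set is a data frame, which modifyList would merge column-wise
  user_regions <- dots$regions
  dots$regions <- NULL
  cfg <- utils::modifyList(cfg, dots)
  if (!is.null(user_regions)) cfg$regions <- user_regions
  cfg
}

validate_cohort_config <- function(config) {
  defaults <- cohort_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown cohort configuration key(s): ",
         paste(unknown, collapse = ", "))
  user_regions <- config$regions
  config$regions <- NULL
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(user_regions)) cfg$regions <- user_regions
  if (!is.null(cfg$template)) {
    tunknown <- setdiff(names(cfg$template), names(defaults$template))
    if (length(tunknown))
      stop("unknown template configuration key(s): ",
           paste(tunknown, collapse = ", "))
  }
  if (cfg$n_subjects < 1) stop("`n_subjects` must be at least 1")
  if (cfg$subject_sd < 0) stop("`subject_sd` must be nonnegative")
  cfg$regions <- as_region_set(cfg$regions)
  cfg
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects, %d regions, T = %d volumes at dt = %g s (seed %d)\n",
    length(x$subjects), nrow(x$regions), x$config$T, x$config$dt,
    x$config$seed))
  invisible(x)
}
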