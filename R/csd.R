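#' Cross-spectral density objects
#'
#' A cross-spectral density (CSD) is a complex Hermitian `n x n` matrix per
#' frequency: the frequency-domain analogue of the cross-covariance
#' function, and the data feature fitted by the spectral model inversion.
#' Spectra follow the angular-frequency convention
#' `C(tau) = (1/2pi) \int G(omega) exp(i omega tau) d omega`, `omega = 2 pi f`.
#'
#' @param values complex array `nfreq x n x n`.
#' @param grid a [frequency_grid()].
#' @param regions region labels or a [region_set()].
#' @return An object of class `csd`.
#' @export
csd <- function(values, grid, regions = NULL) {
  if (length(dim(values)) != 3 || dim(values)[2] != dim(values)[3])
    stop("`values` must be an nfreq x n x n array")
  grid <- if (inherits(grid, "frequency_grid")) grid else frequency_grid(grid)
  if (dim(values)[1] != length(grid$frequencies))
    stop("first dimension of `values` must match the frequency grid")
  n <- dim(values)[2]
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  regions <- as_region_set(regions)
  if (nrow(regions) != n) stop("region set size does not match CSD dimension")
  herm_err <- max(vapply(seq_len(dim(values)[1]), function(k)
    max(Mod(values[k, , ] - Conj(t(values[k, , ])))), numeric(1)))
  if (herm_err > 1e-6 * max(Mod(values), 1e-300))
    stop("CSD slices are not Hermitian (max deviation ", signif(herm_err, 3), ")")
  if (any(Re(apply(values, 1, function(g) diag(matrix(g, n)))) < -1e-10))
    stop("CSD diagonal must be real and nonnegative")
  structure(list(values = values, grid = grid, regions = regions),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("<csd> %d regions x %d frequencies (%.4f-%.4f Hz)\n",
              dim(x$values)[2], length(x$grid$frequencies),
              min(x$grid$frequencies), max(x$grid$frequencies)))
  invisible(x)
}

#' Predicted cross-spectral density of the generative model
#'
#' Computes `G_y(w) = H(w) G_v(w) H(w)* + G_e(w)` with
#' `H(w) = K(w) (iwI - A)^-1`, where `G_v` is the power-law spectrum of the
#' endogenous fluctuations, `G_e` the observation-noise spectrum and `K` the
#' per-region haemodynamic transfer function (identity when `hemo = NULL`).
#' Every slice is Hermitian positive semidefinite by construction.
#'
#' @param A an [effective_connectivity()] (must be stable).
#' @param fluct endogenous [fluctuation_params()].
#' @param hemo a [hemodynamic_params()], or `NULL` for a unit observation
#'   kernel (direct neuronal spectra).
#' @param grid a [frequency_grid()].
#' @param obs_noise observation-noise [fluctuation_params()], or `NULL`
#'   for none.
#' @return A [csd()].
#' @examples
#' # scalar Ornstein-Uhlenbeck process: Lorentzian spectrum alpha/(a^2 + w^2)
#' A <- effective_connectivity(matrix(-0.5, 1, 1))
#' g <- predicted_csd(A, fluctuation_params(1, 0), hemo = NULL,
#'                    grid = frequency_grid(c(0.01, 0.1)), obs_noise = NULL)
#' @export
predicted_csd <- function(A, fluct = fluctuation_params(),
                          hemo = hemodynamic_params(),
                          grid = default_frequency_grid(),
                          obs_noise = fluctuation_params(0.005, 0)) {
  Am <- ec_matrix(A)
  assert_stable(Am)
  f <- grid_frequencies(grid)
  omega <- 2 * pi * f
  n <- nrow(Am)
  rc <- rcond(diag(n) * (1i * omega[1]) - Am)
  if (rc < 1e-12)
    warning("(iwI - A) is ill-conditioned at the lowest frequency ",
            "(rcond = ", signif(rc, 3), ")")
  K <- if (is.null(hemo))
    matrix(1 + 0i, length(omega), n)
  else
    matrix(hemodynamic_transfer(hemo, f), length(omega), n)
  gv <- matrix(fluct$alpha * omega^(-fluct$beta), length(omega), n)
  ge <- if (is.null(obs_noise))
    matrix(0, length(omega), n)
  else
    matrix(obs_noise$alpha * omega^(-obs_noise$beta), length(omega), n)
  cube <- cpp_predict_csd(Am, omega, K, gv, ge)
  vals <- aperm(cube, c(3, 1, 2))
  csd(vals, if (inherits(grid, "frequency_grid")) grid else frequency_grid(f),
      ec_regions(A))
}

#' Estimate a cross-spectral density from data
#'
#' Fits a multivariate autoregressive (MAR) model of the given order by
#' least squares and evaluates the implied parametric spectrum on the grid.
#' MAR smoothing gives stable spectral estimates on short resting-state
#' series; the order trades smoothness against resolution of the 1/f
#' divergence (use a higher order for long series). Ill-conditioned normal
#' equations fall back to a ridge solution with a warning.
#'
#' @param ts a [subject_ts()].
#' @param grid a [frequency_grid()]; defaults to the grid implied by the
#'   series length.
#' @param order MAR model order (default 8).
#' @return A [csd()].
#' @export
estimate_csd <- function(ts, grid = NULL, order = 8) {
  stopifnot(inherits(ts, "subject_ts"))
  Y <- ts$data
  Tn <- nrow(Y)
  n <- ncol(Y)
  if (Tn <= 4 * order)
    stop("need T > 4 * order samples (T = ", Tn, ", order = ", order, ")")
  if (is.null(grid)) grid <- default_frequency_grid(Tn, ts$dt)
  f <- grid_frequencies(grid)
  if (max(f) > 1 / (2 * ts$dt) + 1e-12)
    stop("frequency grid exceeds the Nyquist frequency ", 1 / (2 * ts$dt), " Hz")
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- do.call(cbind, lapply(seq_len(order), function(l)
    Y[(order - l + 1):(Tn - l), , drop = FALSE]))
  Yp <- Y[(order + 1):Tn, , drop = FALSE]
  XtX <- crossprod(X)
  kap <- kappa(XtX, exact = FALSE)
  if (!is.finite(kap) || kap > 1e10) {
    warning("MAR normal equations ill-conditioned (kappa = ",
            signif(kap, 3), "); using ridge fallback")
    XtX <- XtX + 1e-6 * mean(diag(XtX)) * diag(ncol(X))
  }
  B <- solve(XtX, crossprod(X, Yp))
  E <- Yp - X %*% B
  dof <- max(nrow(Yp) - ncol(X), n + 1)
  Se <- crossprod(E) / dof
  omega <- 2 * pi * f
  vals <- array(0i, c(length(f), n, n))
  for (k in seq_along(f)) {
    z <- exp(-1i * omega[k] * ts$dt * seq_len(order))
    Aw <- diag(n) + 0i
    for (l in seq_len(order))
      Aw <- Aw - t(B[((l - 1) * n + 1):(l * n), , drop = FALSE]) * z[l]
    iAw <- solve(Aw)
    G <- ts$dt * (iAw %*% Se %*% Conj(t(iAw)))
    vals[k, , ] <- (G + Conj(t(G))) / 2   # enforce exact Hermitian symmetry
  }
  csd(vals, grid, ts$regions)
}

#' Cross-covariance from a cross-spectral density
#'
#' Inverse Fourier transform of the two-sided CSD (the Hermitian extension
#' to negative frequencies), evaluated at the requested lags by trapezoidal
#' quadrature over the positive frequency grid:
#' `C_ij(tau) = (1/pi) \int_0^wmax Re[G_ij(w) exp(iw tau)] dw`.
#' The result satisfies the time-reversal identity
#' `C_ij(tau) = C_ji(-tau)` to machine precision.
#'
#' @param x a [csd()] with at least 64 frequency bins.
#' @param lags numeric vector of lags in seconds (positive, negative or 0).
#' @return An object of class `cross_covariance`: list with `values`
#'   (`nlag x n x n`), `lags`, `regions`.
#' @export
csd_to_cross_covariance <- function(x, lags = seq(-16, 16, by = 2)) {
  stopifnot(inherits(x, "csd"))
  f <- x$grid$frequencies
  if (length(f) < 64)
    stop("frequency grid too coarse: need at least 64 bins, got ", length(f))
  df <- min(diff(f))
  if (max(abs(lags)) > 1 / (2 * df))
    stop(sprintf(
      "requested lag %.1f s exceeds the aliasing limit 1/(2 df) = %.1f s",
      max(abs(lags)), 1 / (2 * df)))
  omega <- 2 * pi * f
  n <- dim(x$values)[2]
  vals <- array(0, c(length(lags), n, n))
  dw <- diff(omega)
  for (li in seq_along(lags)) {
    ph <- exp(1i * omega * lags[li])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      integrand <- Re(x$values[, i, j] * ph)
      vals[li, i, j] <- sum((integrand[-1] + integrand[-length(integrand)]) *
                              dw) / 2 / pi
    }
  }
  structure(list(values = vals, lags = lags, regions = x$regions),
            class = "cross_covariance")
}

#' @export
print.cross_covariance <- function(x, ...) {
  cat(sprintf("<cross_covariance> %d regions, %d lags (%g to %g s)\n",
              dim(x$values)[2], length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Functional connectivity from a cross-covariance
#'
#' The Pearson correlation matrix: the normalised cross-covariance at zero
#' lag, `r_ij = C_ij(0) / sqrt(C_ii(0) C_jj(0))`.
#'
#' @param cov a [csd_to_cross_covariance()] result whose lag grid includes 0,
#'   or a [csd()] (zero-lag covariance is then computed directly).
#' @return An object of class `fc_matrix`: symmetric, unit diagonal,
#'   entries in `[-1, 1]`.
#' @export
functional_connectivity <- function(cov) {
  if (inherits(cov, "csd")) cov <- csd_to_cross_covariance(cov, lags = 0)
  stopifnot(inherits(cov, "cross_covariance"))
  li <- which(abs(cov$lags) < 1e-12)
  if (!length(li)) stop("lag grid must include lag 0")
  C0 <- cov$values[li[1], , ]
  C0 <- (C0 + t(C0)) / 2
  v <- diag(C0)
  if (any(v <= 0))
    stop("zero (or negative) variance at lag 0 for region(s): ",
         paste(cov$regions$label[v <= 0], collapse = ", "))
  R <- C0 / sqrt(outer(v, v))
  diag(R) <- 1
  R <- pmin(pmax(R, -1), 1)
  fc_matrix(R, cov$regions)
}

#' @rdname functional_connectivity
#' @param values symmetric correlation matrix.
#' @param regions region labels or [region_set()].
#' @export
fc_matrix <- function(values, regions = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("FC matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("FC matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-8) stop("FC matrix must have unit diagonal")
  if (any(abs(values) > 1 + 1e-12)) stop("FC entries must lie in [-1, 1]")
  if (is.null(regions)) {
    labs <- rownames(values)
    if (is.null(labs)) labs <- paste0("R", seq_len(nrow(values)))
    regions <- region_set(labs, rep("net1", nrow(values)))
  } else {
    regions <- as_region_set(regions)
  }
  dimnames(values) <- list(regions$label, regions$label)
  structure(list(values = values, regions = regions), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d regions\n", nrow(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Empirical functional connectivity of a time series
#'
#' @param ts a [subject_ts()].
#' @return An `fc_matrix` of Pearson correlations.
#' @export
empirical_fc <- function(ts) {
  stopifnot(inherits(ts, "subject_ts"))
  fc_matrix(stats::cor(ts$data), ts$regions)
}

#' Convolution kernel of a single connection
#'
#' First-order response of the target region's BOLD signal to an impulse of
#' endogenous input at the source region: the (target, source) entry of the
#' haemodynamic kernel convolved with the neuronal propagator `expm(A t)`.
#' For a stable `A` the kernel decays to zero; for a diagonal `A` and
#' `source != target` it is identically zero.
#'
#' @param A an [effective_connectivity()] (stable).
#' @param hemo a [hemodynamic_params()].
#' @param source,target region labels or indices.
#' @param tspan time points (s) at which to return the kernel.
#' @param dt_fine internal resolution of the convolution (s).
#' @return Numeric vector of kernel values on `tspan`.
#' @export
connection_kernel <- function(A, hemo = hemodynamic_params(), source, target,
                              tspan = seq(0, 32, by = 0.25), dt_fine = 0.02) {
  Am <- ec_matrix(A)
  assert_stable(Am)
  labs <- rownames(Am)
  si <- if (is.character(source)) match(source, labs) else as.integer(source)
  ti <- if (is.character(target)) match(target, labs) else as.integer(target)
  if (is.na(si) || is.na(ti)) stop("unknown source or target region")
  tg <- seq(0, max(tspan), by = dt_fine)
  eg <- eigen(Am)
  Vi <- solve(eg$vectors)
  # x_target(t) for impulse at source
  wts <- eg$vectors[ti, ] * Vi[, si]
  xt <- vapply(tg, function(t) Re(sum(wts * exp(eg$values * t))), numeric(1))
  kern <- hemodynamic_kernel(hemo, tg)
  resp <- stats::convolve(xt, rev(kern), type = "open")[seq_along(tg)] * dt_fine
  stats::approx(tg, resp, xout = tspan, rule = 2)$y
}
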