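#' Power-law fluctuation parameters
#'
#' Parameters of the power-law spectral model `g(omega) = alpha * omega^-beta`
#' used both for the endogenous neuronal fluctuations that drive the state
#' equation and for additive observation noise. `omega` is angular frequency
#' in rad/s and spectra follow the convention
#' `C(tau) = (1/2pi) \int g(omega) exp(i omega tau) d omega`,
#' so for `beta = 0` a series synthesised by [generate_fluctuations()] has
#' variance `alpha`. `beta = 0` is white noise; `beta = 1` is 1/f noise.
#'
#' @param alpha nonnegative amplitude (scalar).
#' @param beta nonnegative spectral exponent (scalar).
#' @return An object of class `fluctuation_params`.
#' @examples
#' fluctuation_params()            # endogenous default: 1/f with unit amplitude
#' fluctuation_params(0.005, 0)    # observation-noise default: weak white noise
#' @export
fluctuation_params <- function(alpha = 1, beta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a nonnegative scalar")
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta < 0)
    stop("`beta` must be a nonnegative scalar")
  structure(list(alpha = alpha, beta = beta), class = "fluctuation_params")
}

#' @export
print.fluctuation_params <- function(x, ...) {
  cat(sprintf("<fluctuation_params> alpha = %g, beta = %g (%s)\n",
              x$alpha, x$beta,
              if (x$beta == 0) "white" else sprintf("1/f^%g", x$beta)))
  invisible(x)
}

#' Synthesise power-law noise by spectral shaping
#'
#' Draws `n` independent columns of Gaussian noise whose expected
#' periodogram follows `alpha * omega^-beta`: white Gaussian noise is shaped
#' in the frequency domain by `sqrt(alpha * omega^-beta)`, the zero-frequency
#' bin is set to zero (no DC drift), and the result is transformed back.
#' For `beta = 0` the sample variance is `alpha` in expectation.
#'
#' @param n number of regions (columns).
#' @param T_sim number of samples (powers of two are fastest).
#' @param dt_sim sampling interval in seconds; must be at most 0.5 s so the
#'   grid oversamples the BOLD band.
#' @param params a [fluctuation_params()].
#' @param seed integer seed.
#' @return A `T_sim` x `n` numeric matrix.
#' @examples
#' v <- generate_fluctuations(2, 1024, 0.1, fluctuation_params(1, 0), seed = 1)
#' var(v[, 1])  # close to 1
#' @export
generate_fluctuations <- function(n, T_sim, dt_sim, params = fluctuation_params(),
                                  seed) {
  stopifnot(inherits(params, "fluctuation_params"))
  if (dt_sim <= 0 || dt_sim > 0.5)
    stop("`dt_sim` must be in (0, 0.5] s (integration grid finer than TR)")
  if (T_sim < 2) stop("`T_sim` must be at least 2")
  gen_powerlaw(n, T_sim, dt_sim, params, seed)
}

# spectral synthesis without the fine-grid precondition (observation noise
# is synthesised directly at the scanner interval)
gen_powerlaw <- function(n, T_sim, dt_sim, params, seed) {
  if (params$alpha == 0) return(matrix(0, T_sim, n))
  k <- 0:(T_sim - 1)
  kk <- pmin(k, T_sim - k)                    # fold to two-sided frequencies
  w <- 2 * pi * kk / (T_sim * dt_sim)
  filt <- ifelse(kk == 0, 0, sqrt(params$alpha) * w^(-params$beta / 2))
  withr::with_seed(as.integer(seed), {
    out <- matrix(0, T_sim, n)
    for (j in seq_len(n)) {
      z <- stats::rnorm(T_sim)
      out[, j] <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / T_sim
    }
    out
  })
}
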