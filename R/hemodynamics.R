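#' Linearised haemodynamic (balloon) model parameters
#'
#' The observation model linking neuronal activity to BOLD is the standard
#' balloon model (vasodilatory signal, inflow, blood volume,
#' deoxyhaemoglobin), linearised about its resting fixed point so that each
#' region's BOLD response is a single convolution kernel. Defaults are
#' canonical literature values and produce a kernel peaking near 4 s.
#'
#' @param decay vasodilatory signal decay rate, 1/s.
#' @param feedback autoregulatory feedback rate, 1/s.
#' @param transit mean vascular transit time, s.
#' @param stiffness vessel stiffness exponent (Grubb exponent), dimensionless.
#' @param extraction resting oxygen extraction fraction.
#' @param v0 resting venous blood volume fraction (output scaling).
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(decay = 0.64, feedback = 0.32, transit = 2.0,
                               stiffness = 0.32, extraction = 0.4, v0 = 0.04) {
  vals <- c(decay = decay, feedback = feedback, transit = transit,
            stiffness = stiffness, extraction = extraction, v0 = v0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all haemodynamic parameters must be positive and finite; got ",
         paste(sprintf("%s = %g", names(vals), vals), collapse = ", "))
  if (extraction >= 1) stop("`extraction` must be a fraction below 1")
  structure(as.list(vals), class = "hemodynamic_params")
}

#' @export
print.hemodynamic_params <- function(x, ...) {
  cat(sprintf(
    "<hemodynamic_params> decay %g /s, feedback %g /s, transit %g s, stiffness %g, extraction %g\n",
    x$decay, x$feedback, x$transit, x$stiffness, x$extraction))
  invisible(x)
}

# Linearised balloon system: states (s, f, v, q), input = neuronal activity,
# output = BOLD. Returns list(J, B, C).
balloon_system <- function(hemo) {
  k1 <- 7 * hemo$extraction
  k2 <- 2
  k3 <- 2 * hemo$extraction - 0.2
  cf <- 1 + (1 - hemo$extraction) * log(1 - hemo$extraction) / hemo$extraction
  tau <- hemo$transit
  a <- hemo$stiffness
  J <- rbind(c(-hemo$decay, -hemo$feedback, 0, 0),
             c(1, 0, 0, 0),
             c(0, 1 / tau, -1 / (tau * a), 0),
             c(0, cf / tau, -(1 / a - 1) / tau, -1 / tau))
  list(J = J, B = c(1, 0, 0, 0),
       C = hemo$v0 * c(0, 0, k2 - k3, -(k1 + k2)))
}

#' Time-domain haemodynamic kernel
#'
#' First-order BOLD impulse response implied by a [hemodynamic_params()]
#' object: `k(t) = C exp(J t) B` for the linearised balloon system,
#' evaluated via the eigendecomposition of the 4 x 4 state matrix.
#'
#' @param hemo a [hemodynamic_params()].
#' @param tgrid time points (s) at which to evaluate the kernel.
#' @return Numeric vector of kernel values (1/s scale: convolving a signal
#'   with `k` requires multiplying by the time step).
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' k <- hemodynamic_kernel(hemodynamic_params(), t)
#' t[which.max(k)]  # peak latency, about 4 s
#' @export
hemodynamic_kernel <- function(hemo = hemodynamic_params(), tgrid) {
  sys <- balloon_system(hemo)
  eg <- eigen(sys$J)
  wts <- as.vector(sys$C %*% eg$vectors) * solve(eg$vectors, sys$B)
  vapply(tgrid, function(t) Re(sum(wts * exp(eg$values * t))), numeric(1))
}

#' Haemodynamic transfer function
#'
#' Frequency response of the linearised haemodynamic kernel, evaluated on a
#' frequency grid. The response is low-pass: magnitude decreases above the
#' kernel's passband, which is what suppresses high-frequency neuronal
#' content in measured BOLD.
#'
#' @param hemo a [hemodynamic_params()] (or a list of them, one per region).
#' @param grid a [frequency_grid()] or numeric vector of frequencies in Hz.
#' @return Complex vector (one value per frequency) for a single parameter
#'   set, or a complex matrix (frequency x region) for a list.
#' @export
hemodynamic_transfer <- function(hemo = hemodynamic_params(), grid) {
  f <- grid_frequencies(grid)
  omega <- 2 * pi * f
  one <- function(h) {
    drop(cpp_balloon_transfer(omega, h$transit, h$decay, h$feedback,
                              h$stiffness, h$extraction, h$v0))
  }
  if (inherits(hemo, "hemodynamic_params")) return(one(hemo))
  vapply(hemo, one, complex(length(omega)))
}
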