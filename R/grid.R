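#' Frequency grids
#'
#' An ordered set of strictly positive frequencies (Hz) on which spectral
#' densities are evaluated. The default grid for a series of `T` volumes at
#' sampling interval `dt` spans 64 linear bins from the fundamental
#' `1/(T dt)` up to 0.25 Hz, the resolvable band at TR = 2 s.
#'
#' @param frequencies strictly increasing positive frequencies in Hz.
#' @param nyquist optional Nyquist frequency (Hz) used for validation.
#' @return An object of class `frequency_grid`.
#' @export
frequency_grid <- function(frequencies, nyquist = NULL) {
  f <- as.numeric(frequencies)
  if (length(f) < 1 || any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be finite and strictly positive")
  if (is.unsorted(f, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (!is.null(nyquist) && max(f) > nyquist + 1e-12)
    stop(sprintf("maximum frequency %.4f Hz exceeds the Nyquist limit %.4f Hz",
                 max(f), nyquist))
  structure(list(frequencies = f), class = "frequency_grid")
}

#' @rdname frequency_grid
#' @param n_volumes,dt series length and sampling interval defining the
#'   fundamental frequency.
#' @param n_bins number of linear bins.
#' @param fmax upper band edge in Hz.
#' @export
default_frequency_grid <- function(n_volumes = 170, dt = 2, n_bins = 64,
                                   fmax = 0.25) {
  f0 <- 1 / (n_volumes * dt)
  frequency_grid(seq(f0, fmax, length.out = n_bins), nyquist = 1 / (2 * dt))
}

#' @export
print.frequency_grid <- function(x, ...) {
  f <- x$frequencies
  cat(sprintf("<frequency_grid> %d bins, %.4f-%.4f Hz\n",
              length(f), min(f), max(f)))
  invisible(x)
}

grid_frequencies <- function(grid) {
  if (inherits(grid, "frequency_grid")) grid$frequencies
  else frequency_grid(grid)$frequencies
}
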