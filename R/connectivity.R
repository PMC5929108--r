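#' Effective connectivity matrices
#'
#' An effective connectivity matrix holds directed coupling rates (Hz) of a
#' linear neuronal state equation dx/dt = A x + v. Entry `A[i, j]` is the
#' influence of region `j` (source, column) on the rate of change of region
#' `i` (target, row). Valid matrices have strictly negative diagonals
#' (self-inhibition) and all eigenvalues with negative real part (stability).
#'
#' @param matrix real square matrix of coupling rates in Hz.
#' @param regions a [region_set()] (or character vector of labels) matching
#'   the matrix dimension.
#' @param check if `TRUE` (default) validate self-inhibition and stability.
#' @return An object of class `effective_connectivity`.
#' @export
effective_connectivity <- function(matrix, regions = NULL, check = TRUE) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("coupling matrix must be square")
  if (!all(is.finite(matrix))) stop("coupling matrix must be finite")
  if (is.null(regions)) {
    labs <- rownames(matrix)
    if (is.null(labs)) labs <- paste0("R", seq_len(nrow(matrix)))
    regions <- region_set(labs, rep("net1", nrow(matrix)))
  } else if (!inherits(regions, "region_set")) {
    regions <- region_set(regions, rep("net1", length(regions)))
  }
  if (nrow(regions) != nrow(matrix))
    stop("region set has ", nrow(regions), " regions but matrix is ",
         nrow(matrix), " x ", ncol(matrix))
  dimnames(matrix) <- list(regions$label, regions$label)
  if (check) {
    if (any(diag(matrix) >= 0))
      stop("diagonal entries must be strictly negative (self-inhibition); ",
           "offending region(s): ",
           paste(regions$label[diag(matrix) >= 0], collapse = ", "))
    assert_stable(matrix)
  }
  structure(list(matrix = matrix, regions = regions),
            class = "effective_connectivity")
}

#' @export
print.effective_connectivity <- function(x, ...) {
  ev <- eigen(x$matrix, only.values = TRUE)$values
  cat(sprintf(
    "<effective_connectivity> %d regions, max Re(eigenvalue) = %.3f Hz\n",
    nrow(x$matrix), max(Re(ev))))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Test dynamical stability of a coupling matrix
#'
#' @param A an `effective_connectivity` or plain square matrix.
#' @return `TRUE` if all eigenvalues have strictly negative real part.
#' @export
is_stable <- function(A) {
  A <- ec_matrix(A)
  all(Re(eigen(A, only.values = TRUE)$values) < 0)
}

assert_stable <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  worst <- ev[which.max(Re(ev))]
  if (Re(worst) >= 0)
    stop(sprintf(
      "coupling matrix is unstable: eigenvalue %.4f%+.4fi has nonnegative real part",
      Re(worst), Im(worst)))
  invisible(TRUE)
}

ec_matrix <- function(A) {
  if (inherits(A, "effective_connectivity")) A$matrix else as.matrix(A)
}

ec_regions <- function(A, default_n = NULL) {
  if (inherits(A, "effective_connectivity")) return(A$regions)
  n <- if (is.null(default_n)) nrow(as.matrix(A)) else default_n
  labs <- rownames(as.matrix(A))
  if (is.null(labs)) labs <- paste0("R", seq_len(n))
  region_set(labs, rep("net1", n))
}

#' Between-network coupling template used throughout the package
#'
#' The six between-network averages reported for the three-network system:
#' inhibitory influences of the salience and dorsal attention networks on the
#' core default network, and weaker excitatory influences everywhere else.
#' Rows index the target network, columns the source network.
#'
#' @return A 3 x 3 numeric matrix with `NA` on the diagonal (within-network
#'   coupling is set separately by [make_template_A()]).
#' @examples
#' default_between_means()
#' @export
default_between_means <- function() {
  m <- matrix(NA_real_, 3, 3, dimnames = list(target = c("cDN", "SN", "DAN"),
                                              source = c("cDN", "SN", "DAN")))
  m["cDN", "SN"] <- -0.13
  m["cDN", "DAN"] <- -0.10
  m["SN", "cDN"] <- 0.02
  m["SN", "DAN"] <- 0.02
  m["DAN", "cDN"] <- 0.02
  m["DAN", "SN"] <- 0.03
  m
}

#' Build a block-structured group template of effective connectivity
#'
#' Constructs an n x n coupling matrix in which every connection from a
#' region of network `b` to a region of network `a` equals the network-level
#' mean `between_means[a, b]`, every within-network off-diagonal equals
#' `within_strength`, and every diagonal equals `self_strength`. The result
#' must be dynamically stable, otherwise an error names the offending
#' eigenvalue.
#'
#' @param regions a [region_set()]; defaults to the packaged 15-region set.
#' @param between_means square numeric matrix of network-level couplings
#'   (Hz), rows = target network, columns = source network, with dimnames
#'   naming the networks. Defaults to [default_between_means()].
#' @param within_strength within-network off-diagonal coupling (Hz).
#' @param self_strength diagonal self-coupling (Hz); must be negative.
#' @return An [effective_connectivity()].
#' @examples
#' A <- make_template_A()
#' is_stable(A)
#' @export
make_template_A <- function(regions = load_region_fixture(),
                            between_means = default_between_means(),
                            within_strength = 0.1,
                            self_strength = -0.8) {
  regions <- as_region_set(regions)
  if (self_strength >= 0) stop("`self_strength` must be negative")
  nets <- unique(regions$network)
  bm <- as.matrix(between_means)
  if (length(nets) > 1) {
    if (is.null(rownames(bm)) || is.null(colnames(bm)))
      stop("`between_means` must have dimnames naming the networks")
    missing <- setdiff(nets, rownames(bm))
    if (length(missing))
      stop("`between_means` lacks rows for network(s): ",
           paste(missing, collapse = ", "))
  }
  n <- nrow(regions)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      A[i, j] <- self_strength
    } else if (regions$network[i] == regions$network[j]) {
      A[i, j] <- within_strength
    } else {
      A[i, j] <- bm[regions$network[i], regions$network[j]]
    }
  }
  if (anyNA(A)) stop("`between_means` contains NA for a required network pair")
  effective_connectivity(A, regions, check = TRUE)
}

#' Draw a subject-specific coupling matrix around a template
#'
#' Adds independent Gaussian variation (sd in Hz) to every off-diagonal
#' entry of the template, keeping the diagonal fixed, and redraws (up to
#' `max_retry` times) until the result is dynamically stable. This is the
#' random between-subject effect assumed by the hierarchical (parametric
#' empirical Bayes) model.
#'
#' @param template an [effective_connectivity()] group template.
#' @param sd standard deviation (Hz) of the off-diagonal variation.
#' @param seed integer seed; the draw is a pure function of
#'   `(template, sd, seed)`.
#' @param max_retry maximum number of stability redraws.
#' @return An [effective_connectivity()].
#' @export
sample_subject_A <- function(template, sd, seed, max_retry = 64L) {
  if (sd < 0) stop("`sd` must be nonnegative")
  A0 <- ec_matrix(template)
  n <- nrow(A0)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(max_retry)) {
      E <- matrix(stats::rnorm(n * n, 0, sd), n, n)
      diag(E) <- 0
      A1 <- A0 + E
      if (all(Re(eigen(A1, only.values = TRUE)$values) < 0))
        return(effective_connectivity(A1, ec_regions(template), check = FALSE))
    }
  })
  stop("no stable draw within ", max_retry, " retries; ",
       "consider a smaller `sd` (currently ", sd, " Hz)")
}
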