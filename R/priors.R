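#' Parameter vector layout of the spectral model
#'
#' The inversion estimates an ordered parameter vector: the `n(n-1)`
#' off-diagonal coupling rates (Hz, column-major), `n` self-connection
#' log-factors (the diagonal is realised as `-0.5 exp(theta)`, so it is
#' always negative), four log-scaling parameters of the endogenous and
#' observation power-law spectra, and `n` log-scaled transit-time deviations
#' of the haemodynamic model. A fully connected `n`-region model therefore
#' carries `n^2` intrinsic connectivity parameters (225 for 15 regions).
#'
#' @param regions a [region_set()] or integer number of regions.
#' @param bases named list of base values scaled by the log-parameters:
#'   `alpha_v`, `beta_v`, `alpha_e`, `beta_e`, `transit` (see
#'   [fluctuation_params()] and [hemodynamic_params()] for meaning).
#' @param hemo a [hemodynamic_params()] supplying the fixed haemodynamic
#'   constants (all but transit time are not estimated).
#' @return A data frame of class `param_map` with columns `name`, `type`
#'   (`A`, `self`, `spectral`, `transit`), `source`, `target`, plus
#'   attributes `n`, `bases`, `hemo`.
#' @export
param_map <- function(regions, bases = list(alpha_v = 1, beta_v = 1,
                                            alpha_e = 0.005, beta_e = 0),
                      hemo = hemodynamic_params()) {
  regions <- if (is.numeric(regions) && length(regions) == 1)
    region_set(paste0("R", seq_len(regions)), rep("net1", regions))
  else as_region_set(regions)
  n <- nrow(regions)
  labs <- regions$label
  src <- rep(labs, each = n)
  tgt <- rep(labs, n)
  off <- src != tgt
  df <- rbind(
    data.frame(name = sprintf("A[%s<-%s]", tgt[off], src[off]),
               type = "A", source = src[off], target = tgt[off]),
    data.frame(name = sprintf("self[%s]", labs),
               type = "self", source = labs, target = labs),
    data.frame(name = c("log_alpha_v", "log_beta_v",
                        "log_alpha_e", "log_beta_e"),
               type = "spectral", source = NA, target = NA),
    data.frame(name = sprintf("transit[%s]", labs),
               type = "transit", source = labs, target = labs)
  )
  bases <- utils::modifyList(
    list(alpha_v = 1, beta_v = 1, alpha_e = 0.005, beta_e = 0), bases)
  structure(df, class = c("param_map", "data.frame"),
            n = n, regions = regions, bases = bases, hemo = hemo)
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %d parameters for %d regions (%d connectivity)\n",
              nrow(x), attr(x, "n"), attr(x, "n")^2))
  invisible(x)
}

#' Priors over the spectral model parameters
#'
#' Shrinkage priors in the style of sparse connectivity estimation:
#' off-diagonal couplings have mean 0 and variance 1/64 Hz^2; when a
#' functional connectivity matrix is supplied, connections whose absolute
#' correlation falls below `fc_threshold` are shrunk to variance 1/512
#' (functional connectivity furnishing priors on effective connectivity).
#' Self-connection factors get variance 1/16, spectral and transit
#' log-parameters 1/64. A zero prior variance marks a parameter as fixed at
#' its prior mean (the observation-noise exponent is fixed when its base
#' value is 0, i.e. white observation noise).
#'
#' @param regions a [region_set()] or number of regions.
#' @param fc optional [fc_matrix()] used to shrink implausible connections.
#' @param scheme named list overriding `a_var`, `a_var_shrunk`,
#'   `fc_threshold`, `self_var`, `spectral_var`, `transit_var`.
#' @param map optional [param_map()] (built from `regions` otherwise).
#' @return An object of class `dcm_priors`: list with `mean`, `var` (named
#'   vectors) and `map`.
#' @export
default_priors <- function(regions, fc = NULL, scheme = list(), map = NULL) {
  if (is.null(map)) map <- param_map(regions)
  sch <- utils::modifyList(
    list(a_var = 1 / 64, a_var_shrunk = 1 / 512, fc_threshold = 0.1,
         self_var = 1 / 16, spectral_var = 1 / 64, transit_var = 1 / 64),
    scheme)
  P <- nrow(map)
  mu <- stats::setNames(numeric(P), map$name)
  v <- stats::setNames(numeric(P), map$name)
  v[map$type == "A"] <- sch$a_var
  v[map$type == "self"] <- sch$self_var
  v[map$type == "spectral"] <- sch$spectral_var
  v[map$type == "transit"] <- sch$transit_var
  bases <- attr(map, "bases")
  if (bases$beta_e == 0) v["log_beta_e"] <- 0   # white noise: exponent fixed
  if (!is.null(fc)) {
    stopifnot(inherits(fc, "fc_matrix"))
    R <- fc$values
    ai <- which(map$type == "A")
    for (k in ai) {
      r <- R[map$target[k], map$source[k]]
      if (abs(r) < sch$fc_threshold) v[k] <- sch$a_var_shrunk
    }
  }
  structure(list(mean = mu, var = v, map = map, scheme = sch),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat(sprintf("<dcm_priors> %d parameters (%d free, %d fixed)\n",
              length(x$mean), sum(x$var > 0), sum(x$var == 0)))
  invisible(x)
}
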