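# Network-level statistics: Bayesian contrasts over the posterior, 3 x 3
# between-network connectivity averages, per-network hierarchy strength,
# and hierarchical clustering of connectivity profiles.

#' Bayesian contrast of a Gaussian posterior
#'
#' For a contrast vector `c` over the `P` parameters of a posterior
#' `N(M, Sigma)`, the contrast has expectation `mu = c'M`, variance
#' `sigma2 = c' Sigma c`, and a posterior probability of being nonzero from
#' the Gaussian tail: one-sided `P(contrast > 0)` by default, or the
#' two-sided probability that it differs from zero in the direction of its
#' mean.
#'
#' @param post a Gaussian posterior (`M`, `Sigma`).
#' @param c numeric contrast weights, length `P` (or named, matched against
#'   parameter names).
#' @param sided `"one"` or `"two"`.
#' @return An object of class `dcm_contrast`: list with `c`, `mu`,
#'   `sigma2`, `p_nonzero`.
#' @export
contrast <- function(post, c, sided = c("one", "two")) {
  sided <- match.arg(sided)
  g <- gaussian_parts(post)
  P <- length(g$mean)
  if (!is.null(names(c)) && !is.null(names(g$mean))) {
    cv <- stats::setNames(numeric(P), names(g$mean))
    if (!all(names(c) %in% names(cv)))
      stop("unknown parameter name(s) in contrast: ",
           paste(setdiff(names(c), names(cv)), collapse = ", "))
    cv[names(c)] <- c
    c <- cv
  }
  if (length(c) != P)
    stop("contrast has length ", length(c), " but the posterior has ",
         P, " parameters")
  mu <- sum(c * g$mean)
  sigma2 <- max(drop(t(c) %*% as.matrix(g$cov) %*% c), 0)
  p <- if (sigma2 == 0) {
    if (mu == 0) 0.5 else 1
  } else if (sided == "one") {
    stats::pnorm(mu / sqrt(sigma2))
  } else {
    2 * stats::pnorm(abs(mu) / sqrt(sigma2)) - 1
  }
  structure(list(c = c, mu = mu, sigma2 = sigma2, p_nonzero = p,
                 sided = sided),
            class = "dcm_contrast")
}

#' @export
print.dcm_contrast <- function(x, ...) {
  cat(sprintf("<contrast> mu = %.4f, sd = %.4f, p(%s) = %.3f\n",
              x$mu, sqrt(x$sigma2),
              if (x$sided == "one") ">0" else "!=0", x$p_nonzero))
  invisible(x)
}

#' Between-network average connectivity
#'
#' Computes the 3 x 3 (or k x k) matrix of network-level average coupling:
#' each cell is a Bayesian contrast with equal weights over all connections
#' from the source network to the target network (within-network cells use
#' the off-diagonal connections only), so each average carries both an
#' expectation and a posterior uncertainty from the full covariance.
#'
#' @param post a Gaussian posterior over model parameters whose `A[...]`
#'   entries are coupling rates, or an [effective_connectivity()] (treated
#'   as a point mass).
#' @param partition a [region_set()] giving each region's network.
#' @param sided tail convention passed to [contrast()].
#' @return An object of class `network_averages`: list of matrices `mean`,
#'   `var`, `p` (target network x source network) plus the per-cell
#'   connection counts.
#' @export
between_network_average <- function(post, partition = NULL,
                                    sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (inherits(post, "effective_connectivity")) {
    if (is.null(partition)) partition <- post$regions
    post <- ec_point_posterior(post)
  }
  if (is.null(partition)) {
    if (!is.null(post$map)) partition <- attr(post$map, "regions")
    if (is.null(partition)) stop("a region partition is required")
  }
  partition <- as_region_set(partition)
  g <- gaussian_parts(post)
  nm <- names(g$mean)
  if (is.null(nm) || !any(startsWith(nm, "A[")))
    stop("posterior does not carry named `A[target<-source]` parameters")
  nets <- levels(network_factor(partition))
  k <- length(nets)
  mean_m <- var_m <- p_m <- cnt <- matrix(
    NA_real_, k, k, dimnames = list(target = nets, source = nets))
  net_of <- stats::setNames(partition$network, partition$label)
  ai <- which(startsWith(nm, "A["))
  asrc <- sub("^A\\[.*<-(.*)\\]$", "\\1", nm[ai])
  atgt <- sub("^A\\[(.*)<-.*\\]$", "\\1", nm[ai])
  for (a in nets) for (b in nets) {
    pick <- ai[net_of[atgt] == a & net_of[asrc] == b]
    if (!length(pick))
      stop("no connections from network ", b, " to network ", a)
    cw <- stats::setNames(rep(1 / length(pick), length(pick)), nm[pick])
    ct <- contrast(post, cw, sided = sided)
    mean_m[a, b] <- ct$mu
    var_m[a, b] <- ct$sigma2
    p_m[a, b] <- ct$p_nonzero
    cnt[a, b] <- length(pick)
  }
  structure(list(mean = mean_m, var = var_m, p = p_m, count = cnt,
                 networks = nets, sided = sided),
            class = "network_averages")
}

#' @rdname between_network_average
#' @param values,networks for `network_averages()`: directly supply the
#'   k x k matrix of cell means (target x source) and the network order,
#'   e.g. to reproduce printed results.
#' @export
network_averages <- function(values, networks = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(networks)) stop("`networks` (cell order) is required")
  dimnames(values) <- list(target = networks, source = networks)
  structure(list(mean = values,
                 var = matrix(0, nrow(values), ncol(values),
                              dimnames = dimnames(values)),
                 p = matrix(NA_real_, nrow(values), ncol(values)),
                 count = matrix(NA_real_, nrow(values), ncol(values)),
                 networks = networks, sided = "two"),
            class = "network_averages")
}

# point-mass posterior over the A parameters of a coupling matrix
ec_point_posterior <- function(A) {
  Am <- ec_matrix(A)
  regions <- ec_regions(A)
  map <- param_map(regions)
  M <- stats::setNames(numeric(nrow(map)), map$name)
  ai <- which(map$type == "A")
  for (k in ai) M[k] <- Am[map$target[k], map$source[k]]
  si <- which(map$type == "self")
  M[si] <- log(pmax(diag(Am) / -0.5, 1e-12))
  out <- list(M = M, Sigma = matrix(0, nrow(map), nrow(map),
                                    dimnames = list(map$name, map$name)),
              F = NA_real_, map = map)
  class(out) <- "dcm_posterior"
  out
}

#' @export
print.network_averages <- function(x, ...) {
  cat("<network_averages> mean coupling (Hz), target x source:\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' Hierarchy strength of a network
#'
#' Ranks networks by the difference between their unsigned efferent and
#' afferent between-network average connections:
#' `score = sum_j |avg(net -> j)| - sum_j |avg(j -> net)|` over the other
#' networks `j`. A positive score marks a net sender (higher in the
#' hierarchy); a negative score a net receiver. `form = "mean"` divides
#' each sum by the number of other networks.
#'
#' @param avgs a [between_network_average()] result (or
#'   [network_averages()] built from printed cell values).
#' @param network network name, or `NULL` for all networks.
#' @param form `"sum"` (default; matches the printed arithmetic of the
#'   worked example) or `"mean"`.
#' @return Named numeric vector of class `hierarchy_score` with the
#'   formula trace in attribute `trace`.
#' @examples
#' nv <- network_averages(rbind(c(NA, -0.13, -0.10),
#'                              c(0.02, NA, 0.02),
#'                              c(0.02, 0.03, NA)),
#'                        networks = c("cDN", "SN", "DAN"))
#' hierarchy_strength(nv)   # SN 0.12, DAN 0.07, cDN -0.19
#' @export
hierarchy_strength <- function(avgs, network = NULL,
                               form = c("sum", "mean")) {
  stopifnot(inherits(avgs, "network_averages"))
  form <- match.arg(form)
  nets <- avgs$networks
  if (is.null(network)) network <- nets
  if (!all(network %in% nets))
    stop("unknown network(s): ", paste(setdiff(network, nets), collapse = ", "))
  M <- avgs$mean
  trace <- list()
  score <- vapply(network, function(nw) {
    others <- setdiff(nets, nw)
    eff <- M[others, nw]      # nw -> others: column nw, rows = targets
    aff <- M[nw, others]      # others -> nw: row nw
    sc <- sum(abs(eff)) - sum(abs(aff))
    if (form == "mean") sc <- sc / length(others)
    trace[[nw]] <<- list(
      efferent = stats::setNames(eff, paste0(nw, "->", others)),
      afferent = stats::setNames(aff, paste0(others, "->", nw)))
    sc
  }, numeric(1))
  structure(stats::setNames(score, network), class = "hierarchy_score",
            form = form, trace = trace)
}

#' @export
print.hierarchy_score <- function(x, ...) {
  cat(sprintf("<hierarchy_score> (%s of unsigned efferent - afferent)\n",
              attr(x, "form")))
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}

#' Hierarchical clustering of connectivity profiles
#'
#' Agglomerative clustering of regions by their connectivity profiles: each
#' region is described by its concatenated afferent row and efferent column
#' (self entry excluded), distances are correlation distances
#' `1 - cor(profile_i, profile_j)`, and linkage is average by default. The
#' same procedure applies to effective (directed) and functional
#' (symmetric) connectivity, so their partitions can be compared directly.
#'
#' @param x an [effective_connectivity()], [fc_matrix()], or labelled
#'   square matrix.
#' @param k number of clusters to cut (>= 2).
#' @param options list; `distance` (only `"correlation"`), `linkage`
#'   (passed to [stats::hclust()], default `"average"`).
#' @return An object of class `cluster_result`: `labels` (named cluster
#'   assignment), `tree` (the `hclust` object), `k`, `order`.
#' @export
cluster_regions <- function(x, k = 2, options = list()) {
  opt <- utils::modifyList(list(distance = "correlation",
                                linkage = "average"), options)
  M <- if (inherits(x, "effective_connectivity")) x$matrix
  else if (inherits(x, "fc_matrix")) x$values
  else as.matrix(x)
  if (nrow(M) != ncol(M)) stop("connectivity matrix must be square")
  if (k < 2 || k > nrow(M)) stop("`k` must be between 2 and the number of regions")
  labs <- rownames(M)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(M)))
  n <- nrow(M)
  profiles <- t(vapply(seq_len(n), function(i)
    c(M[i, -i], M[-i, i]), numeric(2 * (n - 1))))
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("constant connectivity profile (zero variance) for region(s): ",
         paste(labs[sds == 0], collapse = ", "))
  D <- stats::as.dist(1 - stats::cor(t(profiles)))
  tree <- stats::hclust(D, method = opt$linkage)
  tree$labels <- labs
  cl <- stats::cutree(tree, k = k)
  structure(list(labels = stats::setNames(cl, labs), tree = tree, k = k,
                 order = labs[tree$order]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d:\n", x$k))
  for (g in sort(unique(x$labels)))
    cat(sprintf("  %d: %s\n", g, paste(names(x$labels)[x$labels == g],
                                       collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' regions: 1 for identical partitions (up to relabelling), approximately 0
#' for independent random labels.
#'
#' @param a,b cluster assignments ([cluster_regions()] results, or vectors
#'   of labels over the same regions).
#' @return Scalar adjusted Rand index in `[-1, 1]`.
#' @export
compare_partitions <- function(a, b) {
  la <- if (inherits(a, "cluster_result")) a$labels else a
  lb <- if (inherits(b, "cluster_result")) b$labels else b
  if (length(la) != length(lb))
    stop("partitions cover different numbers of regions")
  if (!is.null(names(la)) && !is.null(names(lb))) {
    if (!setequal(names(la), names(lb)))
      stop("partitions cover different region sets")
    lb <- lb[names(la)]
  }
  tab <- table(la, lb)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)   # both partitions trivial
  (nij - expected) / (maxi - expected)
}
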