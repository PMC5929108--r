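#' Region sets and network partitions
#'
#' A region set names the nodes of the model and assigns each to one of the
#' three resting-state networks under study: the core default network (cDN),
#' the salience network (SN) and the dorsal attention network (DAN).
#' Optional MNI coordinates (mm) are carried along for reporting.
#'
#' @param labels character vector of unique region names.
#' @param networks character vector of network tags, one per region
#'   (values among `"cDN"`, `"SN"`, `"DAN"` for the packaged networks;
#'   other tags are allowed for toy problems).
#' @param coordinates optional numeric matrix (n x 3) of MNI coordinates.
#' @return An object of class `region_set`: a data frame with columns
#'   `label`, `network` and optionally `x`, `y`, `z`.
#' @examples
#' region_set(c("a", "b", "c"), c("SN", "SN", "DAN"))
#' @export
region_set <- function(labels, networks, coordinates = NULL) {
  labels <- as.character(labels)
  networks <- as.character(networks)
  if (length(labels) != length(networks))
    stop("`labels` and `networks` must have the same length")
  if (anyDuplicated(labels))
    stop("region labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyNA(labels) || anyNA(networks))
    stop("region labels and network tags must not contain NA")
  df <- data.frame(label = labels, network = networks,
                   stringsAsFactors = FALSE)
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != length(labels) || ncol(coordinates) != 3)
      stop("`coordinates` must be an n x 3 matrix of MNI coordinates")
    df$x <- coordinates[, 1]
    df$y <- coordinates[, 2]
    df$z <- coordinates[, 3]
  }
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions in %d networks (%s)\n",
              nrow(x), length(unique(x$network)),
              paste(sprintf("%s: %d", names(table(x$network)),
                            table(x$network)), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Packaged 15-region fixture
#'
#' Returns the packaged set of 15 group-level volumes of interest: 4 core
#' default network regions (PCC, aMPFC, bilateral angular gyrus), 5 salience
#' network regions (dACC, bilateral anterior insula, bilateral anterior PFC)
#' and 6 dorsal attention network regions (bilateral FEF, IFG and IPS), with
#' their MNI peak coordinates.
#'
#' @return A [region_set()] with 15 rows.
#' @examples
#' load_region_fixture()
#' @export
load_region_fixture <- function() {
  path <- system.file("extdata", "regions.csv", package = "specdcm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_set(df$label, df$network, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname load_region_fixture
#' @export
default_regions <- load_region_fixture

# network factor in canonical order (cDN, SN, DAN first, extras after)
network_factor <- function(regions) {
  nets <- unique(regions$network)
  canon <- c("cDN", "SN", "DAN")
  lev <- c(intersect(canon, nets), setdiff(nets, canon))
  factor(regions$network, levels = lev)
}

as_region_set <- function(x) {
  if (inherits(x, "region_set")) return(x)
  if (is.factor(x) || is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("R", seq_along(x))
    return(region_set(nm, as.character(x)))
  }
  stop("cannot interpret `", deparse(substitute(x)), "` as a region set")
}
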