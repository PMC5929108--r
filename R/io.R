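# Plain-text readers and writers. Every connectivity matrix on disk carries
# an explicit orientation comment (row = target, column = source), the
# single most common source of silent bugs in connectivity work; readers
# refuse files whose comment disagrees.

orientation_comment <- "# orientation: row=target, column=source"

#' Read and write labelled square matrices as CSV
#'
#' The on-disk format is a comment line stating the orientation convention,
#' then a CSV with region labels as both header and first column. Reading a
#' file whose orientation comment disagrees with the package convention is
#' an error, as are label mismatches, non-square data and missing cells.
#' Write-then-read round-trips are value-identical to 1e-12.
#'
#' @param path file path.
#' @return `read_matrix_csv()`: the labelled numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  has_comment <- startsWith(lines[1], "#")
  if (has_comment) {
    cm <- gsub("\\s", "", lines[1])
    if (grepl("orientation", cm) &&
        cm != gsub("\\s", "", orientation_comment))
      stop("line 1 of ", path, ": orientation comment disagrees with the ",
           "package convention (row=target, column=source): ", lines[1])
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  labs <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  offset <- 1 + has_comment  # header line(s) before data
  if (nrow(M) != ncol(M))
    stop(path, ": matrix is not square (", nrow(M), " rows, ",
         ncol(M), " columns)")
  if (!identical(labs, colnames(M)))
    stop(path, ": row labels do not match column labels (first mismatch ",
         "at data line ", which(labs != colnames(M))[1] + offset, ")")
  bad <- which(!is.finite(M), arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": non-numeric or missing cell at data line ",
         bad[1, 1] + offset, ", column ", bad[1, 2] + 1)
  rownames(M) <- labs
  M
}

#' @rdname read_matrix_csv
#' @param matrix labelled square matrix (or [effective_connectivity()] /
#'   [fc_matrix()]).
#' @export
write_matrix_csv <- function(matrix, path) {
  M <- if (inherits(matrix, "effective_connectivity")) matrix$matrix
  else if (inherits(matrix, "fc_matrix")) matrix$values
  else as.matrix(matrix)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  labs <- rownames(M)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(M)))
  dimnames(M) <- list(labs, labs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(orientation_comment, con)
  writeLines(paste(c("region", labs), collapse = ","), con)
  for (i in seq_len(nrow(M)))
    writeLines(paste(c(labs[i], format(M[i, ], digits = 17)),
                     collapse = ","), con)
  invisible(path)
}

#' Write and read a cohort directory
#'
#' Lays a [generate_cohort()] result out as plain text: one CSV per subject
#' (header = region labels, one row per volume), `regions.csv`, per-subject
#' ground-truth coupling matrices under `truth/`, and `config.json` with
#' all generation parameters and seeds.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(cohort$regions),
                   file.path(dir, "regions.csv"), row.names = FALSE)
  for (nm in names(cohort$subjects)) {
    utils::write.csv(as.data.frame(cohort$subjects[[nm]]$data),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    write_matrix_csv(cohort$truth[[nm]],
                     file.path(dir, "truth", paste0(nm, ".csv")))
  }
  write_matrix_csv(cohort$template, file.path(dir, "truth", "template.csv"))
  cfg <- cohort$config
  cfg$regions <- NULL
  cfg$fluct <- unclass(cfg$fluct)
  cfg$obs_noise <- unclass(cfg$obs_noise)
  cfg$hemo <- unclass(cfg$hemo)
  cfg$template$between_means <- as.data.frame(cfg$template$between_means)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_subjects <- function(dir) {
  reg <- utils::read.csv(file.path(dir, "regions.csv"),
                         stringsAsFactors = FALSE)
  regions <- region_set(reg$label, reg$network,
                        if (all(c("x", "y", "z") %in% names(reg)))
                          as.matrix(reg[, c("x", "y", "z")]) else NULL)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^sub-.*\\.csv$",
                           full.names = TRUE))
  subjects <- lapply(files, function(f) {
    subject_ts(as.matrix(utils::read.csv(f, check.names = FALSE)),
               dt = cfg$dt, regions = regions)
  })
  names(subjects) <- sub("\\.csv$", "", basename(files))
  list(subjects = subjects, regions = regions, config = cfg)
}

#' Serialise a posterior as JSON
#'
#' @param post a `dcm_posterior`.
#' @param path output file.
#' @export
write_posterior_json <- function(post, path) {
  g <- gaussian_parts(post)
  jsonlite::write_json(
    list(names = names(g$mean), M = unname(g$mean),
         Sigma = unname(as.matrix(g$cov)), F = post$F,
         lambda = post$lambda, converged = post$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_json
#' @export
read_posterior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- x$Sigma
  if (!is.matrix(S)) S <- do.call(rbind, lapply(S, unlist))
  dimnames(S) <- list(x$names, x$names)
  out <- list(M = stats::setNames(x$M, x$names), Sigma = S,
              F = x$F, lambda = x$lambda, converged = x$converged)
  class(out) <- "dcm_posterior"
  out
}
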