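#' Read and write region time series as delimited text
#'
#' Tab-separated values with a header row of region labels; full-precision
#' locale-independent numeric formatting. Sampling rate and provenance
#' tags travel in a sidecar manifest (see [write_manifest()]) or can be
#' given at read time.
#'
#' @param ts a [region_ts()].
#' @param path file path.
#' @return `write_region_ts()` returns `path` invisibly;
#'   `read_region_ts()` returns a `region_ts`.
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ts$labels, collapse = "\t"), con)
  utils::write.table(format(ts$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_region_ts
#' @param sampling_rate sampling rate in Hz to attach on read.
#' @param subject_id,modality,band optional tags to attach on read.
#' @export
read_region_ts <- function(path, sampling_rate, subject_id = NULL,
                           modality = NULL, band = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) abort(sprintf("%s: need a header and data rows.", path))
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  M <- parse_numeric_block(lines[-1], length(labels), path, offset = 1L)
  colnames(M) <- labels
  region_ts(M, sampling_rate, labels, subject_id, modality, band)
}

parse_numeric_block <- function(lines, ncol_expected, path, offset = 0L) {
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != ncol_expected) {
      abort(sprintf("%s: line %d has %d fields, expected %d.",
                    path, i + offset, length(fields), ncol_expected))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      abort(sprintf("%s: line %d contains non-numeric fields.", path, i + offset))
    }
    vals
  })
  do.call(rbind, rows)
}

#' Read and write connectomes as square delimited matrices
#'
#' First line is the label header; the square numeric block follows. The
#' kind and shrinkage intensity are stored in a leading comment line.
#'
#' @param cn a [connectome()].
#' @param path file path.
#' @return `write_connectome()` returns `path` invisibly;
#'   `read_connectome()` returns a `connectome`.
#' @export
write_connectome <- function(cn, path) {
  stopifnot(inherits(cn, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s lambda=%s", cn$kind,
                     format(cn$shrinkage_lambda, digits = 17)), con)
  writeLines(paste(cn$labels, collapse = "\t"), con)
  utils::write.table(format(cn$matrix, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  lines <- readLines(path)
  kind <- "covariance"; lambda <- NA_real_
  if (length(lines) >= 1 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("kind=(\\S+) lambda=(\\S+)", lines[1]))[[1]]
    if (length(m) == 3) {
      kind <- m[2]
      lambda <- suppressWarnings(as.numeric(m[3]))
    }
    lines <- lines[-1]
  }
  if (length(lines) < 2) abort(sprintf("%s: need a header and matrix rows.", path))
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  M <- parse_numeric_block(lines[-1], length(labels), path, offset = 2L)
  if (nrow(M) != length(labels)) {
    abort(sprintf("%s: matrix is %d x %d but header names %d regions.",
                  path, nrow(M), ncol(M), length(labels)))
  }
  dimnames(M) <- list(labels, labels)
  connectome(symmetrize(M), labels = labels, kind = kind,
             shrinkage_lambda = lambda)
}

#' Read and write edge datasets with an edge-index sidecar
#'
#' The main file is a subjects-by-edges tab-separated table; the sidecar
#' (same path plus `.index`) names the region pair of each column.
#'
#' @param ed an [edge_dataset()].
#' @param path file path for the data table.
#' @return `write_edge_dataset()` returns `path` invisibly;
#'   `read_edge_dataset()` returns an `edge_dataset`.
#' @export
write_edge_dataset <- function(ed, path) {
  stopifnot(inherits(ed, "edge_dataset"))
  utils::write.table(format(ed$matrix, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(ed$edge_index)) {
    utils::write.table(ed$edge_index, paste0(path, ".index"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_edge_dataset
#' @param band,modality,labels optional tags to attach on read.
#' @export
read_edge_dataset <- function(path, band = NULL, modality = NULL,
                              labels = NULL) {
  lines <- readLines(path)
  first_width <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  M <- parse_numeric_block(lines, first_width, path)
  idx_path <- paste0(path, ".index")
  idx <- if (file.exists(idx_path)) {
    as_tibble(utils::read.table(idx_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  } else NULL
  edge_dataset(M, edge_index = idx, band = band, modality = modality,
               labels = labels)
}

#' Write or read a run manifest
#'
#' Structured-text (JSON) record of the provenance of a run directory:
#' subjects, modalities, bands, sampling rates, seeds, and file paths.
#'
#' @param manifest a named list.
#' @param path file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize a fitted sparse CCA model
#'
#' Writes the canonical vector matrices, canonical correlations, penalties,
#' stored column means and provenance to a single structured-text (JSON)
#' archive; `read_scca_model()` restores the fitted object exactly.
#'
#' @param model an [scca_fit()].
#' @param path file path (JSON).
#' @return `write_scca_model()` returns `path` invisibly;
#'   `read_scca_model()` returns the `scca_fit` object.
#' @export
write_scca_model <- function(model, path) {
  stopifnot(inherits(model, "scca_fit"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_scca_model
#' @export
read_scca_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("U", "V")) x[[nm]] <- as.matrix(x[[nm]])
  if (is.list(x$objectives)) x$objectives <- lapply(x$objectives, as.numeric)
  x$K <- as.integer(x$K)
  structure(x, class = "scca_fit")
}

#' Write or read a selection profile as a delimited table
#'
#' One row per column of either block (`block`, `edge`, `column`,
#' `probability`), preceded by a comment line carrying the run parameters
#' so the profile can be reconstructed.
#'
#' @param profile a [randomized_scca()] result.
#' @param path file path.
#' @return `write_selection_profile()` returns `path` invisibly;
#'   `read_selection_profile()` returns a `selection_profile`.
#' @export
write_selection_profile <- function(profile, path) {
  stopifnot(inherits(profile, "selection_profile"))
  tab <- tidy(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_reps=%d c1=%s c2=%s seed=%s weights=%s",
                     profile$n_reps,
                     format(profile$c1, digits = 17),
                     format(profile$c2, digits = 17),
                     format(profile$seed),
                     paste(profile$weight_set, collapse = ",")), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection_profile
#' @export
read_selection_profile <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("n_reps=(\\S+) c1=(\\S+) c2=(\\S+) seed=(\\S+) weights=(\\S+)",
                          header))[[1]]
  if (length(m) != 6) abort(sprintf("%s: line 1 is not a profile header.", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE)
  ys <- tab[tab$block == "y", , drop = FALSE]
  xs <- tab[tab$block != "y", , drop = FALSE]
  xs <- xs[order(xs$column), , drop = FALSE]
  offsets <- NULL
  if (!identical(unique(xs$block), "x")) {
    agg <- lapply(split(xs, factor(xs$block, levels = unique(xs$block))),
                  function(b) c(start = min(b$column), end = max(b$column)))
    offsets <- tibble(band = names(agg),
                      start = vapply(agg, `[[`, numeric(1), "start"),
                      end = vapply(agg, `[[`, numeric(1), "end"))
  }
  structure(
    list(x_probability = xs$probability[order(xs$column)],
         y_probability = ys$probability[order(ys$column)],
         n_reps = as.integer(m[2]), c1 = as.numeric(m[3]),
         c2 = as.numeric(m[4]), K = NA_integer_,
         weight_set = as.numeric(strsplit(m[6], ",")[[1]]),
         seed = as.integer(m[5]), band_offsets = offsets,
         edge_index = NULL),
    class = "selection_profile")
}
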