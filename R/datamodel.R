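#' @keywords internal
"_PACKAGE"

#' Construct a marker matrix
#'
#' The central container of the pipeline: a samples x loci table of dominant
#' marker calls. Calls are stored as an integer matrix with 1 = band present,
#' 0 = band absent, `NA` = missing. Replicate re-genotypings of a sample are
#' ordinary rows flagged through `replicate_of`, a named character vector
#' mapping each replicate row id to the id of the original sample.
#'
#' @param calls numeric/integer/logical matrix with unique rownames (sample
#'   ids) and colnames (locus ids); entries must be 0, 1 or NA.
#' @param replicate_of named character vector: names are replicate sample ids,
#'   values the original sample ids. May be `NULL` (no replicates).
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, replicate_of = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("marker matrix needs at least 1 sample and 1 locus")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(calls))) {
    stop("duplicate locus ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  }
  bad <- which(!(calls %in% c(0L, 1L, NA_integer_)), arr.ind = FALSE)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf("invalid call '%s' at sample '%s', locus '%s' (only 0/1/missing allowed)",
                 calls[bad[1]], rownames(calls)[i[1]], colnames(calls)[i[2]]))
  }
  replicate_of <- replicate_of %||% character(0)
  if (length(replicate_of)) {
    replicate_of <- vapply(replicate_of, as.character, "")
    if (is.null(names(replicate_of)) || any(!nzchar(names(replicate_of)))) {
      stop("replicate_of must be a named character vector")
    }
    missing_rep <- setdiff(names(replicate_of), rownames(calls))
    if (length(missing_rep)) {
      stop("replicate ids not in matrix: ", paste(missing_rep, collapse = ", "))
    }
    missing_orig <- setdiff(unname(replicate_of), rownames(calls))
    if (length(missing_orig)) {
      stop("replicate_of targets not in matrix: ", paste(missing_orig, collapse = ", "))
    }
  }
  structure(calls, replicate_of = replicate_of, class = c("marker_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d samples x %d loci (%d replicate rows, %d missing calls)\n",
              nrow(x), ncol(x), length(attr(x, "replicate_of")), sum(is.na(x))))
  invisible(x)
}

#' Sample ids of a marker matrix
#' @param x a `marker_matrix`
#' @param replicates if FALSE, replicate rows are excluded
#' @return character vector of sample ids
#' @export
sample_ids <- function(x, replicates = TRUE) {
  ids <- rownames(x)
  if (!replicates) ids <- setdiff(ids, names(attr(x, "replicate_of")))
  ids
}

#' Drop replicate rows from a marker matrix
#'
#' Distance, tree, clustering and AMOVA computations operate on the main
#' samples only; replicate rows exist for quality control.
#' @param x a `marker_matrix`
#' @return a `marker_matrix` without replicate rows
#' @export
drop_replicates <- function(x) {
  keep <- sample_ids(x, replicates = FALSE)
  marker_matrix(unclass(x)[keep, , drop = FALSE])
}

#' Replicate pairs of a marker matrix
#' @param x a `marker_matrix`
#' @return data.frame with columns `replicate` and `original`
#' @export
replicate_pairs <- function(x) {
  ro <- attr(x, "replicate_of")
  data.frame(replicate = names(ro) %||% character(0),
             original = unname(ro), stringsAsFactors = FALSE)
}

#' Construct a sample metadata table
#'
#' Per-sample metadata: population assignment, optional group (MOTU) label,
#' island, and decimal geographic coordinates. Unknown columns are preserved.
#'
#' @param df data.frame with at least `sample_id` and `population_id` columns;
#'   optional `group_id`, `island`, `latitude`, `longitude`.
#' @return a validated data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "population_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks required column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$population_id <- as.character(df$population_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  empty <- which(is.na(df$population_id) | !nzchar(trimws(df$population_id)))
  if (length(empty)) stop("population_id empty for row(s): ",
                          paste(empty, collapse = ", "))
  if ("latitude" %in% names(df)) {
    bad <- which(!is.na(df$latitude) & (df$latitude < -90 | df$latitude > 90))
    if (length(bad)) stop("latitude outside [-90, 90] for row(s): ",
                          paste(bad, collapse = ", "))
  }
  if ("longitude" %in% names(df)) {
    bad <- which(!is.na(df$longitude) & (df$longitude < -180 | df$longitude > 180))
    if (length(bad)) stop("longitude outside [-180, 180] for row(s): ",
                          paste(bad, collapse = ", "))
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Construct an aligned/unaligned sequence set
#'
#' Thin wrapper around a named character vector of nucleotide strings
#' (A/C/G/T, gap `-`, ambiguity codes allowed). When `aligned = TRUE` all
#' sequences must have equal length.
#'
#' @param seqs named character vector of sequences
#' @param aligned logical flag
#' @return object of class `sequence_set`
#' @export
sequence_set <- function(seqs, aligned = TRUE) {
  if (!length(seqs)) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs <- toupper(seqs)
  if (aligned && length(unique(nchar(seqs))) > 1L) {
    lens <- nchar(seqs)
    stop(sprintf("aligned flag set but lengths differ (e.g. '%s'=%d vs '%s'=%d)",
                 names(seqs)[1], lens[1],
                 names(seqs)[which(lens != lens[1])[1]],
                 lens[which(lens != lens[1])[1]]))
  }
  structure(seqs, aligned = aligned, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequences%s\n", length(x),
              if (isTRUE(attr(x, "aligned")))
                sprintf(", aligned length %d", nchar(x[[1]])) else ""))
  invisible(x)
}

#' Construct a tagged symmetric distance matrix
#'
#' @param m symmetric numeric matrix with zero diagonal and dimnames
#' @param kind one of "nei_li", "p_distance", "fst", "km", "other"
#' @return object of class `dist_matrix`
#' @export
dist_matrix <- function(m, kind = c("other", "nei_li", "p_distance", "fst", "km")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("i", seq_len(nrow(m)))
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal not zero")
  if (any(m < -1e-12)) stop("negative distances")
  m[m < 0] <- 0
  diag(m) <- 0
  m <- (m + t(m)) / 2
  if (kind == "p_distance" && any(m > 1 + 1e-12)) stop("p-distance > 1")
  structure(m, kind = kind, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}
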