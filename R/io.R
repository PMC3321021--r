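# Boundary IO: every external representation is read/written here and
# invariants are enforced at the boundary. Parsers never silently coerce.

#' Read a dominant marker matrix from delimited text
#'
#' Two dialects are supported: `"wide"` — a delimited table (TSV or CSV,
#' sniffed from the extension or the first line) with sample ids in the first
#' column, locus ids in the header and cells in \{0, 1, missing token\}; and
#' `"string"` — two columns, sample id and one concatenated 0/1 string per
#' sample. Replicate rows are detected by an id suffix rule (default: ids
#' ending in `_rep<k>` replicate the id without the suffix), or supplied
#' explicitly as a two-column file via `replicate_map`.
#'
#' @param path file path
#' @param dialect "wide" or "string"
#' @param missing_token token standing for a missing call (default "?")
#' @param replicate_suffix regular expression stripped from a sample id to
#'   find the original it replicates; set `NULL` to disable suffix detection
#' @param replicate_map optional path to a headerless two-column file
#'   (replicate id, original id) overriding suffix detection
#' @return a [marker_matrix()]
#' @export
read_aflp_matrix <- function(path, dialect = c("wide", "string"),
                             missing_token = "?",
                             replicate_suffix = "_rep[0-9]+$",
                             replicate_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty marker file: ", path)
  sep <- if (grepl(",", lines[[1]]) && !grepl("\t", lines[[1]])) "," else "\t"
  if (dialect == "wide") {
    header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
    locus_ids <- header[-1]
    rows <- strsplit(lines[-1], sep, fixed = TRUE)
    n_field <- lengths(rows)
    ragged <- which(n_field != length(header))
    if (length(ragged)) {
      stop(sprintf("ragged row %d: %d fields, expected %d",
                   ragged[1] + 1L, n_field[ragged[1]], length(header)))
    }
    ids <- vapply(rows, `[[`, "", 1L)
    cells <- t(vapply(rows, function(r) r[-1], character(length(locus_ids))))
    calls <- parse_calls(cells, ids, locus_ids, missing_token)
  } else {
    rows <- strsplit(lines, sep, fixed = TRUE)
    if (any(lengths(rows) != 2L)) {
      stop("string dialect expects exactly 2 columns (row ",
           which(lengths(rows) != 2L)[1], ")")
    }
    ids <- vapply(rows, `[[`, "", 1L)
    strs <- vapply(rows, `[[`, "", 2L)
    if (length(unique(nchar(strs))) != 1L) {
      stop("ragged row ", which(nchar(strs) != nchar(strs[1]))[1],
           ": genotype strings differ in length")
    }
    locus_ids <- paste0("L", seq_len(nchar(strs[1])))
    cells <- do.call(rbind, strsplit(strs, ""))
    calls <- parse_calls(cells, ids, locus_ids, missing_token)
  }
  replicate_of <- read_replicate_map(replicate_map) %||%
    detect_replicates(rownames(calls), replicate_suffix)
  marker_matrix(calls, replicate_of = replicate_of)
}

parse_calls <- function(cells, ids, locus_ids, missing_token) {
  cells <- trimws(cells)
  out <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = list(ids, locus_ids))
  out[cells == "0"] <- 0L
  out[cells == "1"] <- 1L
  bad <- which(matrix(!(cells %in% c("0", "1", missing_token)), nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid entry '%s' at sample '%s', locus '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], locus_ids[bad[1, 2]]))
  }
  out
}

detect_replicates <- function(ids, suffix) {
  if (is.null(suffix)) return(character(0))
  has <- grepl(suffix, ids)
  orig <- sub(suffix, "", ids[has])
  keep <- orig %in% ids
  stats::setNames(orig[keep], ids[has][keep])
}

read_replicate_map <- function(path) {
  if (is.null(path)) return(NULL)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("replicate map must have exactly two columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a marker matrix as wide TSV
#' @param x a [marker_matrix()]
#' @param path output path
#' @param missing_token token used for missing calls
#' @return `path`, invisibly
#' @export
write_aflp_matrix <- function(x, path, missing_token = "?") {
  m <- unclass(x)
  chr <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- missing_token
  df <- data.frame(sample_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text with a header; must contain `sample_id` and `population_id`;
#' `group_id`, `island`, `latitude`, `longitude` are recognized, any other
#' column is carried along untouched.
#'
#' @param path file path
#' @return a [sample_table()]
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  sample_table(df)
}

#' Write a sample table as TSV
#' @param x a [sample_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file
#' @param aligned enforce equal sequence lengths
#' @return a [sequence_set()]
#' @export
read_fasta <- function(path, aligned = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""), "")
  sequence_set(seqs, aligned = aligned)
}

#' Write a sequence set as FASTA
#' @param x a [sequence_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(c(paste0(">", names(x)[i]), unclass(x)[[i]]), con)
  }
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Bootstrap supports stored in `tree$node.label` are written as internal node
#' labels; re-reading round-trips topology, branch lengths and supports.
#'
#' @param tree an [ape::phylo] object with branch lengths
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length in tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path file path
#' @return an [ape::phylo] object
#' @export
read_tree_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' Write a population graph as GraphML
#' @param g a `pop_graph` (see [build_population_graph()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_popgraph_graphml <- function(g, path) {
  igraph::write_graph(g$graph, path, format = "graphml")
  invisible(path)
}
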