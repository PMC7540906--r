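#' Read and write the package's standard plain-text formats
#'
#' Thin wrappers binding the pipeline's artifacts to standard formats:
#' TSV for tables (readr), FASTA for sequences (ape), newick for trees
#' (ape). Every writer has a matching reader so intermediates round-trip.
#'
#' @param x Object to write (tibble, named character vector of sequences,
#'   or `phylo` tree).
#' @param path File path.
#' @name nematax-io
NULL

#' @rdname nematax-io
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname nematax-io
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_integer(),
    count = readr::col_integer(),
    .default = readr::col_character()
  ))
}

#' @rdname nematax-io
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  dna <- ape::as.DNAbin(lapply(strsplit(tolower(x), ""), identity))
  names(dna) <- names(x)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' @rdname nematax-io
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  vapply(as.character(dna), function(s) toupper(paste(s, collapse = "")),
         character(1))
}

#' @rdname nematax-io
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x, file = path, digits = 6)
  invisible(path)
}

#' @rdname nematax-io
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
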