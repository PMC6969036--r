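#' Read protein sequences from FASTA
#'
#' Thin tidy wrapper over Biostrings: any line wrapping is accepted,
#' sequences are upper-cased, and the first whitespace-delimited token of
#' each description line becomes the id.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  tibble::tibble(id = ids, sequence = unname(toupper(as.character(aa))))
}

#' Write protein sequences to FASTA
#'
#' Sequences are wrapped at 60 columns; the record id is the description
#' line.
#'
#' @param x Tibble (or data frame) with `id` and `sequence` columns, or
#'   anything [as_construct_table()] accepts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  tab <- as_construct_table(x)
  aa <- Biostrings::AAStringSet(tab$sequence)
  names(aa) <- tab$id
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
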