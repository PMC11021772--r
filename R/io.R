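# Plain-text input/output: FASTA proteomes via Biostrings, TSV tables for
# seeds, libraries and annotations.

#' Read a proteome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of protein sequences (names truncated at
#'   the first whitespace, as accessions).
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a proteome (or peptide set) as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read a seed phosphopeptide table
#'
#' TSV with header `accession peptide site_index residue origin`; the
#' annotated residue must match the peptide at `site_index`.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_seed_table <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  merge_seed_pools(d)  # reuses the column/residue validation
}

#' Write / read the peptide library TSV
#'
#' Header: `library_id accession window site_offset source`.
#'
#' @param library library data frame.
#' @param path TSV path.
#' @name library_io
#' @export
write_library_tsv <- function(library, path) {
  cols <- c("library_id", "accession", "window", "site_offset", "source")
  utils::write.table(library[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname library_io
#' @export
read_library_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("library_id", "accession", "window", "site_offset", "source")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("library TSV missing column(s): ", paste(missing, collapse = ", "))
  assert_peptides(d$window, "window")
  d
}
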