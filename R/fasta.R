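#' Read a proteome FASTA
#'
#' Reads protein sequences with [Biostrings::readAAStringSet()] (handles
#' 60/70-column wrapped dialects) and returns a named list of protein
#' records. The accession is the first whitespace-delimited token of each
#' header. Sequences are validated against the 20-AA alphabet plus `"X"`.
#'
#' @param path FASTA file path.
#' @return Named list of records, each `list(accession, sequence, length)`.
#' @export
read_proteome <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  acc <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) stop("duplicate accessions in FASTA: ",
                               paste(unique(acc[duplicated(acc)]), collapse = ", "))
  prot <- lapply(seq_along(seqs), function(i) {
    validate_sequence(seqs[[i]])
    protein_record(acc[[i]], seqs[[i]])
  })
  stats::setNames(prot, acc)
}

#' Construct a protein record
#'
#' @param accession Accession string.
#' @param sequence Sequence over the 20-AA alphabet plus `"X"`.
#' @return `list(accession, sequence, length)`.
#' @export
protein_record <- function(accession, sequence) {
  stopifnot(nchar(sequence) > 0L)
  list(accession = accession, sequence = sequence, length = nchar(sequence))
}

#' Write protein records to FASTA
#'
#' @param proteome Named list of protein records.
#' @param path Output path.
#' @export
write_proteome <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteome, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(proteome, `[[`, character(1), "accession")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

# substring helper on a record, 1-based inclusive
.subseq <- function(p, start, end) substr(p$sequence, start, end)
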