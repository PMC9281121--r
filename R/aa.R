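#' @useDynLib degronet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed order used throughout the
#' package for encoding matrices and PSSM rows. `"X"` is the only
#' non-standard symbol accepted in sequences; it marks window padding and
#' unknown residues and always encodes to an all-zero column.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# fast residue -> index lookup (X and anything else -> NA)
.aa_index <- local({
  idx <- rep(NA_integer_, 127L)
  idx[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_len(20L)
  idx
})

#' Convert a sequence string to integer codes
#'
#' Maps each residue to its index in [AA_ALPHABET] (1..20); `"X"` maps to
#' `NA`. Any other symbol is an error: silent coercion of unexpected
#' letters (B, Z, U, ...) would corrupt encodings downstream, so loading
#' fails fast instead.
#'
#' @param sequence Single string over the 20-AA alphabet plus `"X"`.
#' @return Integer vector with `NA` at `"X"` positions.
#' @export
aa_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ints <- utf8ToInt(sequence)
  if (length(ints) == 0L) stop("empty sequence")
  codes <- .aa_index[ints]
  bad <- is.na(codes) & ints != utf8ToInt("X")
  if (any(bad)) {
    stop("illegal symbols in sequence: ",
         paste(unique(intToUtf8(ints[bad], multiple = TRUE)), collapse = ", "))
  }
  codes
}

#' Validate a protein sequence
#'
#' @param sequence Candidate sequence string.
#' @return The sequence, invisibly; errors on illegal symbols or emptiness.
#' @export
validate_sequence <- function(sequence) {
  aa_codes(sequence)
  invisible(sequence)
}

#' Amino-acid background frequencies
#'
#' Reads a two-column TSV (`aa`, `freq`) into a named frequency vector in
#' [AA_ALPHABET] order, renormalised to sum to one. With no argument the
#' bundled human-proteome background table is used, so synthetic and real
#' runs share a reference.
#'
#' @param path TSV path; default the bundled human background.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
load_background <- function(path = system.file("extdata", "human_aa_background.tsv",
                                               package = "degronet")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "freq") %in% names(tab))) {
    stop("background table needs columns 'aa' and 'freq'")
  }
  f <- stats::setNames(tab$freq, tab$aa)[AA_ALPHABET]
  if (anyNA(f) || any(f <= 0)) stop("background must cover all 20 AAs with positive frequency")
  f / sum(f)
}

#' Empirical background from a proteome
#'
#' Counts residue frequencies over a list of protein records, ignoring
#' `"X"`. Used to build a [load_background]-compatible vector from the
#' proteome actually being scanned.
#'
#' @param proteome List of protein records (see [read_proteome]).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
proteome_background <- function(proteome) {
  counts <- integer(20L)
  for (p in proteome) {
    codes <- aa_codes(p$sequence)
    tab <- tabulate(codes[!is.na(codes)], nbins = 20L)
    counts <- counts + tab
  }
  if (sum(counts) == 0L) stop("proteome contains no standard residues")
  stats::setNames(counts / sum(counts), AA_ALPHABET)
}

# Charge classes for property-change flags: K/R/H positive, D/E negative,
# everything else neutral.
.charge_class <- function(aa) {
  ifelse(aa %in% c("K", "R", "H"), "positive",
         ifelse(aa %in% c("D", "E"), "negative", "neutral"))
}

# Kyte-Doolittle hydropathy; the sign convention (positive = hydrophobic)
# defines the two hydrophobicity classes.
.kyte_doolittle <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

.hydro_class <- function(aa) {
  ifelse(.kyte_doolittle[aa] > 0, "hydrophobic", "hydrophilic")
}
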