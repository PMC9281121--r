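#' Build a PSSM from aligned cores
#'
#' Position-specific score matrix over the 20 standard amino acids:
#' `S[i, a] = log2(((C[i, a] + 1) / (N + 20)) / F[a])` with `C` the
#' per-position residue counts over the `N` equal-length alignment cores
#' and `F` the background frequencies. The +1 pseudocount per cell makes
#' every column satisfy `sum_a F[a] * 2^S[i, a] == 1` exactly.
#'
#' @param cores Character vector of equal-length cores (N >= 1), standard
#'   alphabet only.
#' @param bg Background frequencies (default the bundled human table).
#' @param e3 Optional E3 accession carried as provenance.
#' @return Object of class `pssm`: `e3`, `m`, `scores` (m x 20 matrix,
#'   columns in [AA_ALPHABET] order), `cutoff` (`NA` until calibrated),
#'   `n_cores`, `background`.
#' @export
build_pssm <- function(cores, bg = load_background(), e3 = NULL) {
  stopifnot(length(cores) >= 1L)
  m <- nchar(cores[1])
  if (any(nchar(cores) != m)) stop("alignment cores must share one length")
  codes <- t(vapply(cores, .window_codes, integer(m)))
  if (any(codes == 0L)) stop("cores must not contain 'X'")
  N <- length(cores)
  counts <- matrix(0L, m, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(m)) {
    counts[i, ] <- tabulate(codes[, i], nbins = 20L)
  }
  scores <- log2((counts + 1) / (N + 20)) -
    matrix(log2(bg), m, 20L, byrow = TRUE, dimnames = list(NULL, AA_ALPHABET))
  structure(list(e3 = e3, m = m, scores = scores, cutoff = NA_real_,
                 n_cores = N, background = bg),
            class = "pssm")
}

#' Match score of a peptide against a PSSM
#'
#' An equal-length peptide scores the sum of its per-position entries; a
#' longer peptide is slid across and the maximum window sum is returned;
#' a shorter peptide has no score (`NA`, not an error). A window
#' containing `"X"` or any non-standard symbol is skipped rather than
#' imputed; if every window is skipped the score is `NA`.
#'
#' @param pssm A `pssm`.
#' @param peptide Peptide string.
#' @return Numeric score, or `NA` when undefined.
#' @export
match_score <- function(pssm, peptide) {
  codes <- .window_codes(peptide)
  m <- pssm$m
  if (length(codes) < m) return(NA_real_)
  n_off <- length(codes) - m + 1L
  best <- NA_real_
  for (o in seq_len(n_off)) {
    win <- codes[o:(o + m - 1L)]
    if (any(win == 0L)) next
    s <- sum(pssm$scores[cbind(seq_len(m), win)])
    if (is.na(best) || s > best) best <- s
  }
  best
}

#' Reverse a PSSM
#'
#' Reverses the position order; the amino-acid dimension is untouched.
#' Scoring a peptide with the reversed PSSM equals scoring the reversed
#' peptide with the original, which destroys the motif's directional
#' signal while preserving its composition — the null used for cutoff
#' calibration.
#'
#' @param pssm A `pssm`.
#' @return The reversed `pssm`.
#' @export
reverse_pssm <- function(pssm) {
  pssm$scores <- pssm$scores[rev(seq_len(pssm$m)), , drop = FALSE]
  pssm
}

# concatenated integer codes + global legal window starts for a proteome
.proteome_pool <- function(proteome, m) {
  codes <- lapply(proteome, function(p) .window_codes(p$sequence))
  lens <- lengths(codes)
  offs <- cumsum(c(0L, utils::head(lens, -1L)))
  starts <- unlist(lapply(seq_along(codes), function(i) {
    if (lens[i] < m) return(integer(0))
    offs[i] + seq_len(lens[i] - m + 1L)
  }), use.names = FALSE)
  list(flat = unlist(codes, use.names = FALSE), starts = starts)
}

#' Calibrate a PSSM cutoff from random proteome peptides
#'
#' Samples `n_samples` peptides of the PSSM's length uniformly over all
#' legal (protein, offset) windows of the proteome, scores them with the
#' reversed PSSM, and returns the score at descending rank
#' `floor(n_samples * q)` (at least 1). Windows containing non-standard
#' symbols are excluded and redrawn. Deterministic under `seed`.
#'
#' @param pssm A `pssm`.
#' @param proteome Named protein-record list with at least one protein of
#'   length >= the PSSM length.
#' @param n_samples Number of calibration peptides (default 1e6).
#' @param q Upper tail fraction defining the cutoff (default 1/2000).
#' @param seed Integer seed.
#' @return The cutoff score; the calibration scores are attached as
#'   attribute `"scores"`.
#' @export
calibrate_cutoff <- function(pssm, proteome, n_samples = 1e6, q = 1 / 2000,
                             seed = 1L) {
  m <- pssm$m
  pool <- .proteome_pool(proteome, m)
  if (!length(pool$starts)) stop("proteome has no protein of length >= ", m)
  rev_s <- reverse_pssm(pssm)$scores
  n_samples <- as.integer(n_samples)

  scores <- withr::with_seed(seed, {
    out <- numeric(0)
    for (round in seq_len(100L)) {
      need <- n_samples - length(out)
      if (need <= 0L) break
      s <- pool$starts[sample.int(length(pool$starts), need, replace = TRUE)]
      sc <- numeric(length(s))
      ok <- rep(TRUE, length(s))
      for (i in seq_len(m)) {
        ci <- pool$flat[s + i - 1L]
        ok <- ok & ci > 0L
        sc <- sc + rev_s[cbind(i, pmax(ci, 1L))]
      }
      out <- c(out, sc[ok])
    }
    if (length(out) < n_samples) stop("could not draw enough standard-alphabet windows")
    out[seq_len(n_samples)]
  })
  sorted <- sort(scores, decreasing = TRUE)
  cutoff <- sorted[max(1L, floor(n_samples * q))]
  attr(cutoff, "scores") <- scores
  cutoff
}

#' Build and select the motif PSSM for one E3
#'
#' For each candidate core length, aligns the E3's degron peptides
#' (expanded degrons plus 3 flanking residues each side) with the Gibbs
#' sampler (single motif cluster plus trash), builds a PSSM from the
#' alignment cores, and calibrates its cutoff on random proteome
#' peptides. The candidate recovering the largest fraction of the E3's
#' known substrates — substrates with at least one peptide scoring at or
#' above the cutoff — is selected; recall ties break toward the shorter,
#' more permissive motif.
#'
#' @param e3 E3 accession.
#' @param substrate_peptides Named list: substrate accession -> character
#'   vector of flanked degron peptides on that substrate.
#' @param proteome Named protein-record list for cutoff calibration.
#' @param lengths Candidate core lengths (default 5:8).
#' @param trash_threshold Gibbs trash threshold in bits (default 4).
#' @param n_samples,q Calibration parameters (see [calibrate_cutoff]).
#' @param iterations,seed Gibbs sampler controls.
#' @param bg Background frequencies.
#' @return The selected calibrated `pssm`, with `recall` and the
#'   per-length recall table in the `"selection"` attribute.
#' @export
build_e3_motif <- function(e3, substrate_peptides, proteome, lengths = 5:8,
                           trash_threshold = 4, n_samples = 1e5, q = 1 / 2000,
                           iterations = 60L, seed = 1L, bg = load_background()) {
  peptides <- unlist(substrate_peptides, use.names = FALSE)
  if (!length(peptides)) stop("no degron peptides supplied for ", e3)
  candidates <- list()
  recalls <- numeric(0)
  for (m in lengths) {
    usable <- peptides[nchar(peptides) >= m]
    if (!length(usable)) next
    sol <- cluster_cores(usable, K = 1L, m = m, trash_threshold = trash_threshold,
                         iterations = iterations, seed = seed, bg = bg)
    if (all(is.na(sol$assignments))) next  # every peptide trashed at this length
    p <- build_pssm(alignment_cores(sol, 1L), bg = bg, e3 = e3)
    cutoff <- calibrate_cutoff(p, proteome, n_samples = n_samples, q = q, seed = seed)
    p$cutoff <- as.numeric(cutoff)
    hit <- vapply(substrate_peptides, function(peps) {
      sc <- vapply(peps, function(pep) match_score(p, pep), numeric(1))
      any(!is.na(sc) & sc >= p$cutoff)
    }, logical(1))
    candidates[[as.character(m)]] <- p
    recalls[as.character(m)] <- mean(hit)
  }
  if (!length(candidates)) stop("empty alignment: all peptides trashed for ", e3)
  best <- names(recalls)[which.max(recalls)]  # first max = shortest length
  out <- candidates[[best]]
  out$recall <- unname(recalls[best])
  attr(out, "selection") <- data.frame(m = as.integer(names(recalls)),
                                       recall = unname(recalls))
  out
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM%s: length %d, %d alignment cores, cutoff %s\n",
              if (!is.null(x$e3)) paste0(" [", x$e3, "]") else "",
              x$m, x$n_cores,
              if (is.na(x$cutoff)) "uncalibrated" else sprintf("%.3f", x$cutoff)))
  consensus <- AA_ALPHABET[apply(x$scores, 1, which.max)]
  cat("  consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' Serialize a PSSM to JSON
#'
#' The score grid is written 20 x m in fixed [AA_ALPHABET] row order.
#'
#' @param pssm A `pssm`.
#' @param path Output path.
#' @export
write_pssm <- function(pssm, path) {
  obj <- list(e3 = pssm$e3, m = pssm$m,
              aa_order = paste(AA_ALPHABET, collapse = ""),
              scores = unname(t(pssm$scores)),  # 20 x m
              cutoff = pssm$cutoff,
              provenance = list(n_cores = pssm$n_cores,
                                background = unname(pssm$background)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PSSM written by [write_pssm]
#'
#' @param path JSON path.
#' @return A `pssm`.
#' @export
read_pssm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- t(matrix(as.numeric(obj$scores), nrow = 20L))
  colnames(scores) <- AA_ALPHABET
  structure(list(e3 = obj$e3, m = as.integer(obj$m), scores = scores,
                 cutoff = as.numeric(obj$cutoff),
                 n_cores = as.integer(obj$provenance$n_cores),
                 background = stats::setNames(as.numeric(obj$provenance$background),
                                              AA_ALPHABET)),
            class = "pssm")
}

#' Export a PSSM in MEME minimal motif format
#'
#' Converts log-odds scores back to letter probabilities
#' (`p = F * 2^S`, exact under the build formula) and writes a minimal
#' MEME text motif.
#'
#' @param pssm A `pssm`.
#' @param path Output path.
#' @export
write_meme_motif <- function(pssm, path) {
  probs <- sweep(2^pssm$scores, 2, pssm$background, `*`)
  lines <- c("MEME version 4", "",
             paste("ALPHABET=", paste(AA_ALPHABET, collapse = "")), "",
             sprintf("MOTIF %s", if (is.null(pssm$e3)) "motif" else pssm$e3),
             sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d",
                     pssm$m, pssm$n_cores),
             apply(probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
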