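#' Load an E3-substrate interaction table
#'
#' TSV with columns `e3`, `substrate`, `evidence` (`known` or
#' `high_throughput`). Duplicate (e3, substrate) pairs collapse to one
#' record, keeping the `known` label when the pair carries both evidence
#' classes. Summary counts are attached as the `"summary"` attribute.
#'
#' @param path TSV path.
#' @return `data.frame(e3, substrate, evidence)` with attribute
#'   `"summary"` = `list(edges, e3s, substrates)`.
#' @export
load_esi_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("e3", "substrate", "evidence")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("ESI table missing columns: ",
                            paste(missing, collapse = ", "))
  bad <- setdiff(unique(tab$evidence), c("known", "high_throughput"))
  if (length(bad)) stop("unknown evidence labels: ", paste(bad, collapse = ", "))
  # known outranks high_throughput on duplicated pairs
  tab <- tab[order(tab$evidence != "known"), , drop = FALSE]
  tab <- tab[!duplicated(tab[c("e3", "substrate")]), required, drop = FALSE]
  tab <- tab[order(tab$e3, tab$substrate), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "summary") <- list(edges = nrow(tab),
                               e3s = length(unique(tab$e3)),
                               substrates = length(unique(tab$substrate)))
  tab
}

#' E3s eligible for motif calculation
#'
#' E3s with at least `min_substrates` distinct substrates in the ESI
#' dataset, counting both evidence classes.
#'
#' @param esis ESI `data.frame`.
#' @param min_substrates Eligibility threshold (default 10).
#' @return Character vector of E3 accessions.
#' @export
eligible_e3s <- function(esis, min_substrates = 10L) {
  counts <- tapply(esis$substrate, esis$e3, function(s) length(unique(s)))
  sort(names(counts)[counts >= min_substrates])
}

#' Substrates used for motif building of one E3
#'
#' Known substrates from curated databases are more reliable than
#' high-throughput ones: an E3 with at least `min_known` known
#' substrates uses only those; otherwise both evidence classes enter
#' motif building.
#'
#' @param e3 E3 accession.
#' @param esis ESI `data.frame`.
#' @param min_known Known-substrate threshold (default 10).
#' @return Character vector of substrate accessions.
#' @export
substrate_set_for_motif <- function(e3, esis, min_known = 10L) {
  mine <- esis[esis$e3 == e3, , drop = FALSE]
  known <- unique(mine$substrate[mine$evidence == "known"])
  if (length(known) >= min_known) known else unique(mine$substrate)
}

#' Flanked degron peptides of one substrate
#'
#' Each called degron extended by `flank` residues on both sides,
#' clipped at the protein termini — the unit entering motif calculation
#' and matching.
#'
#' @param calls Degron-call `data.frame`.
#' @param p Protein record.
#' @param flank Residues added each side (default 3).
#' @return Character vector of peptides (possibly empty).
#' @export
flanked_degron_peptides <- function(calls, p, flank = 3L) {
  mine <- calls[calls$protein_accession == p$accession, , drop = FALSE]
  if (!nrow(mine)) return(character(0))
  vapply(seq_len(nrow(mine)), function(i)
    .subseq(p, max(1L, mine$start[i] - flank), min(p$length, mine$end[i] + flank)),
    character(1))
}

#' Binding score of an E3 for one substrate
#'
#' Scores every called degron of the substrate (with flanks) against the
#' E3's motif PSSM and returns the maximum — the degron the E3 most
#' plausibly binds. Undefined (`NULL`) when the substrate has no
#' scorable degron.
#'
#' @param pssm Calibrated E3 `pssm`.
#' @param calls Degron-call `data.frame`.
#' @param p Substrate protein record.
#' @param flank Flank width for peptide extraction (default 3).
#' @return `list(score, best_degron)` or `NULL`.
#' @export
binding_score <- function(pssm, calls, p, flank = 3L) {
  mine <- calls[calls$protein_accession == p$accession, , drop = FALSE]
  if (!nrow(mine)) return(NULL)
  peps <- flanked_degron_peptides(mine, p, flank)
  sc <- vapply(peps, function(pep) match_score(pssm, pep), numeric(1))
  if (all(is.na(sc))) return(NULL)
  best <- which.max(sc)
  list(score = sc[[best]], best_degron = mine[best, , drop = FALSE])
}

#' Z-normalise binding scores within one E3
#'
#' Centres and scales a score vector to mean 0 and population (n
#' denominator) standard deviation 1. Undefined for fewer than 2 scores
#' or zero spread.
#'
#' @param scores Numeric vector of one E3's maximal matching scores.
#' @param sample_sd Use the n-1 denominator instead (default `FALSE`).
#' @return Z-scores, or all-`NA` with a warning when the spread is zero.
#' @export
zscore_per_e3 <- function(scores, sample_sd = FALSE) {
  if (length(scores) < 2L) stop("need at least 2 scores to normalise")
  mu <- mean(scores)
  s <- if (sample_sd) stats::sd(scores) else sqrt(mean((scores - mu)^2))
  if (s == 0) {
    warning("zero spread: z-scores undefined")
    return(rep(NA_real_, length(scores)))
  }
  (scores - mu) / s
}

#' Keep motifs that recover enough collected substrates
#'
#' A motif passes when the fraction of its E3's collected substrates
#' whose maximal degron score reaches the motif cutoff is at least
#' `recall_threshold`.
#'
#' @param pssms Named list of calibrated `pssm`s (names = E3 accessions).
#' @param esis ESI `data.frame`.
#' @param calls Degron-call `data.frame` on the substrates.
#' @param proteome Named protein-record list.
#' @param recall_threshold Minimum substrate recall (default 0.4).
#' @param flank Flank width (default 3).
#' @return The subset of `pssms` that pass; per-E3 recall in the
#'   `"recall"` attribute.
#' @export
qc_motifs <- function(pssms, esis, calls, proteome, recall_threshold = 0.4,
                      flank = 3L) {
  recall <- vapply(names(pssms), function(e3) {
    subs <- unique(esis$substrate[esis$e3 == e3])
    if (!length(subs)) return(0)
    hit <- vapply(subs, function(s) {
      p <- proteome[[s]]
      if (is.null(p)) return(FALSE)
      bs <- binding_score(pssms[[e3]], calls, p, flank)
      !is.null(bs) && bs$score >= pssms[[e3]]$cutoff
    }, logical(1))
    mean(hit)
  }, numeric(1))
  kept <- pssms[recall >= recall_threshold]
  attr(kept, "recall") <- recall
  kept
}

#' Build the degradation regulatory network
#'
#' For every kept E3 motif and every protein with at least one scorable
#' called degron, computes the maximal degron-motif score and emits an
#' edge when it reaches the E3's cutoff. Each edge carries its mediating
#' degron, raw score, and within-E3 z-score (z-normalised over all
#' scored proteins of that E3, before cutoff filtering).
#'
#' @param pssms Named list of calibrated, QC-passed `pssm`s.
#' @param calls Degron-call `data.frame` across the proteome.
#' @param proteome Named protein-record list.
#' @param flank Flank width (default 3).
#' @return `data.frame(e3, substrate, degron_start, degron_end, score,
#'   zscore)` sorted by (e3, score descending); only cutoff-passing
#'   edges.
#' @export
build_network <- function(pssms, calls, proteome, flank = 3L) {
  rows <- list()
  for (e3 in names(pssms)) {
    pssm <- pssms[[e3]]
    scored <- list()
    for (acc in unique(calls$protein_accession)) {
      p <- proteome[[acc]]
      if (is.null(p)) next
      bs <- binding_score(pssm, calls, p, flank)
      if (is.null(bs)) next
      scored[[acc]] <- bs
    }
    if (!length(scored)) next
    raw <- vapply(scored, `[[`, numeric(1), "score")
    z <- if (length(raw) >= 2L && stats::sd(raw) > 0) {
      zscore_per_e3(raw)
    } else rep(NA_real_, length(raw))
    pass <- raw >= pssm$cutoff
    if (!any(pass)) next
    idx <- which(pass)
    rows[[e3]] <- data.frame(
      e3 = e3,
      substrate = names(scored)[idx],
      degron_start = vapply(scored[idx], function(b) b$best_degron$start, integer(1)),
      degron_end = vapply(scored[idx], function(b) b$best_degron$end, integer(1)),
      score = unname(raw[idx]),
      zscore = unname(z[idx]))
  }
  if (!length(rows)) {
    return(data.frame(e3 = character(), substrate = character(),
                      degron_start = integer(), degron_end = integer(),
                      score = numeric(), zscore = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$e3, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
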