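#' Load a protein-level missense mutation table
#'
#' TSV columns: `protein_accession`, `position`, `ref_aa`, `alt_aa`,
#' `sample_id`, `cancer_type`. When a proteome is supplied, the stated
#' reference residue is checked against the sequence and mismatching
#' rows are rejected (listed in the `"rejected"` attribute); synonymous
#' rows (`ref == alt`) are always rejected.
#'
#' @param path TSV path.
#' @param proteome Optional named protein-record list for validation.
#' @return Mutation `data.frame`.
#' @export
load_mutation_table <- function(path, proteome = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_accession", "position", "ref_aa", "alt_aa",
                "sample_id", "cancer_type")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("mutation table missing columns: ",
                            paste(missing, collapse = ", "))
  tab$position <- as.integer(tab$position)
  ok <- tab$ref_aa != tab$alt_aa
  if (!is.null(proteome)) {
    for (i in which(ok)) {
      p <- proteome[[tab$protein_accession[i]]]
      ok[i] <- !is.null(p) && tab$position[i] >= 1L && tab$position[i] <= p$length &&
        .subseq(p, tab$position[i], tab$position[i]) == tab$ref_aa[i]
    }
  }
  out <- tab[ok, required, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- tab[!ok, required, drop = FALSE]
  out
}

# merge sorted 1-based inclusive intervals (matrix with columns start, end)
.merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2] + 1L) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Index degron and degron-related regions per protein
#'
#' A degron-related region is a degron interval expanded by `flank`
#' residues on both sides, clipped to the protein, with overlapping
#' expansions merged. The index drives mutation region classification
#' and enrichment testing.
#'
#' @param calls Degron-call `data.frame`.
#' @param proteome Named protein-record list (for terminal clipping).
#' @param flank Flank width in residues (default 10).
#' @return Named list per protein: `list(degrons, related)`, each an
#'   integer matrix of merged disjoint intervals.
#' @export
build_region_index <- function(calls, proteome, flank = 10L) {
  idx <- list()
  for (acc in unique(calls$protein_accession)) {
    p <- proteome[[acc]]
    if (is.null(p)) stop("no sequence for ", acc)
    mine <- calls[calls$protein_accession == acc, , drop = FALSE]
    deg <- cbind(start = mine$start, end = mine$end)
    rel <- cbind(start = pmax(1L, mine$start - flank),
                 end = pmin(p$length, mine$end + flank))
    idx[[acc]] <- list(degrons = .merge_intervals(deg),
                       related = .merge_intervals(rel))
  }
  idx
}

.in_intervals <- function(pos, iv) {
  if (is.null(iv) || !nrow(iv)) return(FALSE)
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

#' Classify a mutation position relative to degrons
#'
#' `in_degron` inside a degron interval; `near_degron` inside a
#' degron-related region but outside every degron; `other` elsewhere.
#' The three classes partition all positions.
#'
#' @param accession Protein accession.
#' @param position 1-based residue position.
#' @param idx Region index from [build_region_index].
#' @return One of `"in_degron"`, `"near_degron"`, `"other"`.
#' @export
classify_mutation <- function(accession, position, idx) {
  reg <- idx[[accession]]
  if (is.null(reg)) return("other")
  if (.in_intervals(position, reg$degrons)) return("in_degron")
  if (.in_intervals(position, reg$related)) return("near_degron")
  "other"
}

#' Keep recurrent mutations
#'
#' Retains (protein, position, alt) changes observed in at least
#' `min_samples` distinct tumour samples.
#'
#' @param mutations Mutation `data.frame`.
#' @param min_samples Recurrence threshold (default 2).
#' @return Subset of `mutations`, with a `recurrence` column added.
#' @export
recurrent_filter <- function(mutations, min_samples = 2L) {
  key <- paste(mutations$protein_accession, mutations$position,
               mutations$alt_aa, sep = "\r")
  counts <- tapply(mutations$sample_id, key, function(s) length(unique(s)))
  mutations$recurrence <- as.integer(counts[key])
  out <- mutations[mutations$recurrence >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degron-region mutation enrichment on one protein
#'
#' One-sided Fisher's exact (hypergeometric) test of whether uniquely
#' mutated residues concentrate in the degron zone: the 2x2 table
#' crosses mutated vs non-mutated residues with in-zone vs out-of-zone,
#' and the alternative is enrichment (greater). By default the zone is
#' the degron intervals themselves; set `zone = "related"` to test the
#' flanked regions.
#'
#' @param mutations Mutation `data.frame` for one protein (or more; rows
#'   are filtered to `accession`).
#' @param accession Protein accession.
#' @param idx Region index from [build_region_index].
#' @param protein_length Protein length in residues.
#' @param zone `"degron"` or `"related"`.
#' @return `list(p_value, k, m, n_mut, L)`: in-zone mutated residues,
#'   zone size, mutated residues, protein length.
#' @export
degron_enrichment <- function(mutations, accession, idx, protein_length,
                              zone = c("degron", "related")) {
  zone <- match.arg(zone)
  reg <- idx[[accession]]
  iv <- if (is.null(reg)) cbind(start = integer(0), end = integer(0))
        else if (zone == "degron") reg$degrons else reg$related
  m_zone <- if (nrow(iv)) sum(iv[, 2] - iv[, 1] + 1L) else 0L

  pos <- unique(mutations$position[mutations$protein_accession == accession])
  n_mut <- length(pos)
  k <- sum(vapply(pos, .in_intervals, logical(1), iv = iv))

  # P(X >= k), X ~ Hypergeometric(m_zone, L - m_zone, n_mut)
  p <- if (n_mut == 0L || m_zone == 0L || m_zone >= protein_length) {
    1
  } else {
    stats::phyper(k - 1L, m_zone, protein_length - m_zone, n_mut,
                  lower.tail = FALSE)
  }
  list(p_value = p, k = k, m = m_zone, n_mut = n_mut, L = protein_length)
}

#' Per-protein enrichment report across cancer types
#'
#' Runs [degron_enrichment] for every (protein, cancer type) group and
#' flags the rows the display rule keeps: more than one mutated residue
#' and p below `p_show`. Benjamini-Hochberg q-values are added as a
#' convenience column (an extension beyond the plain p-value rule).
#'
#' @param mutations Mutation `data.frame`.
#' @param idx Region index.
#' @param proteome Named protein-record list.
#' @param zone Passed to [degron_enrichment].
#' @param p_show Display threshold (default 0.01).
#' @return `data.frame(protein_accession, cancer_type, n_mut, k, m, L,
#'   p_value, q_value, shown)`.
#' @export
enrichment_report <- function(mutations, idx, proteome,
                              zone = "degron", p_show = 0.01) {
  groups <- unique(mutations[c("protein_accession", "cancer_type")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    acc <- groups$protein_accession[i]
    ct <- groups$cancer_type[i]
    sub <- mutations[mutations$protein_accession == acc &
                       mutations$cancer_type == ct, , drop = FALSE]
    p <- proteome[[acc]]
    if (is.null(p)) return(NULL)
    e <- degron_enrichment(sub, acc, idx, p$length, zone)
    data.frame(protein_accession = acc, cancer_type = ct, n_mut = e$n_mut,
               k = e$k, m = e$m, L = e$L, p_value = e$p_value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(protein_accession = character(), cancer_type = character(),
                      n_mut = integer(), k = integer(), m = integer(),
                      L = integer(), p_value = numeric(), q_value = numeric(),
                      shown = logical()))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$shown <- out$n_mut > 1L & out$p_value < p_show
  rownames(out) <- NULL
  out
}

#' Top-percentile residue threshold for a feature track
#'
#' Residues scoring in the top `top` fraction of the supplied track
#' universe define feature regions (MoRF, predicted binding); the
#' threshold is the (1 - top) quantile of all supplied scores.
#'
#' @param track_values Numeric vector of all per-residue scores in the
#'   reference universe.
#' @param top Upper fraction (default 0.05).
#' @return Numeric threshold.
#' @export
track_threshold <- function(track_values, top = 0.05) {
  stats::quantile(track_values, probs = 1 - top, names = FALSE, type = 7)
}

#' Property-change flags for a degron mutation
#'
#' Flags how a missense change could disable a degron: charge-class
#' change (K/R/H positive, D/E negative, others neutral), hydrophobicity
#' class change (sign of the Kyte-Doolittle scale), loss of an annotated
#' phosphosite (ref in S/T/Y at an annotated site, alt not
#' phosphorylatable), overlap of the degron with top-percentile MoRF or
#' predicted-binding residues, and loss of a flanking lysine within the
#' degron-related region.
#'
#' @param mutation One-row mutation record (list or `data.frame` row).
#' @param accession Protein accession.
#' @param idx Region index from [build_region_index].
#' @param phosphosites Optional integer positions of annotated
#'   phosphosites on this protein.
#' @param morf_positions,binding_positions Optional integer positions in
#'   the top percentile of the respective feature tracks.
#' @return Character vector of flags (possibly empty).
#' @export
property_change_flags <- function(mutation, accession, idx,
                                  phosphosites = integer(0),
                                  morf_positions = integer(0),
                                  binding_positions = integer(0)) {
  reg <- idx[[accession]]
  pos <- mutation$position
  ref <- mutation$ref_aa
  alt <- mutation$alt_aa
  cls <- classify_mutation(accession, pos, idx)
  flags <- character(0)

  if (cls == "in_degron") {
    if (.charge_class(ref) != .charge_class(alt)) flags <- c(flags, "charge_change")
    if (.hydro_class(ref) != .hydro_class(alt)) flags <- c(flags, "hydrophobicity_change")
    if (ref %in% c("S", "T", "Y") && pos %in% phosphosites &&
        !(alt %in% c("S", "T", "Y"))) flags <- c(flags, "phospho_loss")
    # does the host degron intersect top-percentile feature residues?
    if (!is.null(reg)) {
      host <- reg$degrons[reg$degrons[, 1] <= pos & reg$degrons[, 2] >= pos, ,
                          drop = FALSE]
      if (nrow(host)) {
        span <- host[1, 1]:host[1, 2]
        if (length(intersect(span, morf_positions))) flags <- c(flags, "morf_overlap")
        if (length(intersect(span, binding_positions))) flags <- c(flags, "binding_overlap")
      }
    }
  }
  if (ref == "K" && alt != "K" && cls %in% c("in_degron", "near_degron")) {
    flags <- c(flags, "flanking_K_loss")
  }
  flags
}

#' Annotate a mutation table against degron calls
#'
#' Adds the region class, recurrence count, and property-change flags to
#' every mutation.
#'
#' @param mutations Mutation `data.frame`.
#' @param idx Region index.
#' @param phosphosites,morf_positions,binding_positions Optional named
#'   lists (per protein accession) of annotated positions.
#' @return The mutation `data.frame` with `region_class`, `recurrence`,
#'   and `flags` (comma-separated) columns.
#' @export
annotate_mutations <- function(mutations, idx, phosphosites = list(),
                               morf_positions = list(),
                               binding_positions = list()) {
  key <- paste(mutations$protein_accession, mutations$position,
               mutations$alt_aa, sep = "\r")
  counts <- tapply(mutations$sample_id, key, function(s) length(unique(s)))
  mutations$recurrence <- as.integer(counts[key])
  mutations$region_class <- vapply(seq_len(nrow(mutations)), function(i)
    classify_mutation(mutations$protein_accession[i], mutations$position[i], idx),
    character(1))
  mutations$flags <- vapply(seq_len(nrow(mutations)), function(i) {
    acc <- mutations$protein_accession[i]
    paste(property_change_flags(mutations[i, ], acc, idx,
                                phosphosites[[acc]] %||% integer(0),
                                morf_positions[[acc]] %||% integer(0),
                                binding_positions[[acc]] %||% integer(0)),
          collapse = ",")
  }, character(1))
  mutations
}

`%||%` <- function(a, b) if (is.null(a)) b else a
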