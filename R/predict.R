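#' Cluster-held-out train/test splits
#'
#' Builds one split per cluster: split i trains on the degrons of every
#' other cluster and tests on cluster i, so test degrons are dissimilar
#' in sequence to training degrons.
#'
#' @param degrons Degron `data.frame`.
#' @param assignment Integer cluster id per degron row (no trash here:
#'   assign trash peptides to a cluster or drop them first).
#' @param K Number of clusters (default `max(assignment)`); every id in
#'   `1..K` must be nonempty.
#' @return List of splits, each `list(cluster_id, train, test)`.
#' @export
make_cluster_splits <- function(degrons, assignment, K = max(assignment)) {
  assignment <- as.integer(assignment)
  stopifnot(nrow(degrons) == length(assignment))
  ids <- seq_len(K)
  sizes <- tabulate(assignment, K)
  if (any(sizes == 0)) stop("empty cluster in assignment")
  lapply(ids, function(k) {
    list(cluster_id = k,
         train = degrons[assignment != k, , drop = FALSE],
         test = degrons[assignment == k, , drop = FALSE])
  })
}

#' Evenly segment a protein for prediction
#'
#' Proteins of at most `max_len` residues are scored whole; longer ones
#' are split into `ceiling(L / max_len)` contiguous parts whose lengths
#' differ by at most one, and whose concatenation reproduces the
#' sequence.
#'
#' @param p Protein record.
#' @param max_len Segment budget (default 1000).
#' @return Character vector of sequence parts, in order.
#' @export
segment_protein <- function(p, max_len = 1000L) {
  L <- p$length
  stopifnot(L >= 1L)
  k <- ceiling(L / max_len)
  if (k <= 1L) return(p$sequence)
  base <- L %/% k
  extra <- L %% k
  lens <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_len(k), function(i) .subseq(p, starts[i], ends[i]), character(1))
}

#' Ensemble residue score track
#'
#' Scores a protein with each member model (segmenting long proteins,
#' scoring parts separately, and concatenating) and returns the
#' position-wise arithmetic mean across members.
#'
#' @param models List of trained `degron_scorer`s (length >= 1).
#' @param p Protein record.
#' @param max_len Segment budget passed to [segment_protein].
#' @return `list(accession, scores)`.
#' @export
ensemble_score <- function(models, p, max_len = 1000L) {
  stopifnot(length(models) >= 1L)
  parts <- segment_protein(p, max_len)
  tracks <- lapply(models, function(m) {
    unlist(lapply(parts, function(s) score_protein(m, s)$scores), use.names = FALSE)
  })
  list(accession = p$accession, scores = Reduce(`+`, tracks) / length(tracks))
}

#' Call degron intervals from a residue score track
#'
#' Takes maximal runs of scores at or above `cutoff`, iteratively merges
#' two runs whenever fewer than 4 residues lie strictly between them,
#' discards merged runs shorter than 3 residues, and reports the mean
#' track score over each final interval.
#'
#' @param track `list(accession, scores)` from [ensemble_score] or
#'   [score_protein].
#' @param cutoff Score threshold in \[0, 1\] (default 0.3).
#' @return `data.frame(protein_accession, start, end, mean_score)`.
#' @export
call_degrons <- function(track, cutoff = 0.3) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  empty <- data.frame(protein_accession = character(), start = integer(),
                      end = integer(), mean_score = numeric())
  hits <- track$scores >= cutoff
  if (!any(hits)) return(empty)
  r <- rle(hits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  # merge while any gap (residues strictly between) < 4
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    gap <- runs[i, 1] - merged[last, 2] - 1L
    if (gap < 4L) merged[last, 2] <- runs[i, 2] else merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= 3L
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(protein_accession = track$accession,
             start = as.integer(merged[, 1]),
             end = as.integer(merged[, 2]),
             mean_score = vapply(seq_len(nrow(merged)), function(i)
               mean(track$scores[merged[i, 1]:merged[i, 2]]), numeric(1)))
}

#' Predict degrons across a proteome
#'
#' Ensemble-scores every protein (with segmentation for long ones) and
#' calls degron intervals on the concatenated tracks.
#'
#' @param models List of trained scorers.
#' @param proteome Named protein-record list.
#' @param cutoff Calling cutoff (default 0.3).
#' @param max_len Segment budget (default 1000).
#' @return `data.frame(protein_accession, start, end, mean_score)`.
#' @export
predict_degrons <- function(models, proteome, cutoff = 0.3, max_len = 1000L) {
  calls <- lapply(proteome, function(p)
    call_degrons(ensemble_score(models, p, max_len), cutoff))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# batched eval-mode scoring of equal-width windows -> T x N score matrix
.score_windows <- function(scorer, windows, batch = 256L) {
  dat <- .window_matrices(windows)
  n <- ncol(dat$codes)
  scores <- matrix(0, nrow(dat$codes), n)
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    out <- bilstm_run_cpp(dat$codes[, idx, drop = FALSE], scorer$params,
                          scorer$config$h1, scorer$config$h2, scorer$config$f,
                          0, FALSE, matrix(0, 1, 1), matrix(FALSE, 1, 1),
                          FALSE, FALSE)
    scores[, idx] <- out$scores
  }
  list(scores = scores, y = dat$y, mask = dat$mask)
}

#' Residue-level false discovery rate at a score cutoff
#'
#' Scores positive and negative window sets, classifies unmasked
#' residues at `cutoff`, and returns FP / (TP + FP). Pairing positives
#' with negatives at 1:20 reproduces the calibration design under which
#' the reference pipeline reports its FDR.
#'
#' @param scorer Trained `degron_scorer`.
#' @param pos_windows,neg_windows Labelled window lists (both nonempty).
#' @param cutoff Classification cutoff (default 0.3).
#' @return `list(fdr, tp, fp)`.
#' @export
calibrate_fdr <- function(scorer, pos_windows, neg_windows, cutoff = 0.3) {
  stopifnot(length(pos_windows) > 0L, length(neg_windows) > 0L)
  all_w <- c(pos_windows, neg_windows)
  sc <- .score_windows(scorer, all_w)
  use <- !sc$mask
  pred <- sc$scores[use] >= cutoff
  truth <- sc$y[use] == 1
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  list(fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_, tp = tp, fp = fp)
}

#' Write degron calls as TSV
#'
#' @param calls Call `data.frame`.
#' @param path Output path.
#' @export
write_degron_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write degron calls as BED
#'
#' 0-based half-open conversion; the BED score column is the mean track
#' score scaled by 1000.
#'
#' @param calls Call `data.frame`.
#' @param path Output path.
#' @export
write_degron_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$protein_accession,
                    chromStart = calls$start - 1L,
                    chromEnd = calls$end,
                    name = sprintf("degron_%d", seq_len(nrow(calls))),
                    score = as.integer(round(calls$mean_score * 1000)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
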