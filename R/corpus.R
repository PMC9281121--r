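#' Load and deduplicate a degron table
#'
#' Reads a TSV of known degron annotations (columns `protein_accession`,
#' `start`, `end`, `sequence`, `source`, `e3`; 1-based inclusive
#' coordinates) and resolves each record against a proteome of canonical
#' ("main isoform") sequences. The same degron annotated on several
#' isoforms of one gene collapses to a single record on the canonical
#' accession: records are grouped by the (gene, degron sequence) key,
#' where the gene is the accession with any UniProt-style `-N` isoform
#' suffix stripped, and the canonical accession is the one present in the
#' supplied proteome. Records whose stated sequence does not match the
#' protein subsequence at the stated coordinates are rejected and listed
#' in the `"rejected"` attribute of the result.
#'
#' @param path TSV path with a header row.
#' @param proteome Named list of protein records from [read_proteome];
#'   one sequence per gene (the canonical isoforms).
#' @return `data.frame` with columns `protein_accession`, `start`, `end`,
#'   `sequence`, `source`, `e3`; attribute `"rejected"` holds the rows
#'   dropped for sequence mismatch (possibly empty).
#' @export
load_degron_table <- function(path, proteome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_accession", "start", "end", "sequence", "source", "e3")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("degron table missing columns: ",
                            paste(missing, collapse = ", "))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (nrow(tab) == 0L) {
    out <- tab[, required]
    attr(out, "rejected") <- out
    return(out)
  }

  gene <- sub("-[0-9]+$", "", tab$protein_accession)
  canonical <- names(proteome)
  canon_gene <- sub("-[0-9]+$", "", canonical)
  canon_of_gene <- stats::setNames(canonical, canon_gene)

  main_acc <- canon_of_gene[gene]
  unresolved <- unique(gene[is.na(main_acc)])
  if (length(unresolved)) {
    stop("accessions with no canonical sequence in the proteome: ",
         paste(unresolved, collapse = ", "))
  }
  tab$protein_accession <- unname(main_acc)

  # collapse isoform duplicates on the (gene, degron sequence) key
  key <- paste(gene, tab$sequence, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]

  ok <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- proteome[[tab$protein_accession[i]]]
    ok[i] <- tab$start[i] >= 1L && tab$end[i] >= tab$start[i] &&
      tab$end[i] <= p$length &&
      .subseq(p, tab$start[i], tab$end[i]) == tab$sequence[i]
  }
  out <- tab[ok, required, drop = FALSE]
  rownames(out) <- NULL
  rejected <- tab[!ok, required, drop = FALSE]
  rownames(rejected) <- NULL
  if (nrow(rejected)) {
    message(nrow(rejected), " degron record(s) rejected: sequence mismatch at stated coordinates")
  }
  attr(out, "rejected") <- rejected
  out
}

#' Expand a short degron to the minimum informative length
#'
#' Length-3 degrons grow to length 5 and length-4 degrons to length 6,
#' symmetrically around the original interval; a degron touching a
#' protein terminus extends only away from that terminus, and any
#' residual overhang at one end is pushed to the other. Degrons of length
#' 5 or more are returned unchanged.
#'
#' @param d One-row degron `data.frame` (or equivalent list) with
#'   `start`, `end` on `p`.
#' @param p Protein record hosting the degron.
#' @return The degron with updated `start`, `end`, `sequence`.
#' @export
expand_short_degron <- function(d, p) {
  len <- d$end - d$start + 1L
  if (len >= 5L) return(d)
  target <- len + 2L
  if (p$length < target) stop("protein too short to host the expanded degron")
  left <- d$start - 1L
  right <- p$length - d$end
  ext_l <- min(1L, left)
  ext_r <- min(1L, right)
  # push what did not fit on one side to the other
  deficit <- 2L - (ext_l + ext_r)
  if (deficit > 0L) {
    add_r <- min(deficit, right - ext_r)
    ext_r <- ext_r + add_r
    ext_l <- ext_l + (deficit - add_r)
  }
  d$start <- d$start - ext_l
  d$end <- d$end + ext_r
  d$sequence <- .subseq(p, d$start, d$end)
  d
}

#' Per-residue labels and loss-exclusion mask for a window
#'
#' Residues inside degron spans are labelled 1 and everything else 0.
#' The three residues flanking each span on either side (clipped at the
#' window bounds) are flagged for exclusion from loss and metrics: they
#' may contribute to E3 binding but carry no experimental label.
#'
#' @param width Window width.
#' @param spans List of `c(start, end)` pairs in 1-based window coordinates.
#' @param flank Number of flanking residues to exclude (default 3).
#' @return `list(y, mask)`: `y` is 0/1, `mask` is logical with `TRUE`
#'   meaning "excluded from loss and metrics".
#' @export
make_labels <- function(width, spans, flank = 3L) {
  y <- integer(width)
  mask <- logical(width)
  for (sp in spans) {
    stopifnot(sp[1] >= 1L, sp[2] <= width, sp[1] <= sp[2])
    y[sp[1]:sp[2]] <- 1L
    lo <- max(1L, sp[1] - flank)
    hi <- min(width, sp[2] + flank)
    if (lo < sp[1]) mask[lo:(sp[1] - 1L)] <- TRUE
    if (hi > sp[2]) mask[(sp[2] + 1L):hi] <- TRUE
  }
  mask[y == 1L] <- FALSE  # degron residues themselves are always kept
  list(y = y, mask = mask)
}

# window of `width` residues whose protein-coordinate start is `wstart`
# (may run off either terminus; overhangs become 'X' padding)
.padded_window <- function(p, wstart, width) {
  pos <- wstart:(wstart + width - 1L)
  chars <- rep("X", width)
  inside <- pos >= 1L & pos <= p$length
  if (any(inside)) {
    chars[inside] <- strsplit(.subseq(p, max(1L, wstart), min(p$length, wstart + width - 1L)),
                              "")[[1]]
  }
  paste(chars, collapse = "")
}

#' Sample training windows around a degron
#'
#' Draws `k` windows of width `w`, each fully containing the degron. The
#' degron's offset inside the window is uniform over all `w - len + 1`
#' placements; windows overhanging a protein terminus are padded with
#' `"X"`, so terminal degrons admit the same placement range as internal
#' ones. Padded positions carry label 0 and are not masked.
#'
#' @param d One-row degron record on `p`.
#' @param p Protein record.
#' @param k Number of windows.
#' @param w Window width (default 128).
#' @param seed Integer seed; identical seeds give identical windows.
#' @return List of labelled windows: `list(residues, y, mask, accession,
#'   window_start)`, with `window_start` the 1-based protein coordinate of
#'   the window's first residue (zero or negative when left-padded).
#' @export
sample_windows <- function(d, p, k, w = 128L, seed = 1L) {
  dlen <- d$end - d$start + 1L
  if (w < dlen) stop("window width ", w, " smaller than degron length ", dlen)
  if (k == 0L) return(list())
  offsets <- withr::with_seed(seed, sample.int(w - dlen + 1L, k, replace = TRUE) - 1L)
  lapply(offsets, function(o) {
    wstart <- d$start - o
    residues <- .padded_window(p, wstart, w)
    lab <- make_labels(w, list(c(o + 1L, o + dlen)))
    list(residues = residues, y = lab$y, mask = lab$mask,
         accession = p$accession, window_start = wstart)
  })
}

#' Build a labelled window corpus from a degron table
#'
#' Expands short degrons, then samples `k` windows per degron. One
#' sub-seed per degron keeps the draw reproducible and independent of
#' table order within a degron.
#'
#' @param degrons Degron `data.frame` from [load_degron_table].
#' @param proteome Named protein-record list.
#' @param k Windows per degron (default 10).
#' @param w Window width (default 128).
#' @param seed Integer seed.
#' @return List of labelled windows.
#' @export
build_window_corpus <- function(degrons, proteome, k = 10L, w = 128L, seed = 1L) {
  out <- vector("list", nrow(degrons) * k)
  n <- 0L
  for (i in seq_len(nrow(degrons))) {
    p <- proteome[[degrons$protein_accession[i]]]
    d <- expand_short_degron(degrons[i, ], p)
    ws <- sample_windows(d, p, k, w, seed = seed + i)
    out[n + seq_along(ws)] <- ws
    n <- n + length(ws)
  }
  out[seq_len(n)]
}

#' Sample negative windows centred on motif matches
#'
#' For the motif-match comparison mode: builds all-zero-label windows
#' from precomputed motif matches on proteins that carry no known degron,
#' one window per sampled match with the match centred. The number of
#' windows honours the requested positive:negative ratio.
#'
#' @param proteome Named protein-record list of degron-free donors.
#' @param matches `data.frame` with `protein_accession`, `start`, `end`
#'   of candidate motif matches on the donor proteins.
#' @param n_pos Number of positive examples the negatives are paired with.
#' @param ratio Negatives per positive (e.g. 5 for 1:5, 20 for 1:20).
#' @param w Window width (default 128).
#' @param seed Integer seed.
#' @return List of labelled windows with all labels 0.
#' @export
sample_negative_windows <- function(proteome, matches, n_pos, ratio, w = 128L, seed = 1L) {
  n_neg <- as.integer(round(n_pos * ratio))
  if (n_neg == 0L) return(list())
  keep <- matches$protein_accession %in% names(proteome)
  matches <- matches[keep, , drop = FALSE]
  if (nrow(matches) < n_neg) {
    stop("insufficient donor motif matches: need ", n_neg, ", have ", nrow(matches))
  }
  rows <- withr::with_seed(seed, sample.int(nrow(matches), n_neg))
  lapply(rows, function(i) {
    p <- proteome[[matches$protein_accession[i]]]
    centre <- (matches$start[i] + matches$end[i]) %/% 2L
    wstart <- centre - w %/% 2L + 1L
    list(residues = .padded_window(p, wstart, w),
         y = integer(w), mask = logical(w),
         accession = p$accession, window_start = wstart)
  })
}

#' Write labelled windows to TSV
#'
#' Columns: `accession`, `window_start`, `residues`, `y`, `mask`, the
#' last two as 0/1 strings of the window width.
#'
#' @param windows List of labelled windows.
#' @param path Output TSV path.
#' @export
write_windows <- function(windows, path) {
  df <- data.frame(
    accession = vapply(windows, `[[`, character(1), "accession"),
    window_start = vapply(windows, `[[`, integer(1), "window_start"),
    residues = vapply(windows, `[[`, character(1), "residues"),
    y = vapply(windows, function(wi) paste(wi$y, collapse = ""), character(1)),
    mask = vapply(windows, function(wi) paste(as.integer(wi$mask), collapse = ""), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labelled windows from TSV
#'
#' @param path TSV written by [write_windows].
#' @return List of labelled windows.
#' @export
read_windows <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(y = "character", mask = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    list(residues = df$residues[i],
         y = as.integer(strsplit(df$y[i], "")[[1]]),
         mask = as.logical(as.integer(strsplit(df$mask[i], "")[[1]])),
         accession = df$accession[i],
         window_start = df$window_start[i])
  })
}
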