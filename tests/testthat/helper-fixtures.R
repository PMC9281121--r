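# Shared in-code fixtures: everything is generated at test time.

# uniform background (every F_a = 0.05) for hand-checkable PSSM algebra
uniform_bg <- function() {
  stats::setNames(rep(0.05, 20), AA_ALPHABET)
}

# deterministic toy proteome: named list of records from bare sequences
toy_proteome <- function(seqs) {
  prot <- lapply(names(seqs), function(a) protein_record(a, seqs[[a]]))
  stats::setNames(prot, names(seqs))
}

# random protein sequence from the bundled background
random_sequence <- function(L, seed = 1L) {
  withr::with_seed(seed, paste(sample(AA_ALPHABET, L, replace = TRUE,
                                      prob = load_background()),
                               collapse = ""))
}

# write a degron data.frame + proteome to temp files, return paths
write_degron_fixture <- function(degrons, proteome) {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  write_proteome(proteome, fa)
  write_degron_table(degrons, tsv)
  list(fasta = fa, tsv = tsv)
}

# a tiny trained scorer for contract tests (seconds, not minutes)
tiny_trained_scorer <- function(seed = 5L, epochs = 8L) {
  p <- protein_record("TP1", random_sequence(80, seed))
  d <- data.frame(protein_accession = "TP1", start = 30L, end = 35L,
                  sequence = substr(p$sequence, 30, 35),
                  source = "ELM", e3 = "")
  win <- sample_windows(d, p, k = 12L, w = 48L, seed = seed)
  train_scorer(win, scorer_config(20, 4, 4, 4),
               train_config(batch_size = 8, max_epochs = epochs,
                            patience = 3, seed = seed))
}

# an untrained scorer (random parameters) with a valid class structure
untrained_scorer <- function(cfg = scorer_config(20, 4, 4, 4), seed = 2L) {
  params <- withr::with_seed(seed, degronet:::.init_params(cfg))
  structure(list(params = params, config = cfg, tconf = train_config(seed = seed),
                 history = numeric(0), best_epoch = 0L, best_loss = NA_real_),
            class = "degron_scorer")
}

# brute-force pairwise AUC oracle
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# brute-force transitive-closure merge oracle for degron calling:
# keep merging any two runs separated by fewer than `gap` residues
merge_bruteforce <- function(runs, gap = 4L) {
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  repeat {
    done <- TRUE
    i <- 1L
    while (i < nrow(runs)) {
      if (runs[i + 1L, 1] - runs[i, 2] - 1L < gap) {
        runs[i, 2] <- max(runs[i, 2], runs[i + 1L, 2])
        runs <- runs[-(i + 1L), , drop = FALSE]
        done <- FALSE
      } else i <- i + 1L
    }
    if (done) return(runs)
  }
}

# exhaustive hypergeometric upper-tail oracle: P(X >= k) for X ~
# Hypergeom(white = m, black = L - m, drawn = n)
hyper_tail_bruteforce <- function(k, m, L, n) {
  ks <- max(0L, k):min(m, n)
  sum(choose(m, ks) * choose(L - m, n - ks)) / choose(L, n)
}
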