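#' Scorer architecture configuration
#'
#' The per-residue scorer is two bidirectional LSTM layers followed by two
#' fully connected layers with a sigmoid output node, applied
#' position-wise. `input_width` is 20 for the one-hot encoder and 768 for
#' a frozen pretrained protein language-model embedder (which contributes
#' no trainable parameters).
#'
#' @param input_width 20 (one-hot) or 768 (pretrained embedder).
#' @param h1,h2 Hidden widths of the first and second bidirectional
#'   recurrent layers (per direction).
#' @param f Width of the first fully connected layer.
#' @param dropout Dropout rate applied after each recurrent layer and the
#'   first fully connected layer during training (default 0.3).
#' @param encoder `"onehot"` or `"pretrained"`.
#' @return Object of class `scorer_config`.
#' @export
scorer_config <- function(input_width = 20L, h1 = 24L, h2 = 24L, f = 16L,
                          dropout = 0.3, encoder = c("onehot", "pretrained")) {
  encoder <- match.arg(encoder)
  stopifnot(input_width %in% c(20L, 768L), h1 >= 1L, h2 >= 1L, f >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(input_width = as.integer(input_width), h1 = as.integer(h1),
                 h2 = as.integer(h2), f = as.integer(f), dropout = dropout,
                 encoder = encoder),
            class = "scorer_config")
}

#' Published architecture presets
#'
#' Layer widths of the two reference architectures, fixed by
#' [search_scorer_widths()]: the bounded integer search for (h1, h2, f)
#' whose closed-form trainable-parameter count equals the published
#' totals, 230,929 for the 768-input model and 243,729 for the one-hot
#' model. Among exact solutions the configuration closest to an
#' equal-width recurrent stack (minimal |h1 - h2|, ties to smaller h1) is
#' selected; for the 768-input model this solution (32, 32, 8) is the
#' unique one with h1 == h2.
#'
#' @param encoder `"onehot"` or `"pretrained"`.
#' @return A [scorer_config].
#' @export
published_scorer_config <- function(encoder = c("onehot", "pretrained")) {
  encoder <- match.arg(encoder)
  if (encoder == "pretrained") {
    scorer_config(768L, 32L, 32L, 8L, encoder = "pretrained")
  } else {
    scorer_config(20L, 81L, 87L, 13L, encoder = "onehot")
  }
}

#' Count trainable parameters of a scorer
#'
#' Closed form under the standard LSTM cell parameterisation with two
#' bias vectors per direction: each direction of a recurrent layer with
#' input width `in` and hidden width `h` has `4*((in+h)*h + 2*h)`
#' parameters; the two fully connected layers add `f*(2*h2 + 1)` and
#' `f + 1`. A frozen pretrained encoder contributes nothing.
#'
#' @param config A [scorer_config].
#' @return Integer parameter count.
#' @export
count_trainable_params <- function(config) {
  d <- config$input_width; h1 <- config$h1; h2 <- config$h2; f <- config$f
  dir1 <- 4L * ((d + h1) * h1 + 2L * h1)
  dir2 <- 4L * ((2L * h1 + h2) * h2 + 2L * h2)
  2L * dir1 + 2L * dir2 + f * (2L * h2 + 1L) + f + 1L
}

#' Bounded width search for the published parameter counts
#'
#' Enumerates (h1, h2, f) in `[1, max_width]^3` and returns every
#' configuration whose [count_trainable_params] equals `target` for the
#' given input width. The `selected` column marks the configuration the
#' package ships as its published-architecture preset: minimal |h1 - h2|,
#' ties broken toward smaller h1, then smaller f.
#'
#' @param input_width 20 or 768.
#' @param target Target parameter count.
#' @param max_width Upper bound of the search cube (default 512).
#' @return `data.frame(h1, h2, f, count, selected)` sorted by |h1 - h2|.
#' @export
search_scorer_widths <- function(input_width, target, max_width = 512L) {
  d <- as.integer(input_width)
  sols <- list()
  for (h1 in seq_len(max_width)) {
    for (h2 in seq_len(max_width)) {
      base <- 8L * h1 * (d + h1 + 2L) + 8L * h2 * (2L * h1 + h2 + 2L) + 1L
      rem <- target - base
      if (rem <= 0L) next
      if (rem %% (2L * h2 + 2L) == 0L) {
        f <- rem %/% (2L * h2 + 2L)
        if (f >= 1L && f <= max_width) sols[[length(sols) + 1L]] <- c(h1, h2, f)
      }
    }
  }
  if (!length(sols)) return(data.frame(h1 = integer(), h2 = integer(), f = integer(),
                                       count = integer(), selected = logical()))
  m <- do.call(rbind, sols)
  df <- data.frame(h1 = m[, 1], h2 = m[, 2], f = m[, 3])
  df$count <- vapply(seq_len(nrow(df)), function(i)
    count_trainable_params(scorer_config(d, df$h1[i], df$h2[i], df$f[i])), integer(1))
  df <- df[order(abs(df$h1 - df$h2), df$h1, df$f), , drop = FALSE]
  df$selected <- seq_len(nrow(df)) == 1L
  rownames(df) <- NULL
  df
}

# residue string -> integer codes with 0 for 'X'
.window_codes <- function(residues) {
  codes <- aa_codes(residues)
  codes[is.na(codes)] <- 0L
  codes
}

#' One-hot encode a protein sequence
#'
#' Returns a 20 x L matrix in [AA_ALPHABET] row order; each standard
#' residue's column has a single 1 and `"X"` columns are all zero.
#'
#' @param sequence Sequence string.
#' @return 20 x L numeric matrix.
#' @export
one_hot_encode <- function(sequence) {
  codes <- .window_codes(sequence)
  L <- length(codes)
  m <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA_ALPHABET, NULL))
  nz <- which(codes > 0L)
  m[cbind(codes[nz], nz)] <- 1
  m
}

#' Embed a sequence with a frozen pretrained protein language model
#'
#' The pretrained encoder (a BERT-style transformer producing a
#' 768 x (L+2) feature matrix with start/end sentinel columns) is an
#' optional external dependency that is not bundled. This stub always
#' raises a capability error directing callers to the one-hot path, so
#' pipelines degrade explicitly rather than silently.
#'
#' @param sequence Sequence string.
#' @export
embed_pretrained <- function(sequence) {
  validate_sequence(sequence)
  stop("pretrained protein language-model embedder is not available in this ",
       "installation; use the one-hot encoder (scorer_config(encoder = 'onehot'))",
       call. = FALSE)
}

#' Weighted per-residue cross-entropy loss
#'
#' `-(1/n^2) * sum((n - n_deg)*y*log(p) + n_deg*(1-y)*log(1-p))` over
#' unmasked residues, where `n` is the number of residues contributing to
#' the loss and `n_deg` the number of those labelled as degron.
#' Predictions are clipped to `[1e-7, 1 - 1e-7]`; logs are natural.
#'
#' @param y 0/1 labels.
#' @param y_pred Predictions in (0, 1).
#' @param mask Logical, `TRUE` = excluded from the loss (default none).
#' @return Nonnegative scalar.
#' @export
weighted_loss <- function(y, y_pred, mask = NULL) {
  if (is.null(mask)) mask <- logical(length(y))
  stopifnot(length(y) == length(y_pred), length(mask) == length(y))
  y <- y[!mask]; p <- y_pred[!mask]
  n <- length(y)
  if (n == 0L) stop("no unmasked residues: loss undefined")
  n_deg <- sum(y == 1L)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -sum((n - n_deg) * y * log(p) + n_deg * (1 - y) * log(1 - p)) / n^2
}

#' Classification metrics from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), FDR = FP/(TP+FP),
#' accuracy = (TP+TN)/total. A metric whose denominator is zero is
#' returned as `NA` (undefined) rather than an arbitrary value.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return Named list `precision`, `recall`, `fdr`, `accuracy`.
#' @export
scorer_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  list(precision = div(tp, tp + fp),
       recall = div(tp, tp + fn),
       fdr = div(fp, tp + fp),
       accuracy = div(tp + tn, tp + fp + tn + fn))
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation with ties credited 0.5, identical
#' to the fraction of positive-negative pairs ranked correctly.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("AUC requires both classes present")
  r <- rank(scores)  # mean ranks on ties
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Training configuration
#'
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 3e-4).
#' @param patience Consecutive non-improving epochs before stopping
#'   (default 5).
#' @param max_epochs Hard cap on epochs (default 100).
#' @param seed Integer seed controlling initialisation, shuffling, and
#'   dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, lr = 3e-4, patience = 5L,
                         max_epochs = 100L, seed = 1L) {
  stopifnot(batch_size >= 1L, lr > 0, patience >= 1L, max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

# PyTorch-style init: every tensor of a recurrent layer ~ U(-k, k) with
# k = 1/sqrt(h); linear layers with k = 1/sqrt(fan_in)
.init_params <- function(config) {
  d <- config$input_width; h1 <- config$h1; h2 <- config$h2; f <- config$f
  blk <- function(n, k) stats::runif(n, -k, k)
  c(blk(2 * (4 * h1 * (d + h1 + 2)), 1 / sqrt(h1)),
    blk(2 * (4 * h2 * (2 * h1 + h2 + 2)), 1 / sqrt(h2)),
    blk(f * 2 * h2 + f, 1 / sqrt(2 * h2)),
    blk(f + 1, 1 / sqrt(f)))
}

# stack windows into T x N matrices for the C++ core
.window_matrices <- function(windows) {
  w <- nchar(windows[[1]]$residues)
  n <- length(windows)
  codes <- matrix(0L, w, n)
  y <- matrix(0, w, n)
  mask <- matrix(FALSE, w, n)
  for (i in seq_len(n)) {
    wi <- windows[[i]]
    stopifnot(nchar(wi$residues) == w)
    codes[, i] <- .window_codes(wi$residues)
    y[, i] <- wi$y
    mask[, i] <- wi$mask
  }
  list(codes = codes, y = y, mask = mask)
}

#' Train the per-residue degron scorer
#'
#' Fits the bidirectional recurrent scorer on labelled fixed-width
#' windows by minibatch Adam under the weighted cross-entropy loss.
#' Masked (degron-flanking) residues are excluded from the loss. Training
#' stops when the epoch loss has not improved for `patience` consecutive
#' epochs (or at `max_epochs`), and the parameters from the best-loss
#' epoch are returned. Only the one-hot encoder is trainable in this
#' installation; see [embed_pretrained].
#'
#' @param windows List of labelled windows (see [build_window_corpus]);
#'   must contain at least one positive residue, otherwise both loss
#'   weights vanish and there is no gradient.
#' @param config A [scorer_config] (one-hot).
#' @param tconf A [train_config].
#' @return Object of class `degron_scorer` with elements `params`,
#'   `config`, `tconf`, `history` (per-epoch loss), `best_epoch`,
#'   `best_loss`.
#' @export
train_scorer <- function(windows, config = scorer_config(), tconf = train_config()) {
  if (config$encoder != "onehot") {
    stop("only the one-hot encoder is trainable here; the pretrained path ",
         "requires the external embedder (see embed_pretrained)")
  }
  dat <- .window_matrices(windows)
  if (sum(dat$y[!dat$mask]) == 0) {
    stop("degenerate corpus: no positive labels, loss is identically zero")
  }
  n <- ncol(dat$codes)

  withr::with_seed(tconf$seed, {
    params <- .init_params(config)
    mom <- numeric(length(params)); vel <- numeric(length(params))
    beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8; step <- 0L
    history <- numeric(0)
    best_loss <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L

    for (epoch in seq_len(tconf$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = tconf$batch_size)) {
        idx <- ord[b0:min(b0 + tconf$batch_size - 1L, n)]
        out <- bilstm_run_cpp(dat$codes[, idx, drop = FALSE], params,
                              config$h1, config$h2, config$f,
                              config$dropout, TRUE,
                              dat$y[, idx, drop = FALSE],
                              dat$mask[, idx, drop = FALSE],
                              TRUE, TRUE)
        step <- step + 1L
        mom <- beta1 * mom + (1 - beta1) * out$grad
        vel <- beta2 * vel + (1 - beta2) * out$grad^2
        mhat <- mom / (1 - beta1^step)
        vhat <- vel / (1 - beta2^step)
        params <- params - tconf$lr * mhat / (sqrt(vhat) + aeps)
        losses <- c(losses, out$loss)
      }
      epoch_loss <- mean(losses)
      history <- c(history, epoch_loss)
      if (epoch_loss < best_loss) {
        best_loss <- epoch_loss; best_params <- params
        best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tconf$patience) break
      }
    }
  })

  structure(list(params = best_params, config = config, tconf = tconf,
                 history = history, best_epoch = best_epoch,
                 best_loss = best_loss),
            class = "degron_scorer")
}

#' Score every residue of a protein
#'
#' Evaluation-mode (dropout off, hence deterministic) forward pass over
#' the full sequence; one score in \[0, 1\] per residue. Long proteins
#' should be segmented first (see [segment_protein]); this function
#' scores exactly the sequence it is given.
#'
#' @param scorer A trained `degron_scorer`.
#' @param p Protein record, or a bare sequence string.
#' @return `list(accession, scores)` with `length(scores) ==` protein length.
#' @export
score_protein <- function(scorer, p) {
  if (is.character(p)) p <- protein_record("query", p)
  codes <- matrix(.window_codes(p$sequence), ncol = 1L)
  out <- bilstm_run_cpp(codes, scorer$params,
                        scorer$config$h1, scorer$config$h2, scorer$config$f,
                        0, FALSE,
                        matrix(0, nrow(codes), 1L), matrix(FALSE, nrow(codes), 1L),
                        FALSE, FALSE)
  list(accession = p$accession, scores = as.numeric(out$scores))
}

#' @export
predict.degron_scorer <- function(object, newdata, ...) {
  score_protein(object, newdata)$scores
}

#' @export
coef.degron_scorer <- function(object, ...) object$params

#' @export
print.degron_scorer <- function(x, ...) {
  cfg <- x$config
  cat("Per-residue degron scorer (bidirectional LSTM x2 + FC x2, sigmoid)\n")
  cat(sprintf("  encoder: %s (input width %d); h1=%d h2=%d f=%d; dropout %.2f\n",
              cfg$encoder, cfg$input_width, cfg$h1, cfg$h2, cfg$f, cfg$dropout))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_params(cfg), big.mark = ",")))
  cat(sprintf("  trained %d epoch(s); best epoch %d, loss %.6g\n",
              length(x$history), x$best_epoch, x$best_loss))
  invisible(x)
}

#' Serialize a trained scorer to JSON
#'
#' Single-file checkpoint embedding the architecture, training seed, and
#' flat parameter vector.
#'
#' @param scorer A `degron_scorer`.
#' @param path Output path.
#' @export
write_scorer <- function(scorer, path) {
  obj <- list(config = unclass(scorer$config), tconf = unclass(scorer$tconf),
              params = scorer$params, history = scorer$history,
              best_epoch = scorer$best_epoch, best_loss = scorer$best_loss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scorer checkpoint written by [write_scorer]
#'
#' @param path Checkpoint path.
#' @return A `degron_scorer`.
#' @export
read_scorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(scorer_config, obj$config[c("input_width", "h1", "h2", "f",
                                             "dropout", "encoder")])
  structure(list(params = as.numeric(obj$params), config = cfg,
                 tconf = do.call(train_config, obj$tconf),
                 history = as.numeric(obj$history),
                 best_epoch = as.integer(obj$best_epoch),
                 best_loss = as.numeric(obj$best_loss)),
            class = "degron_scorer")
}
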