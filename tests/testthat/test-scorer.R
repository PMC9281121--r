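test_that("one-hot encoding has unit columns and all-zero X columns", {
  m <- one_hot_encode("ACD")
  expect_equal(dim(m), c(20L, 3L))
  expect_equal(unname(colSums(m)), c(1, 1, 1))
  expect_equal(unname(m["A", 1]), 1)
  expect_equal(unname(m["D", 3]), 1)

  mx <- one_hot_encode("AXA")
  expect_equal(unname(colSums(mx)), c(1, 0, 1))

  expect_error(one_hot_encode(""), "empty")
  expect_error(one_hot_encode("ABZ"), "illegal symbols")
})

test_that("the pretrained embedder path degrades with a capability error", {
  expect_error(embed_pretrained("ACDEFGHIKL"), "one-hot")
})

test_that("weighted loss matches hand evaluation and its degenerate cases", {
  # n = 2, n_deg = 1, y = (1,0), y_pred = (.5,.5), natural log
  expect_equal(weighted_loss(c(1, 0), c(0.5, 0.5)), 0.3465736, tolerance = 1e-6)
  expect_equal(weighted_loss(c(1, 0), c(0.5, 0.5)), log(2) / 2)

  # perfect predictions at the clip boundary -> loss ~ 0
  expect_lt(weighted_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  # all-negative window: both weights vanish
  expect_equal(weighted_loss(rep(0, 8), runif(8)), 0)
  # masked positions are excluded entirely
  expect_equal(weighted_loss(c(1, 0, 1), c(0.5, 0.5, 0.01), mask = c(FALSE, FALSE, TRUE)),
               weighted_loss(c(1, 0), c(0.5, 0.5)))
  expect_error(weighted_loss(c(1, 0), c(.5, .5), mask = c(TRUE, TRUE)), "no unmasked")
})

test_that("loss decreases as predictions move toward labels, and is symmetric at balance", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- 30L
      y <- rbinom(n, 1, 0.4)
      if (sum(y) %in% c(0L, n)) next
      p <- runif(n, 0.05, 0.95)
      closer <- y + (p - y) / 2  # halve every prediction error
      expect_lt(weighted_loss(y, closer), weighted_loss(y, p))
    }
    # n_deg = n/2: both class weights equal, complement symmetry holds
    y <- rep(c(1, 0), 10)
    p <- runif(20, 0.05, 0.95)
    expect_equal(weighted_loss(y, p), weighted_loss(1 - y, 1 - p))
  })
})

test_that("trainable-parameter count matches the published totals and the C++ core", {
  expect_identical(count_trainable_params(published_scorer_config("pretrained")),
                   230929L)
  expect_identical(count_trainable_params(published_scorer_config("onehot")),
                   243729L)
  # closed form agrees with the compiled layout and the initialiser length
  for (cfg in list(scorer_config(20, 3, 5, 7), scorer_config(20, 24, 24, 16))) {
    n <- count_trainable_params(cfg)
    expect_identical(n, degronet:::bilstm_nparam_cpp(cfg$input_width, cfg$h1,
                                                     cfg$h2, cfg$f))
    expect_length(withr::with_seed(1, degronet:::.init_params(cfg)), n)
  }
  # strictly increasing in each width
  base <- count_trainable_params(scorer_config(20, 8, 8, 8))
  expect_gt(count_trainable_params(scorer_config(20, 9, 8, 8)), base)
  expect_gt(count_trainable_params(scorer_config(20, 8, 9, 8)), base)
  expect_gt(count_trainable_params(scorer_config(20, 8, 8, 9)), base)
})

test_that("bounded width search recovers the shipped presets", {
  s768 <- search_scorer_widths(768, 230929)
  expect_true(all(s768$count == 230929L))
  sel <- s768[s768$selected, ]
  expect_equal(c(sel$h1, sel$h2, sel$f), c(32L, 32L, 8L))

  s20 <- search_scorer_widths(20, 243729)
  expect_true(all(s20$count == 243729L))
  sel20 <- s20[s20$selected, ]
  expect_equal(c(sel20$h1, sel20$h2, sel20$f), c(81L, 87L, 13L))
})

test_that("analytic gradients match numerical differentiation", {
  withr::with_seed(42, {
    cfg <- scorer_config(20, 3, 4, 5, dropout = 0)
    np <- count_trainable_params(cfg)
    params <- runif(np, -0.3, 0.3)
    T <- 7L; B <- 2L
    codes <- matrix(sample(0:20, T * B, replace = TRUE), T, B)
    y <- matrix(rbinom(T * B, 1, 0.3), T, B)
    mask <- matrix(runif(T * B) < 0.2, T, B)
    if (sum(y[!mask]) == 0) y[1, 1] <- 1
    out <- degronet:::bilstm_run_cpp(codes, params, 3L, 4L, 5L, 0, FALSE,
                                     y, mask, TRUE, TRUE)
    eps <- 1e-6
    idx <- sample.int(np, 60L)  # spot-check a spread of parameters
    for (i in idx) {
      pp <- params; pp[i] <- pp[i] + eps
      pm <- params; pm[i] <- pm[i] - eps
      lp <- degronet:::bilstm_run_cpp(codes, pp, 3L, 4L, 5L, 0, FALSE,
                                      y, mask, TRUE, FALSE)$loss
      lm <- degronet:::bilstm_run_cpp(codes, pm, 3L, 4L, 5L, 0, FALSE,
                                      y, mask, TRUE, FALSE)$loss
      expect_equal(out$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  })
})

test_that("training is seeded, returns the best epoch, and rejects degenerate corpora", {
  sc1 <- tiny_trained_scorer(seed = 5L)
  sc2 <- tiny_trained_scorer(seed = 5L)
  expect_identical(sc1$history, sc2$history)
  expect_identical(sc1$params, sc2$params)

  expect_equal(sc1$best_loss, min(sc1$history))
  expect_equal(sc1$best_epoch, which.min(sc1$history))
  # stopped within patience of the best epoch (or at the cap)
  expect_lte(length(sc1$history), sc1$best_epoch + sc1$tconf$patience)

  # all-negative corpus has no gradient
  neg <- list(list(residues = strrep("A", 32L), y = integer(32L),
                   mask = logical(32L), accession = "N", window_start = 1L))
  expect_error(train_scorer(neg, scorer_config(20, 4, 4, 4)), "degenerate")
})

test_that("protein scoring is per-residue, bounded, and deterministic", {
  sc <- tiny_trained_scorer(seed = 6L, epochs = 3L)
  p <- protein_record("Q", random_sequence(137, seed = 3))
  t1 <- score_protein(sc, p)
  expect_length(t1$scores, 137L)
  expect_true(all(t1$scores >= 0 & t1$scores <= 1))
  expect_identical(t1, score_protein(sc, p))
  expect_identical(predict(sc, p), t1$scores)
})

test_that("confusion metrics follow the stated formulas with NA on empty denominators", {
  m <- scorer_metrics(tp = 8, fp = 2, tn = 88, fn = 2)
  expect_equal(m, list(precision = 0.8, recall = 0.8, fdr = 0.2, accuracy = 0.96))
  m2 <- scorer_metrics(tp = 5, fp = 0, tn = 10, fn = 1)
  expect_equal(m2$precision, 1)
  expect_equal(m2$fdr, 0)
  m3 <- scorer_metrics(tp = 0, fp = 3, tn = 10, fn = 0)
  expect_true(is.na(m3$recall))
})

test_that("AUC equals the pairwise comparison oracle and is rank-invariant", {
  expect_equal(auc_score(c(1, 0, 0), c(0.9, 0.8, 0.3)), 1)
  expect_equal(auc_score(c(1, 0), c(0.2, 0.7)), 0)
  expect_error(auc_score(c(1, 1), c(.2, .3)), "both classes")

  withr::with_seed(13, {
    for (rep in 1:5) {
      labels <- rbinom(50, 1, 0.4)
      if (sum(labels) %in% c(0L, 50L)) labels[1:2] <- c(0L, 1L)
      scores <- round(runif(50), 2)  # coarse grid forces ties
      a <- auc_score(labels, scores)
      expect_equal(a, auc_bruteforce(labels, scores))
      # invariance under a strictly monotone transform
      expect_equal(auc_score(labels, exp(3 * scores)), a)
    }
  })
})

test_that("scorer checkpoints round-trip through JSON", {
  sc <- tiny_trained_scorer(seed = 9L, epochs = 3L)
  path <- tempfile(fileext = ".json")
  write_scorer(sc, path)
  back <- read_scorer(path)
  expect_equal(back$params, sc$params)
  expect_equal(unclass(back$config), unclass(sc$config))
  p <- protein_record("Q", random_sequence(60, seed = 4))
  expect_equal(score_protein(back, p), score_protein(sc, p))
})
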