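test_that("PSSM cells follow the pseudocount log-odds formula exactly", {
  # 20 cores, 9 of them with 'A' at position 1, uniform background 0.05:
  # S[1, A] = log2(((9+1)/(20+20)) / 0.05) = log2(5)
  cores <- c(rep("AC", 9), rep("CC", 11))
  p <- build_pssm(cores, bg = uniform_bg())
  expect_equal(unname(p$scores[1, "A"]), log2(5))
  expect_equal(unname(p$scores[1, "A"]), 2.3219, tolerance = 1e-4)
  # a cell at exactly the background rate scores 0: (C+1)/(N+20) == F
  # C = 1 at position 2 for 'G' with N = 20: (1+1)/40 = 0.05
  cores2 <- c("AG", rep("AC", 19))
  p2 <- build_pssm(cores2, bg = uniform_bg())
  expect_equal(unname(p2$scores[2, "G"]), 0)
})

test_that("every PSSM column satisfies the normalisation identity", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- sample(3:50, 1)
      m <- sample(5:8, 1)
      cores <- vapply(seq_len(n), function(i)
        paste(sample(AA_ALPHABET, m, replace = TRUE), collapse = ""), character(1))
      bg <- load_background()
      p <- build_pssm(cores, bg = bg)
      for (i in seq_len(m)) {
        expect_equal(sum(bg * 2^p$scores[i, ]), 1, tolerance = 1e-9)
      }
    }
  })
})

test_that("match scoring sums equal-length peptides and slides longer ones", {
  cores <- c("ACDEF", "ACDEG", "ACDEH")
  p <- build_pssm(cores, bg = uniform_bg())
  # equal length: plain sum of per-position entries
  pep <- "ACDEF"
  expect_equal(match_score(p, pep),
               sum(p$scores[cbind(1:5, match(strsplit(pep, "")[[1]], AA_ALPHABET))]))
  # length m+1: max of the two window sums
  pep6 <- "KACDEF"
  w1 <- sum(p$scores[cbind(1:5, match(strsplit("KACDE", "")[[1]], AA_ALPHABET))])
  w2 <- sum(p$scores[cbind(1:5, match(strsplit("ACDEF", "")[[1]], AA_ALPHABET))])
  expect_equal(match_score(p, pep6), max(w1, w2))
  # shorter than the PSSM: undefined, not an error
  expect_true(is.na(match_score(p, "ACDE")))
  # windows containing X are skipped, not imputed
  expect_equal(match_score(p, "XACDEF"), w2)
  expect_true(is.na(match_score(p, "ACXEF")))
})

test_that("reversal flips positions only and double reversal is the identity", {
  withr::with_seed(8, {
    cores <- vapply(1:10, function(i)
      paste(sample(AA_ALPHABET, 6, replace = TRUE), collapse = ""), character(1))
  })
  p <- build_pssm(cores)
  expect_equal(reverse_pssm(reverse_pssm(p)), p)
  # palindromic score grid is unchanged
  pp <- p
  pp$scores <- (pp$scores + pp$scores[6:1, ]) / 2
  expect_equal(reverse_pssm(pp)$scores, pp$scores)
  # scoring with the reversed PSSM equals scoring the reversed peptide
  withr::with_seed(9, {
    for (rep in 1:10) {
      pep <- paste(sample(AA_ALPHABET, 6, replace = TRUE), collapse = "")
      rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
      expect_equal(match_score(reverse_pssm(p), pep), match_score(p, rev_pep))
    }
  })
})

test_that("cutoff calibration honours the descending-rank definition", {
  proteome <- toy_proteome(list(P1 = random_sequence(800, seed = 41),
                                P2 = random_sequence(700, seed = 42)))
  withr::with_seed(10, {
    cores <- vapply(1:15, function(i)
      paste(sample(AA_ALPHABET, 5, replace = TRUE), collapse = ""), character(1))
  })
  p <- build_pssm(cores)
  # n*q = 1: the cutoff is the single highest score
  cut <- calibrate_cutoff(p, proteome, n_samples = 2000, q = 1 / 2000, seed = 6)
  scores <- attr(cut, "scores")
  expect_equal(as.numeric(cut), max(scores))
  # exceedance count matches the rank definition up to ties
  cut2 <- calibrate_cutoff(p, proteome, n_samples = 2000, q = 0.05, seed = 6)
  sc2 <- attr(cut2, "scores")
  rank_target <- floor(2000 * 0.05)
  n_ge <- sum(sc2 >= as.numeric(cut2))
  n_ties <- sum(sc2 == as.numeric(cut2))
  expect_gte(n_ge, rank_target)
  expect_lte(n_ge, rank_target + n_ties)
  # smaller q -> cutoff no smaller; determinism under the seed
  expect_gte(as.numeric(cut), as.numeric(cut2))
  expect_equal(as.numeric(calibrate_cutoff(p, proteome, 2000, 0.05, seed = 6)),
               as.numeric(cut2))
  expect_error(calibrate_cutoff(p, toy_proteome(list(S = "ACD")), 100, 0.05),
               "length >=")
})

test_that("the PSSM builder recovers a known ground-truth PWM from sampled cores", {
  bg <- load_background()
  pwm <- gen_truth_pwms(1L, motif_length = 6L, consensus_weight = 0.7,
                        bg = bg, seed = 77)[[1]]
  withr::with_seed(78, {
    cores <- vapply(1:5000, function(i) sample_pwm_instance(pwm), character(1))
  })
  p <- build_pssm(cores, bg = bg)
  probs <- sweep(2^p$scores, 2, bg, `*`)  # back-transformed probabilities
  expect_lt(max(abs(probs - pwm)), 0.03)
  expect_gt(stats::cor(as.numeric(p$scores), as.numeric(log2(pwm / matrix(bg, 6, 20, byrow = TRUE)))),
            0.95)
})

test_that("per-E3 motif selection maximises substrate recall with shortest-length ties", {
  bg <- load_background()
  pwm <- gen_truth_pwms(1L, motif_length = 6L, consensus_weight = 0.9,
                        bg = bg, seed = 55)[[1]]
  proteome <- toy_proteome(stats::setNames(
    lapply(1:40, function(i) random_sequence(300, seed = 500 + i)),
    paste0("BG", 1:40)))
  withr::with_seed(56, {
    sp <- lapply(1:30, function(i) {
      flank <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE, prob = bg),
                                 collapse = "")
      paste0(flank(3), sample_pwm_instance(pwm), flank(3))
    })
    names(sp) <- paste0("SUB", 1:30)
  })
  sel <- build_e3_motif("E3X", sp, proteome, n_samples = 2e4, iterations = 40L,
                        seed = 5L, bg = bg)
  tab <- attr(sel, "selection")
  expect_gte(sel$recall, max(tab$recall[tab$m != sel$m]))
  # the implanted consensus should dominate the selected PSSM columns
  cons <- attr(pwm, "consensus")
  sel_cons <- paste(AA_ALPHABET[apply(sel$scores, 1, which.max)], collapse = "")
  expect_true(grepl(substr(cons, 2, 5), sel_cons, fixed = TRUE) ||
                grepl(substr(sel_cons, 2, min(5, sel$m)), cons, fixed = TRUE))
  # a recall tie across lengths resolves to the shortest motif
  recalls <- c(`5` = 0.8, `6` = 0.8, `7` = 0.5)
  expect_equal(names(recalls)[which.max(recalls)], "5")
})

test_that("PSSM JSON and MEME exports round-trip and agree", {
  withr::with_seed(12, {
    cores <- vapply(1:12, function(i)
      paste(sample(AA_ALPHABET, 5, replace = TRUE), collapse = ""), character(1))
  })
  p <- build_pssm(cores, e3 = "E3Z")
  p$cutoff <- 3.21
  path <- tempfile(fileext = ".json")
  write_pssm(p, path)
  back <- read_pssm(path)
  expect_equal(back$scores, p$scores, ignore_attr = TRUE)
  expect_equal(back$cutoff, p$cutoff)
  expect_equal(back$e3, "E3Z")

  meme <- tempfile(fileext = ".txt")
  write_meme_motif(p, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("MOTIF E3Z", lines)))
  grid <- read.table(text = lines[(which(grepl("letter-probability", lines)) + 1):length(lines)])
  expect_equal(rowSums(as.matrix(grid)), rep(1, 5), tolerance = 1e-4)
})
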