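# Seeded synthetic-data generators: background proteomes, ground-truth
# motif PWMs with implanted degron instances, matching E3-substrate
# tables, mutation tables with controllable degron enrichment, and
# reference-shaped degron/ESI fixtures. Everything is fully determined by
# (parameters, seed).

#' Generate a background proteome
#'
#' Protein lengths are Gamma-distributed (shape 16, mean `mean_length`,
#' floor 50) and residues are i.i.d. draws from the background
#' frequencies.
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean protein length (default 400).
#' @param bg Background frequencies (default the bundled human table).
#' @param seed Integer seed.
#' @param prefix Accession prefix (default `"SYNP"`).
#' @return Named list of protein records.
#' @export
gen_proteome <- function(n_proteins, mean_length = 400, bg = load_background(),
                         seed = 1L, prefix = "SYNP") {
  if (n_proteins == 0L) return(stats::setNames(list(), character(0)))
  withr::with_seed(seed, {
    lens <- pmax(50L, as.integer(round(stats::rgamma(n_proteins, shape = 16,
                                                     scale = mean_length / 16))))
    prot <- lapply(seq_len(n_proteins), function(i) {
      seqchars <- sample(AA_ALPHABET, lens[i], replace = TRUE, prob = bg)
      protein_record(sprintf("%s%04d", prefix, i), paste(seqchars, collapse = ""))
    })
    stats::setNames(prot, vapply(prot, `[[`, character(1), "accession"))
  })
}

#' Ground-truth motif PWMs for synthetic E3s
#'
#' Each E3 gets a position weight matrix of length `motif_length`: a
#' random consensus letter per position carrying `consensus_weight`
#' probability, the remainder spread over the other letters in
#' proportion to background. Sharp (information-rich) motifs by default,
#' so ground-truth recovery is identifiable.
#'
#' @param n_e3 Number of synthetic E3s.
#' @param motif_length Motif length (default 6).
#' @param consensus_weight Probability of the consensus letter per
#'   position (default 0.85).
#' @param bg Background frequencies.
#' @param seed Integer seed.
#' @return Named list (E3 accession -> m x 20 probability matrix with a
#'   `"consensus"` attribute).
#' @export
gen_truth_pwms <- function(n_e3 = 3L, motif_length = 6L, consensus_weight = 0.85,
                           bg = load_background(), seed = 1L) {
  withr::with_seed(seed, {
    pwms <- lapply(seq_len(n_e3), function(e) {
      cons <- sample(AA_ALPHABET, motif_length, replace = TRUE)
      pwm <- matrix(0, motif_length, 20L, dimnames = list(NULL, AA_ALPHABET))
      for (i in seq_len(motif_length)) {
        rest <- bg
        rest[cons[i]] <- 0
        pwm[i, ] <- (1 - consensus_weight) * rest / sum(rest)
        pwm[i, cons[i]] <- pwm[i, cons[i]] + consensus_weight
      }
      attr(pwm, "consensus") <- paste(cons, collapse = "")
      pwm
    })
    stats::setNames(pwms, sprintf("SYNE3_%d", seq_len(n_e3)))
  })
}

#' Sample one instance from a PWM
#'
#' @param pwm m x 20 probability matrix.
#' @return Peptide string of length m.
#' @export
sample_pwm_instance <- function(pwm) {
  paste(vapply(seq_len(nrow(pwm)), function(i)
    sample(AA_ALPHABET, 1L, prob = pwm[i, ]), character(1)), collapse = "")
}

#' Implant degron instances into a proteome
#'
#' Draws instances column-wise from the ground-truth PWMs and overwrites
#' background residues at uniformly chosen positions, at most
#' `instances_per_protein` non-overlapping instances per carrier
#' protein. E3s are assigned to carriers in rotation, so instance counts
#' per E3 are balanced.
#'
#' @param proteome Named protein-record list (background).
#' @param pwms Named PWM list from [gen_truth_pwms].
#' @param n_instances Total instances to implant.
#' @param instances_per_protein Maximum per carrier (default 1).
#' @param seed Integer seed.
#' @return `list(proteome, truth)`: the modified proteome and a
#'   `data.frame(protein_accession, start, end, e3, sequence)` of
#'   implanted instances.
#' @export
implant_degrons <- function(proteome, pwms, n_instances,
                            instances_per_protein = 1L, seed = 1L) {
  if (n_instances == 0L) {
    return(list(proteome = proteome,
                truth = data.frame(protein_accession = character(),
                                   start = integer(), end = integer(),
                                   e3 = character(), sequence = character())))
  }
  m <- nrow(pwms[[1]])
  withr::with_seed(seed, {
    n_carriers <- ceiling(n_instances / instances_per_protein)
    if (n_carriers > length(proteome)) stop("not enough proteins to carry the implants")
    carriers <- sample(names(proteome), n_carriers)
    rows <- list()
    e3_cycle <- rep_len(names(pwms), n_instances)
    inst <- 0L
    for (acc in carriers) {
      p <- proteome[[acc]]
      taken <- cbind(start = integer(0), end = integer(0))
      for (j in seq_len(instances_per_protein)) {
        if (inst >= n_instances) break
        # rejection-sample a non-overlapping start
        ok <- FALSE
        for (try in seq_len(200L)) {
          s <- sample.int(p$length - m + 1L, 1L)
          if (!any(s <= taken[, 2] + m - 1L & s + m - 1L >= taken[, 1])) { ok <- TRUE; break }
        }
        if (!ok) break
        inst <- inst + 1L
        e3 <- e3_cycle[inst]
        pep <- sample_pwm_instance(pwms[[e3]])
        substr(p$sequence, s, s + m - 1L) <- pep
        taken <- rbind(taken, c(s, s + m - 1L))
        rows[[inst]] <- data.frame(protein_accession = acc, start = s,
                                   end = s + m - 1L, e3 = e3, sequence = pep)
      }
      proteome[[acc]] <- protein_record(acc, p$sequence)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(proteome = proteome, truth = truth)
  })
}

#' Synthetic ESI table from implant ground truth
#'
#' One `known` edge per implanted (E3, protein) pair plus a stated
#' fraction of spurious edges to non-carrier proteins.
#'
#' @param truth Implant table from [implant_degrons].
#' @param proteome Named protein-record list (source of noise substrates).
#' @param noise Fraction of extra spurious edges (default 0).
#' @param seed Integer seed.
#' @return ESI `data.frame(e3, substrate, evidence)`.
#' @export
gen_esi_table <- function(truth, proteome, noise = 0, seed = 1L) {
  real <- unique(truth[c("e3", "protein_accession")])
  edges <- data.frame(e3 = real$e3, substrate = real$protein_accession,
                      evidence = "known", stringsAsFactors = FALSE)
  n_noise <- as.integer(round(nrow(edges) * noise))
  if (n_noise > 0L) {
    withr::with_seed(seed, {
      free <- setdiff(names(proteome), truth$protein_accession)
      if (length(free) < n_noise) stop("not enough non-carrier proteins for noise edges")
      noise_edges <- data.frame(
        e3 = sample(unique(truth$e3), n_noise, replace = TRUE),
        substrate = sample(free, n_noise),
        evidence = "high_throughput", stringsAsFactors = FALSE)
      edges <- rbind(edges, noise_edges)
    })
  }
  rownames(edges) <- NULL
  edges
}

#' Random background peptides from a proteome
#'
#' `ceiling(L / 1000)` uniformly placed windows of `len` residues per
#' protein — the background peptide sample used for property baselines.
#'
#' @param proteome Named protein-record list.
#' @param len Peptide length (default 10).
#' @param seed Integer seed.
#' @return Character vector of peptides.
#' @export
sample_background_peptides <- function(proteome, len = 10L, seed = 1L) {
  withr::with_seed(seed, {
    unlist(lapply(proteome, function(p) {
      if (p$length < len) return(character(0))
      k <- ceiling(p$length / 1000)
      starts <- sample.int(p$length - len + 1L, k, replace = TRUE)
      vapply(starts, function(s) .subseq(p, s, s + len - 1L), character(1))
    }), use.names = FALSE)
  })
}

#' Synthetic mutation table with controllable degron enrichment
#'
#' Mutation positions are drawn with probability weight `r` inside
#' degron-related regions (implant intervals plus `flank` residues each
#' side) and weight 1 elsewhere; `r = 1` is the uniform null. The
#' reference residue always matches the sequence; the alternate is
#' uniform over the other 19; samples are drawn from a pool of
#' `n_samples` tumour identifiers.
#'
#' @param proteome Named protein-record list.
#' @param truth Implant table (degron ground truth).
#' @param r Relative risk inside degron-related regions (default 1).
#' @param n_mutations Number of mutation records.
#' @param flank Related-region flank (default 10).
#' @param n_samples Tumour sample pool size (default 200).
#' @param cancer_type Label for all records (default `"SYNTH"`).
#' @param seed Integer seed.
#' @return Mutation `data.frame`.
#' @export
gen_mutation_table <- function(proteome, truth, r = 1, n_mutations = 1000L,
                               flank = 10L, n_samples = 200L,
                               cancer_type = "SYNTH", seed = 1L) {
  accs <- names(proteome)
  lens <- vapply(proteome, `[[`, integer(1), "length")
  offs <- cumsum(c(0L, utils::head(lens, -1L)))
  names(offs) <- accs
  total <- sum(lens)

  # per-residue weights: r inside related regions, 1 elsewhere
  wts <- rep(1, total)
  if (nrow(truth) && r != 1) {
    for (i in seq_len(nrow(truth))) {
      acc <- truth$protein_accession[i]
      lo <- max(1L, truth$start[i] - flank)
      hi <- min(lens[[acc]], truth$end[i] + flank)
      wts[offs[[acc]] + (lo:hi)] <- r
    }
  }
  withr::with_seed(seed, {
    gpos <- sample.int(total, n_mutations, replace = TRUE, prob = wts)
    pidx <- findInterval(gpos - 1L, unname(offs))
    acc <- accs[pidx]
    pos <- gpos - unname(offs)[pidx]
    ref <- vapply(seq_len(n_mutations), function(i)
      .subseq(proteome[[acc[i]]], pos[i], pos[i]), character(1))
    alt <- vapply(ref, function(a) sample(setdiff(AA_ALPHABET, a), 1L), character(1))
    data.frame(protein_accession = acc, position = pos, ref_aa = ref,
               alt_aa = unname(alt),
               sample_id = sprintf("S%04d", sample.int(n_samples, n_mutations,
                                                       replace = TRUE)),
               cancer_type = cancer_type, stringsAsFactors = FALSE)
  })
}

#' Default synthetic degron study
#'
#' The package's standard simulation: a background proteome of 300
#' proteins (mean length 400), 3 synthetic E3s with sharp length-6
#' motifs, and 150 implanted degron instances (one per carrier protein)
#' with a matching known-evidence ESI table. Sized to train the one-hot
#' scorer in minutes on one CPU while leaving enough instances per E3
#' for motif recovery.
#'
#' @param seed Integer seed driving every stage.
#' @param n_proteins,mean_length,n_e3,motif_length,n_instances,consensus_weight
#'   Generator parameters (see the individual generators).
#' @return `list(proteome, truth, pwms, esis, background)`.
#' @export
simulate_degron_study <- function(seed = 1L, n_proteins = 300L, mean_length = 400,
                                  n_e3 = 3L, motif_length = 6L,
                                  n_instances = 150L, consensus_weight = 0.85) {
  bg <- load_background()
  proteome <- gen_proteome(n_proteins, mean_length, bg, seed = seed)
  pwms <- gen_truth_pwms(n_e3, motif_length, consensus_weight, bg, seed = seed + 1L)
  imp <- implant_degrons(proteome, pwms, n_instances, seed = seed + 2L)
  esis <- gen_esi_table(imp$truth, imp$proteome, noise = 0, seed = seed + 3L)
  list(proteome = imp$proteome, truth = imp$truth, pwms = pwms,
       esis = esis, background = bg)
}

#' Synthetic stand-in for the curated degron collection
#'
#' Emits a synthetic degron table with the published shape of the
#' curated collection — 303 degrons of 3-10 residues on canonical
#' proteins — together with its host proteome. The sequences are
#' simulated, not the real collection; only the table's shape and
#' dialect match.
#'
#' @param seed Integer seed.
#' @param n_degrons Number of degrons (default 303).
#' @return `list(proteome, degrons)`.
#' @export
gen_reference_degron_table <- function(seed = 1L, n_degrons = 303L) {
  bg <- load_background()
  proteome <- gen_proteome(n_degrons, mean_length = 300, bg, seed = seed,
                           prefix = "SYNDEG")
  withr::with_seed(seed + 1L, {
    lens <- sample(3:10, n_degrons, replace = TRUE,
                   prob = c(.05, .05, .25, .25, .2, .1, .05, .05))
    src <- sample(c("ELM", "study1", "study2", "study3"), n_degrons, replace = TRUE,
                  prob = c(.5, .2, .2, .1))
    rows <- lapply(seq_len(n_degrons), function(i) {
      p <- proteome[[i]]
      s <- sample.int(p$length - lens[i] + 1L, 1L)
      data.frame(protein_accession = p$accession, start = s,
                 end = s + lens[i] - 1L,
                 sequence = .subseq(p, s, s + lens[i] - 1L),
                 source = src[i], e3 = "", stringsAsFactors = FALSE)
    })
  })
  list(proteome = proteome, degrons = do.call(rbind, rows))
}

#' Synthetic stand-in for the collected ESI dataset
#'
#' Deterministically constructs an interaction table with the published
#' shape of the curated ESI collection: 3766 nonredundant edges between
#' 307 E3s and 2713 substrates, of which exactly 55 E3s have at least 10
#' substrates. Accessions are synthetic.
#'
#' @return ESI `data.frame(e3, substrate, evidence)`.
#' @export
gen_reference_esi_table <- function() {
  # 252 small E3s with 1..9 substrates (28 cycles of 1..9 = 1260 edges)
  # and 55 large E3s sharing the remaining 2506 edges (31 x 46 + 24 x 45)
  small_sizes <- rep(1:9, 28)
  large_sizes <- c(rep(46L, 31), rep(45L, 24))
  sizes <- c(large_sizes, small_sizes)
  e3s <- sprintf("SYNE%03d", seq_along(sizes))
  n_sub <- 2713L
  subs <- sprintf("SYNS%04d", seq_len(n_sub))

  cursor <- 0L
  rows <- lapply(seq_along(sizes), function(i) {
    take <- ((cursor + seq_len(sizes[i]) - 1L) %% n_sub) + 1L
    cursor <<- cursor + sizes[i]
    ev <- if (sizes[i] >= 10L) {
      c(rep("known", 12L), rep("high_throughput", sizes[i] - 12L))
    } else rep("known", sizes[i])
    data.frame(e3 = e3s[i], substrate = subs[take], evidence = ev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an ESI table to TSV
#'
#' @param esis ESI `data.frame`.
#' @param path Output path.
#' @export
write_esi_table <- function(esis, path) {
  utils::write.table(esis, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a degron table to TSV
#'
#' @param degrons Degron `data.frame`.
#' @param path Output path.
#' @export
write_degron_table <- function(degrons, path) {
  utils::write.table(degrons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
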