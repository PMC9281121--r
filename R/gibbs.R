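# Gibbs-sampling alignment of variable-length peptides into K clusters of
# fixed-length cores plus a trash cluster for outliers. Core scoring is the
# same +1-pseudocount base-2 log-odds used by the PSSM builder, so the
# alignment and motif stages share one scoring convention.

# peptide codes (integer vector), cluster log-odds L (m x 20):
# score of every legal offset
.offset_scores <- function(codes, L, m) {
  n_off <- length(codes) - m + 1L
  vapply(seq_len(n_off), function(o)
    sum(L[cbind(seq_len(m), codes[o:(o + m - 1L)])]), numeric(1))
}

# counts (m x 20) and size -> log2 odds matrix vs background
.logodds <- function(counts, size, bg) {
  log2((counts + 1) / (size + 20)) - matrix(log2(bg), nrow(counts), 20, byrow = TRUE)
}

# cluster counts from member cores
.core_counts <- function(codes_list, offsets, members, m) {
  counts <- matrix(0L, m, 20L)
  for (i in members) {
    core <- codes_list[[i]][offsets[i]:(offsets[i] + m - 1L)]
    counts[cbind(seq_len(m), core)] <- counts[cbind(seq_len(m), core)] + 1L
  }
  counts
}

# total objective: sum of member core scores against their own cluster's
# pseudocount log-odds (all members included in the counts)
.gibbs_objective <- function(codes_list, assignments, offsets, K, m, bg) {
  total <- 0
  for (k in seq_len(K)) {
    members <- which(!is.na(assignments) & assignments == k)
    if (!length(members)) next
    counts <- .core_counts(codes_list, offsets, members, m)
    L <- .logodds(counts, length(members), bg)
    for (i in members) {
      core <- codes_list[[i]][offsets[i]:(offsets[i] + m - 1L)]
      total <- total + sum(L[cbind(seq_len(m), core)])
    }
  }
  total
}

#' Gibbs alignment of peptides into clusters of fixed-length cores
#'
#' Samples (cluster, core offset) jointly for each peptide from the
#' conditional given all other peptides' current cores, scoring a
#' candidate core by its +1-pseudocount base-2 log-odds against the
#' cluster's leave-one-out residue counts versus background. The sampler
#' anneals linearly from `temp0` to `temp1` over `iterations` sweeps and
#' finishes with a deterministic hill-climb in which a move is accepted
#' only if it increases the total alignment objective. A peptide whose
#' best achievable core score (in bits) stays below `trash_threshold`
#' lands in the trash cluster and contributes nothing to any profile.
#'
#' @param peptides Character vector of peptides, each of length >= `m`.
#' @param K Number of clusters.
#' @param m Core (motif) length.
#' @param trash_threshold Bits; outlier sink threshold (default 4).
#' @param iterations Annealed sweeps (default 100).
#' @param seed Integer seed; identical inputs and seed give identical
#'   solutions.
#' @param bg Background frequencies (default the bundled human table).
#' @param temp0,temp1 Annealing start/end temperatures.
#' @return Object of class `gibbs_solution`: `assignments` (integer or
#'   `NA` for trash), `offsets` (1-based core starts; `NA` for trash),
#'   `m`, `K`, `peptides`, `objective`, `trash_threshold`, `seed`.
#' @export
cluster_cores <- function(peptides, K, m, trash_threshold = 4, iterations = 100L,
                          seed = 1L, bg = load_background(),
                          temp0 = 1.5, temp1 = 0.1) {
  stopifnot(K >= 1L, m >= 1L)
  too_short <- nchar(peptides) < m
  if (any(too_short)) {
    stop("peptides shorter than the core length ", m, ": ",
         paste(utils::head(which(too_short), 10L), collapse = ", "))
  }
  n <- length(peptides)
  codes_list <- lapply(peptides, .window_codes)
  if (any(vapply(codes_list, function(x) any(x == 0L), logical(1)))) {
    stop("peptides entering alignment must not contain 'X'")
  }

  withr::with_seed(seed, {
    n_off <- nchar(peptides) - m + 1L
    assignments <- sample.int(K, n, replace = TRUE)
    offsets <- vapply(n_off, function(k) sample.int(k, 1L), integer(1))

    counts <- lapply(seq_len(K), function(k)
      .core_counts(codes_list, offsets, which(assignments == k), m))
    sizes <- tabulate(assignments, K)

    remove_pep <- function(i) {
      k <- assignments[i]
      if (is.na(k)) return(invisible())
      core <- codes_list[[i]][offsets[i]:(offsets[i] + m - 1L)]
      idx <- cbind(seq_len(m), core)
      counts[[k]][idx] <<- counts[[k]][idx] - 1L
      sizes[k] <<- sizes[k] - 1L
      assignments[i] <<- NA_integer_
    }
    add_pep <- function(i, k, o) {
      core <- codes_list[[i]][o:(o + m - 1L)]
      idx <- cbind(seq_len(m), core)
      counts[[k]][idx] <<- counts[[k]][idx] + 1L
      sizes[k] <<- sizes[k] + 1L
      assignments[i] <<- k
      offsets[i] <<- o
    }

    candidate_scores <- function(i) {
      lapply(seq_len(K), function(k) {
        L <- .logodds(counts[[k]], sizes[k], bg)
        .offset_scores(codes_list[[i]], L, m)
      })
    }

    # annealed sampling sweeps
    temps <- seq(temp0, temp1, length.out = max(iterations, 2L))
    for (sweep in seq_len(iterations)) {
      temp <- temps[sweep]
      for (i in seq_len(n)) {
        remove_pep(i)
        sc <- candidate_scores(i)
        best <- max(unlist(sc))
        if (best < trash_threshold) next  # stays in trash
        flat <- unlist(sc)
        w <- exp(log(2) * (flat - best) / temp)
        pick <- sample.int(length(flat), 1L, prob = w)
        k <- findInterval(pick - 1L, cumsum(c(0L, lengths(sc)))[seq_len(K)],
                          left.open = FALSE)
        o <- pick - cumsum(c(0L, lengths(sc)))[k]
        add_pep(i, k, o)
      }
    }

    # deterministic hill-climb: accept only objective-increasing moves
    obj <- .gibbs_objective(codes_list, assignments, offsets, K, m, bg)
    for (pass in seq_len(20L)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        cur_k <- assignments[i]; cur_o <- offsets[i]
        remove_pep(i)
        sc <- candidate_scores(i)
        best <- max(unlist(sc))
        if (best < trash_threshold) {
          cand_k <- NA_integer_
        } else {
          flat <- unlist(sc)
          pick <- which.max(flat)
          cand_k <- findInterval(pick - 1L, cumsum(c(0L, lengths(sc)))[seq_len(K)])
          cand_o <- pick - cumsum(c(0L, lengths(sc)))[cand_k]
        }
        if (!is.na(cand_k)) add_pep(i, cand_k, cand_o)
        new_obj <- .gibbs_objective(codes_list, assignments, offsets, K, m, bg)
        same <- identical(cand_k, cur_k) && (is.na(cand_k) || cand_o == cur_o)
        if (!same && new_obj > obj) {
          obj <- new_obj
          changed <- TRUE
        } else if (!same) {
          # revert
          if (!is.na(assignments[i])) remove_pep(i)
          if (!is.na(cur_k)) add_pep(i, cur_k, cur_o)
        } else {
          obj <- new_obj
        }
      }
      if (!changed) break
    }

    structure(list(assignments = assignments, offsets = ifelse(is.na(assignments), NA_integer_, offsets),
                   m = m, K = K, peptides = peptides, objective = obj,
                   trash_threshold = trash_threshold, background = bg, seed = seed),
              class = "gibbs_solution")
  })
}

#' Recompute the trash set on a frozen solution
#'
#' Scores every peptide's best core against the fixed cluster profiles
#' built from the solution's current non-trash members and flags those
#' whose best score falls below `threshold`. Raising the threshold can
#' only grow the flagged set.
#'
#' @param solution A `gibbs_solution`.
#' @param threshold Bits.
#' @return Logical vector, `TRUE` = trash at this threshold.
#' @export
gibbs_trash_pass <- function(solution, threshold = solution$trash_threshold) {
  codes_list <- lapply(solution$peptides, .window_codes)
  m <- solution$m
  profiles <- lapply(seq_len(solution$K), function(k) {
    members <- which(!is.na(solution$assignments) & solution$assignments == k)
    .logodds(.core_counts(codes_list, solution$offsets, members, m),
             length(members), solution$background)
  })
  vapply(seq_along(codes_list), function(i) {
    best <- max(vapply(profiles, function(L)
      max(.offset_scores(codes_list[[i]], L, m)), numeric(1)))
    best < threshold
  }, logical(1))
}

#' Alignment cores of one cluster
#'
#' @param solution A `gibbs_solution`.
#' @param cluster_id Cluster to extract (trash excluded).
#' @return Character vector of `m`-length cores, one per member.
#' @export
alignment_cores <- function(solution, cluster_id) {
  members <- which(!is.na(solution$assignments) &
                     solution$assignments == cluster_id)
  if (!length(members)) stop("cluster ", cluster_id, " is empty")
  vapply(members, function(i)
    substr(solution$peptides[i], solution$offsets[i],
           solution$offsets[i] + solution$m - 1L), character(1))
}

#' @export
print.gibbs_solution <- function(x, ...) {
  n_trash <- sum(is.na(x$assignments))
  cat(sprintf("Gibbs core alignment: %d peptides, K=%d, core length %d\n",
              length(x$peptides), x$K, x$m))
  cat(sprintf("  cluster sizes: %s; trash: %d; objective %.2f bits\n",
              paste(tabulate(x$assignments, x$K), collapse = ", "),
              n_trash, x$objective))
  invisible(x)
}
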