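#' @name duplication_cluster
#' @title Iterative HMM-HMM clustering into duplication groups
#'
#' @description
#' The clustering core: every input sequence starts as its own
#' single-sequence profile HMM; all pairs are scored by local HMM-HMM
#' alignment and calibrated E-values; the best (lowest-E) pair below the
#' cutoff is merged, its members realigned along the winning alignment path,
#' the group HMM rebuilt, and the procedure repeated until no pair qualifies.
#' Tight clusters under a stringent cutoff (default E < 1e-20) are read as
#' products of gene duplication. A UPGMA relationship tree over the final
#' groups and singlets summarises between-group similarity.
NULL

#' Cluster sequences into duplication groups
#'
#' @param seqs a `seq_set` of protein sequences (>= 1, unique ids).
#' @param cutoff merge E-value threshold; a pair merges only when its
#'   symmetrised E-value is strictly below this (default 1e-20).
#' @param seed integer seed driving decoy shuffles; the partition is a pure
#'   function of the inputs and this seed, and is invariant to input order.
#' @param pseudocount_weight emission pseudocount for [build_profile_hmm()];
#'   the clustering default (0.5) is sharper than the construction default
#'   so that single-sequence profiles retain discriminative emissions.
#' @param transition_pseudocount transition smoothing for
#'   [build_profile_hmm()]; the clustering default (0.1) keeps observed
#'   match-match transitions near 1 for small alignments, where add-one
#'   smoothing would cost ~2 bits per aligned column and drown the
#'   co-emission signal.
#' @param n_decoys decoy alignments pooled for the extreme-value
#'   calibration (>= 50 required by the fit).
#' @param recalibrate_each_iteration if TRUE, regenerate the decoy pool and
#'   refit the Gumbel location/scale after every merge; the default FALSE
#'   fits location/scale once from the initial single-sequence decoy pool
#'   and refreshes only the comparison-set size N each iteration. Merge
#'   ordering is identical either way (E is monotone in score for fixed
#'   parameters); only the reported E-values differ slightly.
#' @param single_pass logical; if TRUE, merge decisions use only the initial
#'   all-vs-all matrix of single-sequence HMM E-values (minimum linkage
#'   between groups) with no per-merge recalibration; group alignments are
#'   still built progressively.
#' @param verbose print merge progress.
#' @return A `grouping_result`: list with `groups` (>= 2 members),
#'   `singlets`, `tree` (a `dup_tree`), `cutoff`, `merge_log` (data.frame
#'   `iteration`, `merged` (comma-joined ids), `e_value`), `seq_evalues`
#'   (initial all-vs-all sequence-level E matrix), `membership` (named
#'   group label per sequence id), `report` (see [duplication_report()]).
#' @export
cluster_sequences <- function(seqs, cutoff = 1e-20, seed = 1L,
                              pseudocount_weight = 0.5,
                              transition_pseudocount = 0.1,
                              n_decoys = 100L,
                              recalibrate_each_iteration = FALSE,
                              single_pass = FALSE, verbose = FALSE) {
  stopifnot(cutoff > 0)
  if (is.null(seqs) || nrow(seqs) == 0L)
    stop("empty input: no sequences to cluster", call. = FALSE)
  if (anyDuplicated(seqs$id))
    stop("duplicate sequence ids in input", call. = FALSE)
  n <- nrow(seqs)

  mk_group <- function(id, members, aln) {
    list(group_id = id, member_ids = members, alignment = aln,
         hmm = build_profile_hmm(aln, pseudocount_weight = pseudocount_weight,
                                 transition_pseudocount =
                                   transition_pseudocount,
                                 name = id))
  }
  groups <- lapply(seq_len(n), function(k) {
    aln <- as_alignment(setNames(seqs$residues[k], seqs$id[k]))
    mk_group(seqs$id[k], seqs$id[k], aln)
  })
  canon <- function(gs) gs[order(vapply(gs, `[[`, "", "group_id"))]
  groups <- canon(groups)

  iter_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n + 1L))
  merge_log <- data.frame(iteration = integer(0), merged = character(0),
                          e_value = numeric(0), stringsAsFactors = FALSE)
  seq_evalues <- NULL
  score_mat <- NULL
  params <- NULL
  iteration <- 0L

  recalibrate <- function() {
    hmms <- lapply(groups, `[[`, "hmm")
    ds <- decoy_scores(hmms, n_decoys = n_decoys,
                       seed = iter_seeds[iteration + 1L])
    fit_evd(ds, n_comparisons = length(groups))
  }
  full_scores <- function() {
    hmms <- lapply(groups, `[[`, "hmm")
    m <- length(hmms)
    S <- matrix(NA_real_, m, m)
    if (m >= 2)
      for (i in seq_len(m - 1)) for (j in (i + 1):m)
        S[i, j] <- S[j, i] <- hmm_score(hmms[[i]], hmms[[j]])
    dimnames(S) <- rep(list(vapply(groups, `[[`, "", "group_id")), 2)
    S
  }

  if (n >= 2) {
    params <- recalibrate()
    score_mat <- full_scores()
    E0 <- score_to_evalue(score_mat, params)$e_value
    dimnames(E0) <- dimnames(score_mat)
    seq_evalues <- E0

    repeat {
      m <- length(groups)
      if (m < 2) break
      E <- if (single_pass) {
        group_min_linkage(groups, seq_evalues)
      } else {
        score_to_evalue(score_mat, params)$e_value
      }
      pick <- best_pair(E, groups)
      if (is.null(pick) || !(E[pick[1], pick[2]] < cutoff)) break
      i <- pick[1]; j <- pick[2]
      ga <- groups[[i]]; gb <- groups[[j]]
      iteration <- iteration + 1L
      ev <- E[i, j]
      if (verbose)
        message(sprintf("merge %d: %s + %s (E = %.3g)", iteration,
                        ga$group_id, gb$group_id, ev))
      pa <- align_hmms(ga$hmm, gb$hmm)
      aln <- merge_alignments(ga$alignment, gb$alignment, pa,
                              ga$hmm$match_columns, gb$hmm$match_columns)
      gid <- min(c(ga$member_ids, gb$member_ids))
      gnew <- mk_group(gid, sort(c(ga$member_ids, gb$member_ids)), aln)
      merge_log <- rbind(merge_log, data.frame(
        iteration = iteration,
        merged = paste(sort(c(ga$group_id, gb$group_id)), collapse = ","),
        e_value = ev, stringsAsFactors = FALSE))
      groups <- canon(c(groups[-c(i, j)], list(gnew)))
      if (!single_pass) {
        params <- if (recalibrate_each_iteration) recalibrate() else
          calibration_params(params$lam, params$mu,
                             n_comparisons = length(groups))
        # incremental update: only the merged group's scores change
        keep_ids <- setdiff(rownames(score_mat),
                            c(ga$group_id, gb$group_id))
        S <- score_mat[keep_ids, keep_ids, drop = FALSE]
        hmms_by_id <- setNames(lapply(groups, `[[`, "hmm"),
                               vapply(groups, `[[`, "", "group_id"))
        snew <- vapply(keep_ids, function(gid)
          hmm_score(hmms_by_id[[gid]], gnew$hmm), 0.0)
        S <- rbind(cbind(S, snew), c(snew, NA_real_))
        rownames(S)[nrow(S)] <- colnames(S)[ncol(S)] <- gnew$group_id
        ord <- order(rownames(S))
        score_mat <- S[ord, ord, drop = FALSE]
      }
    }
  }

  res <- structure(list(
    groups = Filter(function(g) length(g$member_ids) >= 2, groups),
    singlets = Filter(function(g) length(g$member_ids) == 1, groups),
    tree = NULL, cutoff = cutoff, merge_log = merge_log,
    seq_evalues = seq_evalues,
    membership = grouping_membership(groups)), class = "grouping_result")
  res$tree <- build_group_tree(res)
  res$report <- duplication_report(res)
  res
}

grouping_membership <- function(groups) {
  mem <- unlist(lapply(groups, function(g)
    setNames(rep(g$group_id, length(g$member_ids)), g$member_ids)))
  mem[order(names(mem))]
}

# group-level E = min over member-pair E from the sequence-level matrix
group_min_linkage <- function(groups, seqE) {
  m <- length(groups)
  E <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    E[i, j] <- E[j, i] <-
      min(seqE[groups[[i]]$member_ids, groups[[j]]$member_ids])
  }
  dimnames(E) <- rep(list(vapply(groups, `[[`, "", "group_id")), 2)
  E
}

# lowest-E pair; ties broken lexicographically by the pair's member ids
best_pair <- function(E, groups) {
  m <- nrow(E)
  best <- NULL; bestE <- Inf; bestkey <- NULL
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    e <- E[i, j]
    ids <- sort(c(min(groups[[i]]$member_ids), min(groups[[j]]$member_ids)))
    key <- paste(ids, collapse = "\r")
    if (e < bestE || (e == bestE && key < bestkey)) {
      bestE <- e; best <- c(i, j); bestkey <- key
    }
  }
  best
}

#' Merge two group alignments along an HMM-HMM alignment path
#'
#' Columns paired by MM path elements are stacked; unpaired match columns
#' and insert columns are carried through against gaps, so every member row
#' of the merged alignment spells its original ungapped sequence.
#'
#' @param alnA,alnB `msa` objects of the two groups.
#' @param pa `pair_alignment` between the two group HMMs.
#' @param mcA,mcB the HMMs' `match_columns` (alignment column index per
#'   match state).
#' @return merged `msa` with rows of `alnA` then `alnB`.
#' @export
merge_alignments <- function(alnA, alnB, pa, mcA, mcB) {
  mA <- alignment_matrix(alnA); mB <- alignment_matrix(alnB)
  na_ <- nrow(mA); nb_ <- nrow(mB)
  gapA <- rep("-", na_); gapB <- rep("-", nb_)
  cols <- vector("list", ncol(mA) + ncol(mB))
  nc <- 0L
  lastA <- 0L; lastB <- 0L
  emitA <- function(to) {
    while (lastA < to) {
      lastA <<- lastA + 1L; nc <<- nc + 1L
      cols[[nc]] <<- c(mA[, lastA], gapB)
    }
  }
  emitB <- function(to) {
    while (lastB < to) {
      lastB <<- lastB + 1L; nc <<- nc + 1L
      cols[[nc]] <<- c(gapA, mB[, lastB])
    }
  }
  p <- pa$path
  for (r in seq_len(nrow(p))) {
    st <- p$state[r]
    if (st == "MM") {
      emitA(mcA[p$i[r]] - 1L); emitB(mcB[p$j[r]] - 1L)
      lastA <- lastA + 1L; lastB <- lastB + 1L; nc <- nc + 1L
      cols[[nc]] <- c(mA[, lastA], mB[, lastB])
    } else if (st %in% c("MI", "DG")) {
      emitA(mcA[p$i[r]])
    } else {  # IM, GD
      emitB(mcB[p$j[r]])
    }
  }
  emitA(ncol(mA)); emitB(ncol(mB))
  m <- do.call(cbind, cols[seq_len(nc)])
  as_alignment(setNames(apply(m, 1, paste, collapse = ""),
                        c(alnA$ids, alnB$ids)))
}

#' UPGMA relationship tree over groups and singlets
#'
#' Between-group distance is the minimum member-pair E-value from the initial
#' sequence-level all-vs-all matrix, transformed as
#' `d = -log10(max(E, 1e-300))` and rescaled to the similarity distance
#' `d' = 300 - d` (0 for maximal similarity).
#'
#' @param result a `grouping_result`.
#' @return a `dup_tree` with one leaf per group/singlet id.
#' @export
build_group_tree <- function(result) {
  units <- c(result$groups, result$singlets)
  labs <- vapply(units, `[[`, "", "group_id")
  if (length(units) == 1L) return(tree_leaf(labs))
  m <- length(units)
  D <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    E <- min(result$seq_evalues[units[[i]]$member_ids,
                                units[[j]]$member_ids])
    D[i, j] <- D[j, i] <- 300 - (-log10(max(E, 1e-300)))
  }
  upgma(D)
}

#' UPGMA (average linkage, ultrametric) tree from a distance matrix
#'
#' @param D symmetric distance matrix with dimnames = leaf labels.
#' @return a `dup_tree`; node heights are half the merge distance. Ties are
#'   broken lexicographically by the pair's smallest leaf labels.
#' @export
upgma <- function(D) {
  labs <- rownames(D)
  nodes <- lapply(labs, tree_leaf)
  sizes <- rep(1L, length(labs))
  keys <- labs  # smallest leaf label per active node
  while (length(nodes) > 1L) {
    m <- length(nodes)
    bi <- bj <- NULL; bd <- Inf; bk <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      k <- paste(sort(c(keys[i], keys[j])), collapse = "\r")
      if (D[i, j] < bd || (D[i, j] == bd && k < bk)) {
        bd <- D[i, j]; bi <- i; bj <- j; bk <- k
      }
    }
    h <- bd / 2
    newnode <- tree_node(list(nodes[[bi]], nodes[[bj]]),
                         height = max(h, nodes[[bi]]$height,
                                      nodes[[bj]]$height))
    ni <- sizes[bi]; nj <- sizes[bj]
    dnew <- (ni * D[bi, ] + nj * D[bj, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
    sizes <- c(sizes[keep], ni + nj)
    keys <- c(keys[keep], min(keys[c(bi, bj)]))
  }
  nodes[[1]]
}

round_half_up <- function(x) floor(x + 0.5)

#' Summarise a grouping into the headline duplication ratios
#'
#' @param result a `grouping_result` (or the output of [as_grouping()]).
#' @param detected_ids optional character vector of sequence ids detected in
#'   the proteome, for the overlap percentages.
#' @return list with `n_total`, `n_groups`, `n_in_groups`, `n_singlets`,
#'   `fraction_pct` (whole-percent share of sequences in >= 2-member
#'   groups); with `detected_ids` also `n_detected`, `detected_pct`
#'   (of total), `n_detected_in_groups`, `detected_from_groups_pct`
#'   (of detected).
#' @export
duplication_report <- function(result, detected_ids = NULL) {
  sizes_g <- vapply(result$groups, function(g) length(g$member_ids), 0L)
  n_in_groups <- sum(sizes_g)
  n_singlets <- length(result$singlets)
  n_total <- n_in_groups + n_singlets
  out <- list(n_total = n_total, n_groups = length(result$groups),
              n_in_groups = n_in_groups, n_singlets = n_singlets,
              fraction_pct = round_half_up(100 * n_in_groups /
                                             max(n_total, 1L)))
  if (!is.null(detected_ids)) {
    grouped_ids <- unlist(lapply(result$groups, `[[`, "member_ids"))
    out$n_detected <- length(detected_ids)
    out$detected_pct <- round_half_up(100 * out$n_detected / max(n_total, 1L))
    out$n_detected_in_groups <- sum(detected_ids %in% grouped_ids)
    out$detected_from_groups_pct <-
      round_half_up(100 * out$n_detected_in_groups /
                      max(out$n_detected, 1L))
  }
  out
}

#' Build a minimal grouping from a membership vector
#'
#' Useful for reporting on an externally constructed partition (no
#' alignments or HMMs attached).
#'
#' @param membership named character vector: sequence id -> group label.
#' @return a `grouping_result` skeleton usable with [duplication_report()].
#' @export
as_grouping <- function(membership) {
  split_ids <- split(names(membership), membership)
  units <- lapply(names(split_ids), function(lab)
    list(group_id = min(split_ids[[lab]]),
         member_ids = sort(split_ids[[lab]]),
         alignment = NULL, hmm = NULL))
  structure(list(
    groups = Filter(function(g) length(g$member_ids) >= 2, units),
    singlets = Filter(function(g) length(g$member_ids) == 1, units),
    tree = NULL, cutoff = NA_real_,
    merge_log = NULL, seq_evalues = NULL,
    membership = membership[order(names(membership))]),
    class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  r <- duplication_report(x)
  cat(sprintf(
    "grouping_result: %d sequences -> %d groups (%d members, %d %%) + %d singlets\n",
    r$n_total, r$n_groups, r$n_in_groups, r$fraction_pct, r$n_singlets))
  invisible(x)
}
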