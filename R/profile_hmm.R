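#' @name profile_hmm
#' @title Position-specific profile HMMs
#'
#' @description
#' A profile HMM summarises a multiple alignment as a chain of match states
#' with per-position emission distributions and match/insert/delete
#' transitions. It is the unit compared by the HMM-HMM clustering: two
#' families are similar when their profiles align with a significant score.
NULL

TR_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a profile HMM from a multiple alignment
#'
#' Match columns are those in which strictly more than 50 % of rows carry a
#' non-gap character. Match emissions are pseudocount-smoothed weighted
#' residue frequencies; insert emissions are fixed to the background;
#' transition probabilities are estimated from the observed per-sequence
#' state paths with add-one smoothing over each state's outgoing set.
#'
#' @param alignment an `msa` (see [as_alignment()]), amino-acid residues.
#' @param pseudocount_weight strength of the background pseudocount added to
#'   match-emission counts (must be > 0; the limit towards 0 approaches raw
#'   observed frequencies).
#' @param transition_pseudocount additive smoothing applied to each allowed
#'   outgoing transition before normalisation (default 1, i.e. add-one).
#'   Small alignments with add-one smoothing get heavily flattened
#'   transitions; the clustering module deliberately uses a smaller value
#'   (see [cluster_sequences()]).
#' @param background named emission background over the 20 canonical amino
#'   acids; default uniform 1/20.
#' @param weighting `"uniform"` (default) or `"henikoff"` position-based
#'   sequence weights.
#' @param name model name.
#' @return A `profile_hmm`: list with `name`, `L`, `alphabet`,
#'   `match_emissions` (L x 20), `insert_emissions`, `transitions`
#'   ((L+1) x 7, rows = positions 0..L, columns MM, MI, MD, IM, II, DM, DD),
#'   `background`, `n_seqs`, `match_columns` (alignment column indices).
#' @details Residues outside the 20-letter alphabet (e.g. `X`) count as
#'   occupancy for the match-column rule but contribute no emission counts.
#' @export
build_profile_hmm <- function(alignment, pseudocount_weight = 1,
                              background = NULL,
                              weighting = c("uniform", "henikoff"),
                              transition_pseudocount = 1,
                              name = "hmm") {
  weighting <- match.arg(weighting)
  stopifnot(inherits(alignment, "msa"), pseudocount_weight > 0,
            transition_pseudocount > 0)
  K <- length(AA20)
  if (is.null(background)) background <- setNames(rep(1 / K, K), AA20)
  background <- background[AA20]
  if (any(is.na(background)) || any(background <= 0))
    stop("background must be strictly positive over the 20 amino acids",
         call. = FALSE)
  background <- background / sum(background)

  m <- alignment_matrix(alignment)
  n <- nrow(m); ncol_aln <- ncol(m)
  nongap <- m != "-"
  match_cols <- which(colMeans(nongap) > 0.5)
  L <- length(match_cols)
  if (L == 0L) stop("no match states", call. = FALSE)

  w <- if (weighting == "uniform") rep(1 / n, n) else henikoff_weights(m)

  em <- matrix(0, L, K, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    for (a in AA20) {
      sel <- col == a
      if (any(sel)) em[k, a] <- sum(w[sel])
    }
    tot <- sum(em[k, ])
    em[k, ] <- (em[k, ] + pseudocount_weight * background) /
      (tot + pseudocount_weight)
  }

  # transition counts from observed state paths (positions 0..L; position 0
  # is the begin state, treated as a match)
  cnt <- matrix(0, L + 1, 7, dimnames = list(NULL, TR_COLS))
  is_match_col <- logical(ncol_aln)
  is_match_col[match_cols] <- TRUE
  add_cnt <- function(p, key, amount) {
    # D->I and I->D are not modelled (plan-7 style); such steps in an
    # observed path contribute no count but still switch state
    if (key %in% TR_COLS) cnt[p, key] <<- cnt[p, key] + amount
  }
  for (s in seq_len(n)) {
    state <- "M"; pos <- 0L
    for (c in seq_len(ncol_aln)) {
      if (is_match_col[c]) {
        nxt <- if (nongap[s, c]) "M" else "D"
        add_cnt(pos + 1L, paste0(state, nxt), w[s] * n)
        state <- nxt; pos <- pos + 1L
      } else if (nongap[s, c]) {
        add_cnt(pos + 1L, paste0(state, "I"), w[s] * n)
        state <- "I"
      }
    }
    # path exits via a match-type transition to the (virtual) end state
    add_cnt(pos + 1L, paste0(state, "M"), w[s] * n)
  }

  tr <- matrix(0, L + 1, 7, dimnames = list(NULL, TR_COLS))
  for (p in seq_len(L + 1)) {
    for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
      v <- cnt[p, grp] + transition_pseudocount
      tr[p, grp] <- v / sum(v)
    }
  }

  structure(list(name = name, L = L, alphabet = AA20,
                 match_emissions = em,
                 insert_emissions = matrix(rep(background, each = L), L, K,
                                           dimnames = list(NULL, AA20)),
                 transitions = tr, background = background,
                 n_seqs = n, match_columns = match_cols),
            class = "profile_hmm")
}

# Henikoff & Henikoff position-based sequence weights (gap counts as a type).
henikoff_weights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (c in seq_len(ncol(m))) {
    col <- m[, c]
    tab <- table(col)
    r <- length(tab)
    w <- w + 1 / (r * as.numeric(tab[col]))
  }
  w / sum(w)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states, %d sequences\n",
              x$name, x$L, x$n_seqs))
  invisible(x)
}

#' Shuffle the match columns of a profile HMM
#'
#' Decoy generator for E-value calibration: the match-state columns (emission
#' rows and the per-position transition rows) are permuted uniformly at
#' random, preserving the column multiset while destroying positional order.
#'
#' @param hmm a `profile_hmm` with at least 2 match states.
#' @param seed integer seed; the permutation is a pure function of it.
#' @return a `profile_hmm` decoy.
#' @export
shuffle_hmm <- function(hmm, seed) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (hmm$L < 2L) stop("shuffle_hmm requires L >= 2", call. = FALSE)
  perm <- with_seed(seed, sample.int(hmm$L))
  out <- hmm
  out$name <- paste0(hmm$name, "_shuf")
  out$match_emissions <- hmm$match_emissions[perm, , drop = FALSE]
  # transitions out of positions 1..L follow their columns; position 0 fixed
  out$transitions[2:(hmm$L + 1), ] <-
    hmm$transitions[perm + 1L, , drop = FALSE]
  out
}
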