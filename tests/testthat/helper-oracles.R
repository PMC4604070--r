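# Independent oracles and random-instance generators shared across tests.
# These deliberately re-derive quantities by a different route than the
# package implementation (enumeration, direct summation, closed forms).

# --- random valid profile HMMs (direct construction, not via alignments) ---
random_hmm <- function(L, seed, name = "rnd") {
  set.seed(seed)
  K <- 20L
  alpha <- c("A","C","D","E","F","G","H","I","K","L",
             "M","N","P","Q","R","S","T","V","W","Y")
  rdir <- function(n) { g <- rgamma(n, shape = 0.5) + 1e-6; g / sum(g) }
  em <- t(vapply(seq_len(L), function(i) rdir(K), numeric(K)))
  colnames(em) <- alpha
  tr <- matrix(0, L + 1, 7,
               dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (p in seq_len(L + 1)) {
    tr[p, c("MM","MI","MD")] <- rdir(3)
    tr[p, c("IM","II")] <- rdir(2)
    tr[p, c("DM","DD")] <- rdir(2)
  }
  bg <- stats::setNames(rep(1 / K, K), alpha)
  structure(list(name = name, L = L, alphabet = alpha,
                 match_emissions = em,
                 insert_emissions = matrix(rep(bg, each = L), L, K,
                                           dimnames = list(NULL, alpha)),
                 transitions = tr, background = bg, n_seqs = 1L,
                 match_columns = seq_len(L)),
            class = "profile_hmm")
}

# --- brute-force local pair-HMM score by exhaustive path enumeration ------
# Pair states and step costs mirror the documented model; implemented as a
# plain recursion over all legal paths (feasible for L <= 4).
enumerate_align_score <- function(a, b) {
  La <- a$L; Lb <- b$L
  f <- unname(a$background)
  colscore <- function(i, j) {
    s <- sum(a$match_emissions[i, ] * b$match_emissions[j, ] / f)
    if (s > 0) log2(s) else -Inf
  }
  lg <- function(x) if (x > 0) log2(x) else -Inf
  tA <- a$transitions; tB <- b$transitions
  # g(state, i, j): best score of a path-suffix starting at state/(i,j),
  # required to end in an MM element
  g <- function(state, i, j) {
    if (i > La || j > Lb) return(-Inf)
    if (state == "MM") {
      here <- colscore(i, j)
      if (!is.finite(here)) return(-Inf)
      cont <- c(0,  # end the path at this MM cell
        if (i < La && j < Lb)
          lg(tA[i + 1, "MM"]) + lg(tB[j + 1, "MM"]) + g("MM", i + 1, j + 1),
        if (i < La) lg(tA[i + 1, "MM"]) + lg(tB[j + 1, "MI"]) +
          g("MI", i + 1, j),
        if (j < Lb) lg(tA[i + 1, "MI"]) + lg(tB[j + 1, "MM"]) +
          g("IM", i, j + 1),
        if (i < La) lg(tA[i + 1, "MD"]) + g("DG", i + 1, j),
        if (j < Lb) lg(tB[j + 1, "MD"]) + g("GD", i, j + 1))
      return(here + max(cont))
    }
    if (state == "MI") {
      return(max(-Inf,
        if (i < La && j < Lb)
          lg(tA[i + 1, "MM"]) + lg(tB[j + 1, "IM"]) + g("MM", i + 1, j + 1),
        if (i < La) lg(tA[i + 1, "MM"]) + lg(tB[j + 1, "II"]) +
          g("MI", i + 1, j)))
    }
    if (state == "IM") {
      return(max(-Inf,
        if (i < La && j < Lb)
          lg(tA[i + 1, "IM"]) + lg(tB[j + 1, "MM"]) + g("MM", i + 1, j + 1),
        if (j < Lb) lg(tA[i + 1, "II"]) + lg(tB[j + 1, "MM"]) +
          g("IM", i, j + 1)))
    }
    if (state == "DG") {
      return(max(-Inf,
        if (i < La && j < Lb)
          lg(tA[i + 1, "DM"]) + lg(tB[j + 1, "MM"]) + g("MM", i + 1, j + 1),
        if (i < La) lg(tA[i + 1, "DD"]) + g("DG", i + 1, j)))
    }
    # GD
    max(-Inf,
      if (i < La && j < Lb)
        lg(tA[i + 1, "MM"]) + lg(tB[j + 1, "DM"]) + g("MM", i + 1, j + 1),
      if (j < Lb) lg(tB[j + 1, "DD"]) + g("GD", i, j + 1))
  }
  best <- 0
  for (i in seq_len(La)) for (j in seq_len(Lb))
    best <- max(best, g("MM", i, j))
  best
}

# --- adjusted Rand index (closed form over the contingency table) ---------
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(length(x), 2)
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# --- direct-formula Tajima's D on a character matrix ----------------------
# Written from the published formulas, independent of the package routine
# (different data path: combn over rows, column masks via vectors).
tajima_oracle <- function(rows, drop_chars = c("-", ".", "X", "?", "*")) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- !apply(m, 2, function(cc) any(cc %in% drop_chars))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(cc) length(unique(cc)) > 1))
  prs <- utils::combn(n, 2)
  pi_hat <- mean(apply(prs, 2, function(p) sum(m[p[1], ] != m[p[2], ])))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- if (S > 0) (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
       else NA_real_
  list(S = S, pi = pi_hat, a1 = a1, D = D)
}

# --- misc -----------------------------------------------------------------
random_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

seq_set_df <- function(ids, residues) {
  structure(data.frame(id = ids, description = rep("", length(ids)),
                       residues = residues,
                       stringsAsFactors = FALSE),
            class = c("seq_set", "data.frame"))
}

rgumbel <- function(n, mu, lam) mu - log(-log(runif(n))) / lam

# planted partition labels: family members share their family label; each
# unrelated decoy is its own singleton class
planted_labels <- function(sim, ids) {
  fam <- sim$truth$family[match(ids, sim$truth$id)]
  ifelse(fam == "decoy", ids, fam)
}
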