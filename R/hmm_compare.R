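#' @name hmm_compare
#' @title Pairwise HMM-HMM alignment and E-value calibration
#'
#' @description
#' Two profile HMMs are compared by a local Viterbi dynamic program over the
#' five pair states MM, MI, IM, DG and GD (HHsearch-style). MM cells emit the
#' log2 co-emission odds of the two aligned match columns; pair-state steps
#' cost the log2 product of the two models' corresponding transition
#' probabilities. Raw bit scores are converted to P- and E-values through a
#' Gumbel (extreme-value) fit to decoy scores obtained from column-shuffled
#' models.
NULL

#' Log-odds co-emission score of two match columns
#'
#' @param q,p emission probability rows over the same alphabet.
#' @param f strictly positive background over that alphabet.
#' @return `log2(sum_a q(a) p(a) / f(a))` in bits; `-Inf` when the supports
#'   are disjoint.
#' @export
column_score <- function(q, p, f) {
  if (length(q) != length(p) || length(q) != length(f))
    stop("alphabet mismatch between emission rows and background",
         call. = FALSE)
  if (!is.null(names(q)) && !is.null(names(p)) &&
      !identical(names(q), names(p)))
    stop("alphabet mismatch: emission rows have different residue order",
         call. = FALSE)
  if (any(f <= 0)) stop("background must be strictly positive", call. = FALSE)
  s <- sum(q * p / f)
  if (s > 0) log2(s) else -Inf
}

#' Local pairwise HMM-HMM alignment
#'
#' @param a,b `profile_hmm` objects over the same alphabet and background.
#' @return A `pair_alignment`: list with `score_bits` (>= 0; 0 for the empty
#'   alignment), `path` (data.frame with `state` in MM/MI/IM/DG/GD and
#'   1-based match-state coordinates `i`, `j`), and `i_start`, `i_end`,
#'   `j_start`, `j_end` (NA when empty).
#' @details Local semantics: paths start and end in MM; MM cells are floored
#'   at zero so the alignment can restart after a non-positive prefix; the
#'   empty alignment scores 0 when no positive-scoring cell exists.
#' @export
align_hmms <- function(a, b) {
  stopifnot(inherits(a, "profile_hmm"), inherits(b, "profile_hmm"))
  if (!identical(a$alphabet, b$alphabet))
    stop("alphabet mismatch between HMMs", call. = FALSE)
  if (max(abs(a$background - b$background)) > 1e-12)
    stop("background mismatch between HMMs", call. = FALSE)
  res <- pair_hmm_align_cpp(a$match_emissions, b$match_emissions,
                            unname(a$background),
                            a$transitions, b$transitions)
  states <- c("MM", "MI", "IM", "DG", "GD")
  p <- res$path
  path <- data.frame(state = states[p[, 1] + 1L],
                     i = p[, 2], j = p[, 3], stringsAsFactors = FALSE)
  empty <- nrow(path) == 0L
  structure(list(score_bits = res$score_bits, path = path,
                 i_start = if (empty) NA_integer_ else path$i[1],
                 i_end = if (empty) NA_integer_ else path$i[nrow(path)],
                 j_start = if (empty) NA_integer_ else path$j[1],
                 j_end = if (empty) NA_integer_ else path$j[nrow(path)]),
            class = "pair_alignment")
}

# score-only fast path: skips traceback and R-side path assembly
hmm_score <- function(a, b) {
  pair_hmm_align_cpp(a$match_emissions, b$match_emissions,
                     unname(a$background), a$transitions, b$transitions,
                     score_only = TRUE)$score_bits
}

#' Calibration parameters for score-to-E-value conversion
#'
#' @param lam Gumbel scale (> 0).
#' @param mu Gumbel location.
#' @param n_comparisons comparison-set size N used in E = P * N (>= 1).
#' @return a `calibration_params` object.
#' @export
calibration_params <- function(lam, mu, n_comparisons = 1L) {
  stopifnot(lam > 0, n_comparisons >= 1)
  structure(list(lam = lam, mu = mu, n_comparisons = n_comparisons),
            class = "calibration_params")
}

#' Fit a Gumbel extreme-value distribution to decoy scores
#'
#' Maximum-likelihood fit of the Gumbel location/scale to a sample of decoy
#' alignment scores, by profile likelihood in the scale parameter.
#'
#' @param decoy_scores numeric vector of at least 50 finite scores.
#' @param n_comparisons comparison-set size stored in the result.
#' @return a `calibration_params` with `lam` (scale), `mu` (location).
#' @export
fit_evd <- function(decoy_scores, n_comparisons = 1L) {
  x <- decoy_scores[is.finite(decoy_scores)]
  if (length(x) < 50L) stop("insufficient decoys", call. = FALSE)
  if (sd(x) < 1e-12) stop("degenerate fit: decoy scores are constant",
                          call. = FALSE)
  n <- length(x); xbar <- mean(x)
  mu_hat <- function(lam) {
    z <- -lam * x
    mz <- max(z)
    -(1 / lam) * (mz + log(mean(exp(z - mz))))
  }
  prof_ll <- function(lam) {
    mu <- mu_hat(lam)
    n * log(lam) - lam * (n * xbar - n * mu) - n
  }
  lam0 <- pi / (sd(x) * sqrt(6))  # moment start
  opt <- optimize(prof_ll, interval = c(lam0 / 20, lam0 * 20),
                  maximum = TRUE, tol = 1e-10)
  lam <- opt$maximum
  calibration_params(lam = lam, mu = mu_hat(lam),
                     n_comparisons = n_comparisons)
}

#' Convert a bit score to P- and E-values
#'
#' @param score_bits alignment score in bits.
#' @param params a `calibration_params`.
#' @return list with `p_value` = 1 - exp(-exp(-lam (S - mu))) and
#'   `e_value` = p_value * n_comparisons.
#' @export
score_to_evalue <- function(score_bits, params) {
  stopifnot(inherits(params, "calibration_params"))
  y <- params$lam * (score_bits - params$mu)
  p <- -expm1(-exp(-y))  # stable for large y (p -> exp(-y))
  list(p_value = p, e_value = p * params$n_comparisons)
}

#' Compare two HMMs with symmetrised E-value
#'
#' The comparison is run in both operand orders and the better (lower)
#' E-value kept. (The alignment score is symmetric by construction, so the
#' two directions agree; both are still computed per the module contract.)
#'
#' @param a,b `profile_hmm` objects.
#' @param params `calibration_params`.
#' @return A `comparison_result`: list with `hmm_a`, `hmm_b` (names),
#'   `score_bits`, `p_value`, `e_value`.
#' @export
compare_hmms <- function(a, b, params) {
  s_ab <- align_hmms(a, b)$score_bits
  s_ba <- align_hmms(b, a)$score_bits
  s <- max(s_ab, s_ba)
  pe <- score_to_evalue(s, params)
  structure(list(hmm_a = a$name, hmm_b = b$name, score_bits = s,
                 p_value = pe$p_value, e_value = pe$e_value),
            class = "comparison_result")
}

#' Decoy score pool from column-shuffled HMMs
#'
#' Scores real models against column-shuffled copies of other models to
#' obtain a null-score sample for [fit_evd()].
#'
#' @param hmms list of `profile_hmm` (length >= 1; models of L < 2 are
#'   skipped as they cannot be shuffled).
#' @param n_decoys total number of decoy alignments (default 200).
#' @param seed integer seed.
#' @return numeric vector of decoy scores (length `n_decoys`).
#' @export
decoy_scores <- function(hmms, n_decoys = 200L, seed = 1L) {
  ok <- which(vapply(hmms, function(h) h$L >= 2L, TRUE))
  if (length(ok) == 0L) stop("no shuffleable HMMs (all L < 2)", call. = FALSE)
  with_seed(seed, {
    qi <- sample(ok, n_decoys, replace = TRUE)
    si <- sample(ok, n_decoys, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max, n_decoys)
  })
  vapply(seq_len(n_decoys), function(k) {
    hmm_score(hmms[[qi[k]]], shuffle_hmm(hmms[[si[k]]], seeds[k]))
  }, 0.0)
}

#' All-vs-all symmetrised E-value matrix
#'
#' @param hmms named list of `profile_hmm`.
#' @param params `calibration_params`.
#' @return list with `evalue` and `score` symmetric matrices (diagonal NA).
#' @export
all_vs_all <- function(hmms, params) {
  n <- length(hmms)
  nm <- vapply(hmms, function(h) h$name, "")
  E <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  S <- E
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cr <- compare_hmms(hmms[[i]], hmms[[j]], params)
        E[i, j] <- E[j, i] <- cr$e_value
        S[i, j] <- S[j, i] <- cr$score_bits
      }
    }
  }
  list(evalue = E, score = S)
}
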