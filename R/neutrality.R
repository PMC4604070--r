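#' @name neutrality
#' @title Tajima's test of neutrality per duplication group
#'
#' @description
#' Tajima's D contrasts mean pairwise diversity (pi) with the
#' Watterson estimate S/a1 of the population mutation rate. Under neutral
#' evolution E\[D\] is near 0; markedly positive values indicate an excess
#' of intermediate-frequency variants, as under balancing selection. The
#' implementation is alphabet-agnostic: any residue symbol is a discrete
#' state, so the test applies to nucleotide or amino-acid group alignments.
NULL

#' Tajima's D for an alignment
#'
#' @param alignment an `msa` with at least 3 rows.
#' @param ambiguity_chars characters that, together with gaps (`-`, `.`),
#'   disqualify a column listwise (default `X`, `?`, `*`; add `"N"` for
#'   nucleotide data).
#' @return A `tajima_result`: list with `n`, `n_sites_used`, `S`
#'   (segregating sites), `pi` (mean pairwise differences), the constants
#'   `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`, `D`, and `d_defined`
#'   (FALSE with `D = NA` when `S == 0`).
#' @details
#' With n sequences: a1 = sum_{i=1}^{n-1} 1/i, a2 = sum 1/i^2,
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2+a2), and
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)).
#' @export
tajima_d <- function(alignment, ambiguity_chars = c("X", "?", "*")) {
  stopifnot(inherits(alignment, "msa"))
  n <- alignment$n_rows
  if (n < 3) stop("group too small: Tajima's D requires n >= 3",
                  call. = FALSE)
  m <- alignment_matrix(alignment)
  excluded <- c("-", ".", ambiguity_chars)
  use <- which(apply(m, 2, function(col) !any(col %in% excluded)))
  mu <- m[, use, drop = FALSE]

  seg <- apply(mu, 2, function(col) length(unique(col)) > 1L)
  S <- sum(seg)
  # mean pairwise differences
  npairs <- n * (n - 1) / 2
  diffs <- 0
  if (ncol(mu) && n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      diffs <- diffs + sum(mu[i, ] != mu[j, ])
  }
  pi <- diffs / npairs

  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d_defined <- S > 0
  D <- if (d_defined) (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
       else NA_real_
  structure(list(n = n, n_sites_used = length(use), S = S, pi = pi,
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = e1, e2 = e2, D = D, d_defined = d_defined),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("Tajima's D: n=%d, sites=%d, S=%d, pi=%.4f, D=%s\n",
              x$n, x$n_sites_used, x$S, x$pi,
              if (x$d_defined) sprintf("%.4f", x$D) else "undefined (S=0)"))
  invisible(x)
}
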