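test_that("identical sequences form one group; empty input errors", {
  s <- random_seq(100, seed = 1)
  res <- cluster_sequences(seq_set_df(c("a", "b"), c(s, s)), seed = 1)
  expect_length(res$groups, 1)
  expect_equal(res$groups[[1]]$member_ids, c("a", "b"))
  expect_length(res$singlets, 0)
  expect_error(cluster_sequences(seq_set_df(character(0), character(0))),
               "empty input")
})

test_that("merge rule is strictly below the cutoff", {
  # drive the decision rule directly: a pair at E equal/above cutoff must
  # not merge, strictly below must
  s <- random_seq(120, seed = 2)
  seqs <- seq_set_df(c("a", "b"), c(s, s))
  res_loose <- cluster_sequences(seqs, cutoff = 1e-20, seed = 1)
  expect_length(res_loose$groups, 1)
  E_ab <- min(res_loose$merge_log$e_value)
  # rerun with a cutoff at exactly the observed E: strict '<' forbids merge
  res_eq <- cluster_sequences(seqs, cutoff = E_ab, seed = 1)
  expect_length(res_eq$groups, 0)
  expect_length(res_eq$singlets, 2)
  res_lt <- cluster_sequences(seqs, cutoff = E_ab * 1.01, seed = 1)
  expect_length(res_lt$groups, 1)
})

test_that("planted families are recovered exactly across seeds", {
  for (sd in 1:10) {
    sim <- simulate_family_set(family_sim_spec(
      n_families = 3, members_per_family = 4, ancestor_length = 120,
      substitution_prob = 0.10, n_decoys = 6, seed = sd))
    res <- cluster_sequences(sim$sequences, seed = sd)
    expect_length(res$groups, 3)
    expect_true(all(vapply(res$groups, function(g)
      length(g$member_ids), 0L) == 4))
    expect_length(res$singlets, 6)
    truth <- planted_labels(sim, names(res$membership))
    expect_equal(adjusted_rand_index(res$membership, truth), 1)
    expect_true(all(res$merge_log$e_value < res$cutoff))
  }
})

test_that("group realignment preserves member sequences and invariants", {
  sim <- simulate_family_set(family_sim_spec(
    n_families = 2, members_per_family = 4, ancestor_length = 90,
    substitution_prob = 0.12, n_decoys = 2, seed = 8))
  res <- cluster_sequences(sim$sequences, seed = 8)
  all_ids <- sort(c(unlist(lapply(res$groups, `[[`, "member_ids")),
                    unlist(lapply(res$singlets, `[[`, "member_ids"))))
  expect_identical(all_ids, sort(sim$sequences$id))  # exact partition
  for (g in res$groups) {
    expect_identical(sort(g$alignment$ids), sort(g$member_ids))
    degapped <- gsub("-", "", g$alignment$seqs)
    orig <- sim$sequences$residues[match(g$alignment$ids,
                                         sim$sequences$id)]
    expect_identical(degapped, orig)
  }
  # termination bound: at most n-1 merges
  expect_lte(nrow(res$merge_log), nrow(sim$sequences) - 1)
})

test_that("partition is invariant to input order", {
  sim <- simulate_family_set(family_sim_spec(
    n_families = 2, members_per_family = 3, ancestor_length = 100,
    substitution_prob = 0.08, n_decoys = 4, seed = 13))
  res1 <- cluster_sequences(sim$sequences, seed = 13)
  set.seed(99)
  perm <- sim$sequences[sample(nrow(sim$sequences)), ]
  res2 <- cluster_sequences(perm, seed = 13)
  expect_identical(res1$membership, res2$membership)
  expect_identical(write_newick(res1$tree), write_newick(res2$tree))
})

test_that("single-pass mode clusters from the initial matrix", {
  sim <- simulate_family_set(family_sim_spec(
    n_families = 2, members_per_family = 3, ancestor_length = 100,
    substitution_prob = 0.08, n_decoys = 3, seed = 4))
  res <- cluster_sequences(sim$sequences, seed = 4, single_pass = TRUE)
  truth <- planted_labels(sim, names(res$membership))
  expect_equal(adjusted_rand_index(res$membership, truth), 1)
})

test_that("UPGMA tree agrees with an independent average-linkage oracle", {
  skip_if_not_installed("ape")
  set.seed(31)
  for (rep in 1:5) {
    n <- 8
    D <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(D) <- rep(list(sprintf("g%02d", seq_len(n))), 2)
    mine <- ape::read.tree(text = write_newick(upgma(D)))
    orac <- ape::as.phylo(stats::hclust(as.dist(D), method = "average"))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(orac)), 0,
                 ignore_attr = TRUE)
    # heights too: cophenetic distances match UPGMA's
    coph <- as.matrix(stats::cophenetic(stats::hclust(as.dist(D),
                                                      method = "average")))
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), rownames(D)],
                 coph[rownames(D), rownames(D)], tolerance = 1e-9)
  }
})

test_that("three-group UPGMA ordering: closest pair forms the first cherry", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = rep(list(c("g1", "g2", "g3")), 2))
  nwk <- write_newick(upgma(D))
  expect_match(nwk, "^\\(\\(g1:0\\.5,g2:0\\.5\\):")
  # one group: trivial one-leaf tree
  res <- cluster_sequences(seq_set_df("g1", random_seq(50, 3)), seed = 1)
  expect_equal(write_newick(res$tree), "g1;")
})

test_that("duplication_report arithmetic and as_grouping", {
  # all singlets -> 0 %
  mem <- setNames(sprintf("s%d", 1:5), sprintf("s%d", 1:5))
  expect_equal(duplication_report(as_grouping(mem))$fraction_pct, 0)
  # constructed partition mirroring the published counts: 13 groups / 36
  # members + 19 singlets, 12 detected of which 6 grouped
  ids <- sprintf("p%02d", 1:55)
  sizes <- c(rep(3, 10), 2, 2, 2)  # 13 groups totalling 36
  lab <- c(rep(sprintf("G%02d", seq_along(sizes)), sizes),
           sprintf("S%02d", 1:19))
  g <- as_grouping(setNames(lab, ids))
  detected <- c(ids[c(1, 4, 7, 10, 13, 16)], ids[37:42])
  r <- duplication_report(g, detected_ids = detected)
  expect_equal(r$n_total, 55)
  expect_equal(r$n_groups, 13)
  expect_equal(r$n_in_groups, 36)
  expect_equal(r$n_singlets, 19)
  expect_equal(r$fraction_pct, 65)
  expect_equal(r$n_detected, 12)
  expect_equal(r$detected_pct, 22)
  expect_equal(r$n_detected_in_groups, 6)
  expect_equal(r$detected_from_groups_pct, 50)
})
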