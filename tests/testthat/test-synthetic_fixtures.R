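test_that("family simulator: zero divergence, determinism, labels cover all", {
  spec0 <- family_sim_spec(n_families = 2, members_per_family = 3,
                           ancestor_length = 50, substitution_prob = 0,
                           n_decoys = 2, seed = 9)
  sim <- simulate_family_set(spec0)
  expect_equal(nrow(sim$sequences), 8)
  expect_identical(sim$truth$id, sim$sequences$id)
  for (f in c("fam1", "fam2")) {
    mem <- sim$sequences$residues[sim$truth$family == f]
    expect_length(unique(mem), 1)  # identical to the ancestor
  }
  sim2 <- simulate_family_set(spec0)
  expect_identical(sim, sim2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(sim$sequences, f1); write_fasta(sim2$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("pairwise member differences match the closed-form expectation", {
  # under uniform replacement over 19 alternatives, two members differ at a
  # site with probability 2p(1-p) + p^2 * 18/19 = 2p - (20/19) p^2
  p <- 0.1; L <- 150
  expected <- L * (2 * p - (20 / 19) * p^2)
  diffs <- numeric(0)
  for (k in 1:200) {
    sim <- simulate_family_set(family_sim_spec(
      n_families = 1, members_per_family = 2, ancestor_length = L,
      substitution_prob = p, n_decoys = 0, seed = 7000 + k))
    a <- strsplit(sim$sequences$residues[1], "")[[1]]
    b <- strsplit(sim$sequences$residues[2], "")[[1]]
    diffs <- c(diffs, sum(a != b))
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("neutral alignment generator: Watterson expectation and limits", {
  n <- 10; theta <- 5
  a1 <- sum(1 / seq_len(n - 1))
  Ss <- vapply(1:600, function(k) {
    aln <- simulate_neutral_alignment(n, theta, seed = 100 + k)
    sum(apply(alignment_matrix(aln), 2, function(cc)
      length(unique(cc)) > 1))
  }, 0.0)
  se <- sd(Ss) / sqrt(length(Ss))
  expect_lt(abs(mean(Ss) - theta * a1), 3 * se)
  # theta -> 0: increasingly monomorphic
  S_small <- vapply(1:100, function(k) {
    aln <- simulate_neutral_alignment(3, 0.01, seed = k)
    sum(apply(alignment_matrix(aln), 2, function(cc)
      length(unique(cc)) > 1))
  }, 0.0)
  expect_lt(mean(S_small), 0.2)
  # determinism
  expect_identical(simulate_neutral_alignment(5, 2, seed = 3),
                   simulate_neutral_alignment(5, 2, seed = 3))
  expect_error(simulate_neutral_alignment(2, 1), "n >= 3")
})

test_that("pipeline fixture: truth covers all ids; empty edge case", {
  sim <- simulate_pipeline_fixture(n_true = 5, n_decoys = 13, seed = 2)
  expect_setequal(sim$truth$protein_id, unique(sim$hits_toxdb$query_id))
  # round-robin allocation of designed reasons
  expect_equal(as.vector(table(sim$truth$designed_reason)[
    c("evalue", "no_rbbh", "coverage", "inconsistent", "structure",
      "no_paralog_support")]), c(3, 2, 2, 2, 2, 2))
  fr <- run_toxin_pipeline(sim$hits_toxdb, sim$hits_toxdb_rev,
                           sim$hits_fulldb, sim$hits_fulldb_rev,
                           sim$hits_cniddb, sim$hits_cniddb_rev,
                           sim$hits_selfgenome, sim$annotations)
  expect_identical(fr$retained,
                   sort(sim$truth$protein_id[sim$truth$role == "true"]))
  sim0 <- simulate_pipeline_fixture(n_true = 0, n_decoys = 6, seed = 2)
  fr0 <- run_toxin_pipeline(sim0$hits_toxdb, sim0$hits_toxdb_rev,
                            sim0$hits_fulldb, sim0$hits_fulldb_rev,
                            sim0$hits_cniddb, sim0$hits_cniddb_rev,
                            sim0$hits_selfgenome, sim0$annotations)
  expect_length(fr0$retained, 0)
})

test_that("peptide observation generator constructs detectable truth", {
  sim <- simulate_family_set(family_sim_spec(
    n_families = 0, members_per_family = 0, ancestor_length = 120,
    substitution_prob = 0, n_decoys = 10, seed = 77))
  prots <- sim$sequences
  det_ids <- prots$id[c(1, 4, 7)]
  obs <- simulate_peptide_observations(prots, det_ids,
                                       peptides_per_protein = 3,
                                       mismatch_rate = 0, seed = 5)
  got <- detect_proteins(obs$peptides, prots)
  expect_identical(got$detected, sort(det_ids))
  # empty detectable set -> nothing detected
  obs0 <- simulate_peptide_observations(prots, character(0), seed = 5)
  expect_length(detect_proteins(obs0$peptides, prots)$detected, 0)
  # determinism
  expect_identical(obs,
                   simulate_peptide_observations(prots, det_ids,
                                                 peptides_per_protein = 3,
                                                 mismatch_rate = 0,
                                                 seed = 5))
})
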