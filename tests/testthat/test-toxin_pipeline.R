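mk_hits <- function(q, s, evalue = 1e-30, cov = 0.9, bits = 300) {
  rank_hits(data.frame(
    query_id = q, subject_id = s, percent_identity = 90,
    alignment_length = 100, mismatches = 10, gap_opens = 0,
    q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    evalue = evalue, bitscore = bits, query_coverage = cov,
    stringsAsFactors = FALSE))
}

test_that("stage 0 applies a strict e-value cutoff", {
  cfg <- pipeline_config()
  h <- mk_hits(c("keep", "drop", "boundary"), "t",
               evalue = c(9.9e-6, 1.1e-5, 1e-5))
  expect_identical(stage0_evalue_filter(h, cfg), "keep")
  expect_identical(stage0_evalue_filter(h[0, ], cfg), character(0))
  # 20 planted sub-threshold among 30
  set.seed(2)
  ids <- sprintf("p%02d", 1:30)
  ev <- c(10^-runif(20, 6, 40), 10^-runif(10, 0, 4.9))
  h2 <- mk_hits(ids, "t", evalue = ev)
  expect_identical(stage0_evalue_filter(h2, cfg), sort(ids[1:20]))
})

test_that("strict and relaxed RBBH agree with a double-loop oracle", {
  expect_error(compute_relaxed_rbbh(mk_hits("a", "b"), mk_hits("b", "a"),
                                    k = 0), "k must be")
  # hand cases
  ab <- mk_hits(c("a", "a"), c("b1", "b2"), evalue = c(1e-30, 1e-10))
  ba <- mk_hits(c("b1", "b1"), c("a", "z"), evalue = c(1e-30, 1e-10))
  expect_equal(compute_rbbh(ab, ba),
               data.frame(a_id = "a", b_id = "b1"), ignore_attr = TRUE)
  ba2 <- mk_hits(c("b1", "b1"), c("z", "a"), evalue = c(1e-30, 1e-10))
  expect_equal(nrow(compute_rbbh(ab, ba2)), 0)          # a is rank 2 of b1
  expect_equal(compute_relaxed_rbbh(ab, ba2, k = 5),
               data.frame(a_id = "a", b_id = "b1"), ignore_attr = TRUE)

  # randomised tables vs exhaustive double loop
  set.seed(14)
  for (rep in 1:100) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    A <- sprintf("a%d", seq_len(na)); B <- sprintf("b%d", seq_len(nb))
    ab <- mk_hits(rep(A, each = nb), rep(B, na),
                  evalue = 10^-runif(na * nb, 0, 50),
                  bits = round(runif(na * nb, 50, 500)))
    ba <- mk_hits(rep(B, each = na), rep(A, nb),
                  evalue = 10^-runif(na * nb, 0, 50),
                  bits = round(runif(na * nb, 50, 500)))
    k <- sample(1:3, 1)
    got <- compute_relaxed_rbbh(ab, ba, k)
    # oracle: rank subject lists per query independently
    topk <- function(h, q, k) {
      hh <- h[h$query_id == q, ]
      hh <- hh[order(hh$evalue, -hh$bitscore, hh$subject_id), ]
      utils::head(hh$subject_id, k)
    }
    want <- list()
    for (a in A) for (b in B)
      if (b %in% topk(ab, a, k) && a %in% topk(ba, b, k))
        want[[length(want) + 1L]] <- c(a, b)
    want <- if (length(want)) do.call(rbind, want) else
      matrix(character(0), 0, 2)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got))
      expect_identical(paste(got$a_id, got$b_id),
                       sort(paste(want[, 1], want[, 2])))
    # relaxed is a superset of strict
    strict <- compute_rbbh(ab, ba)
    expect_true(all(paste(strict$a_id, strict$b_id) %in%
                      paste(got$a_id, got$b_id)))
  }
})

test_that("stage 1 requires reciprocal support AND coverage above 70 %", {
  cfg <- pipeline_config()
  hits <- mk_hits(c("low", "ok", "noR"), "t", cov = c(0.69, 0.90, 0.90))
  rbbh <- data.frame(a_id = c("low", "ok"), b_id = "t",
                     stringsAsFactors = FALSE)
  r <- stage1_toxdb_filter(c("low", "ok", "noR"), rbbh, hits, cfg)
  expect_identical(r$retained, "ok")
  expect_equal(unname(r$reason["low"]), "coverage")
  expect_equal(unname(r$reason["noR"]), "no_rbbh")
  # boundary: exactly 0.70 fails
  hb <- mk_hits("b", "t", cov = 0.70)
  expect_length(stage1_toxdb_filter(
    "b", data.frame(a_id = "b", b_id = "t"), hb, cfg)$retained, 0)
})

test_that("stage 2 is a conjunction over both databases", {
  cfg <- pipeline_config()
  rb_full <- data.frame(a_id = c("x", "y"), b_id = "t")
  rb_cnid <- data.frame(a_id = "x", b_id = "t")
  h_full <- mk_hits(c("x", "y"), "t", evalue = 1e-6)
  h_cnid <- mk_hits(c("x", "y"), "t", evalue = c(1e-6, 1e-30))
  r <- stage2_dual_database_filter(c("x", "y"), rb_full, rb_cnid,
                                   h_full, h_cnid, cfg)
  expect_identical(r$retained, "x")   # y qualifies in full db only
  # boundary e-value 1e-5 fails
  h_eq <- mk_hits("x", "t", evalue = 1e-5)
  r2 <- stage2_dual_database_filter("x", rb_full, rb_cnid, h_eq, h_cnid,
                                    cfg)
  expect_length(r2$retained, 0)
})

test_that("stage 3 discards on strictly higher non-toxin bitscore", {
  cfg <- pipeline_config()
  mk3 <- function(tox_bits, non_bits) {
    h <- mk_hits(c("p", "p"), c("tox", "non"), bits = c(tox_bits, non_bits))
    h$is_toxin_subject <- c(TRUE, FALSE)[match(h$subject_id,
                                               c("tox", "non"))]
    h
  }
  expect_length(stage3_consistency_filter("p", mk3(210, 250),
                                          cfg = cfg)$retained, 0)
  expect_identical(stage3_consistency_filter("p", mk3(250, 250),
                                             cfg = cfg)$retained, "p")
  # no toxin-subject hits at all -> discarded as inconsistent
  h <- mk_hits("p", "non"); h$is_toxin_subject <- FALSE
  r <- stage3_consistency_filter("p", h, cfg = cfg)
  expect_equal(unname(r$reason["p"]), "inconsistent")
  # randomised tables vs a double-loop oracle
  set.seed(6)
  for (rep in 1:100) {
    np <- sample(2:5, 1); ns <- sample(2:6, 1)
    P <- sprintf("p%d", seq_len(np)); S <- sprintf("s%d", seq_len(ns))
    h <- mk_hits(rep(P, each = ns), rep(S, np),
                 bits = round(runif(np * ns, 50, 500)))
    istox <- setNames(sample(c(TRUE, FALSE), ns, replace = TRUE), S)
    got <- stage3_consistency_filter(P, h, subject_is_toxin = istox,
                                     cfg = cfg)$retained
    want <- character(0)
    for (p in P) {
      bt <- -Inf; bn <- -Inf
      for (i in which(h$query_id == p)) {
        if (istox[h$subject_id[i]]) bt <- max(bt, h$bitscore[i])
        else bn <- max(bn, h$bitscore[i])
      }
      if (is.finite(bt) && !(bn > bt)) want <- c(want, p)
    }
    expect_identical(got, want)
  }
})

test_that("stage 4 structural exclusions and missing-annotation policy", {
  cfg <- pipeline_config()
  ann <- data.frame(
    protein_id = sprintf("p%d", 1:10),
    tm_count = c(2L, 1L, 0L, 0L, 3L, 0L, 1L, 0L, 0L, 0L),
    domain_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE),
    go_excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    is_toxin_subject = FALSE, stringsAsFactors = FALSE)
  r <- stage4_structure_filter(ann$protein_id, ann, cfg)
  # planted violations: p1 (tm=2), p3 (domain), p4 (GO), p5 (tm=3)
  expect_identical(r$retained, sprintf("p%d", c(2, 6, 7, 8, 9, 10)))
  expect_true(all(r$reason == "structure"))
  # missing annotation: reject by default, pass-through when configured
  expect_length(stage4_structure_filter("ghost", ann, cfg)$retained, 0)
  cfg2 <- pipeline_config(missing_annotation = "pass")
  expect_identical(stage4_structure_filter("ghost", ann, cfg2)$retained,
                   "ghost")
})

test_that("stage 5 conjunction, boundaries, and self-hit policy", {
  cfg <- pipeline_config()
  h <- mk_hits(rep("p", 3), c("q1", "q2", "q3"),
               evalue = c(1e-25, 1e-19, 1e-25),
               cov = c(0.80, 0.76, 0.75))
  expect_identical(stage5_genome_support_filter("p", h, cfg)$retained, "p")
  # each criterion alone fails: evalue 1e-19 (with cov ok), cov 0.75 exact
  expect_length(stage5_genome_support_filter(
    "p", h[2, ], cfg)$retained, 0)
  expect_length(stage5_genome_support_filter(
    "p", h[3, ], cfg)$retained, 0)
  # boundary e-value exactly 1e-20 fails
  hb <- mk_hits("p", "q", evalue = 1e-20, cov = 0.9)
  expect_length(stage5_genome_support_filter("p", hb, cfg)$retained, 0)
  # self-hit policy
  hself <- mk_hits("p", "p", evalue = 1e-30, cov = 0.95)
  expect_identical(stage5_genome_support_filter("p", hself, cfg)$retained,
                   "p")
  cfg_x <- pipeline_config(exclude_self_hits = TRUE)
  expect_length(stage5_genome_support_filter("p", hself, cfg_x)$retained, 0)
})

test_that("end-to-end fixture: planted candidates survive, reports reconcile", {
  sim <- simulate_pipeline_fixture(n_true = 12, n_decoys = 40, seed = 5)
  fr <- run_toxin_pipeline(sim$hits_toxdb, sim$hits_toxdb_rev,
                           sim$hits_fulldb, sim$hits_fulldb_rev,
                           sim$hits_cniddb, sim$hits_cniddb_rev,
                           sim$hits_selfgenome, sim$annotations)
  truth <- sim$truth
  expect_identical(fr$retained,
                   sort(truth$protein_id[truth$role == "true"]))
  # per-stage counts equal the designed construction
  expect_true(all(diff(fr$report$n_out) <= 0))  # non-increasing
  designed_failures <- table(factor(truth$designed_fail_stage,
                                    levels = 0:5))
  n_in <- 52
  expected_out <- n_in - cumsum(as.integer(designed_failures))
  expect_equal(fr$report$n_out, expected_out)
  # every rejected protein carries exactly its designed reason
  rej <- fr$candidates[!fr$candidates$pass, ]
  expect_identical(rej$rejection_reason,
                   truth$designed_reason[match(rej$protein_id,
                                               truth$protein_id)])
  expect_true(all(fr$candidates$pass ==
                    (fr$candidates$stage_reached == 5L)))
  # purity: identical rerun is identical
  fr2 <- run_toxin_pipeline(sim$hits_toxdb, sim$hits_toxdb_rev,
                            sim$hits_fulldb, sim$hits_fulldb_rev,
                            sim$hits_cniddb, sim$hits_cniddb_rev,
                            sim$hits_selfgenome, sim$annotations)
  expect_identical(fr, fr2)
})
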