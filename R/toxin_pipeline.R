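#' @name toxin_pipeline
#' @title Five-stage candidate-toxin filter
#'
#' @description
#' Turns raw homology hits of a predicted proteome against a toxin database
#' into candidate toxins via five successive filters: (0) an initial
#' e-value screen; (1) strict or relaxed reciprocal-best-hit support against
#' the toxin database with query coverage above 70 %; (2) reciprocal support
#' below e-value 1e-5 against both a supplemented full protein database and
#' a cnidarian-only database; (3) consistency — candidates scoring higher
#' (bitscore) against non-toxin than toxin subjects are discarded; (4)
#' structural plausibility — two or more predicted transmembrane segments, a
#' domain architecture unlike known toxins, or an excluded GO term discards;
#' (5) confident support in the organism's own translated genome (coverage
#' > 75 % and e-value < 1e-20). All thresholds are strict inequalities;
#' boundary values fail.
NULL

#' Pipeline configuration
#'
#' Defaults reproduce the published thresholds exactly.
#'
#' @param evalue_initial stage-0 e-value cutoff (hit must be strictly below).
#' @param qcov_stage1 stage-1 query-coverage threshold, fraction (strictly
#'   above).
#' @param evalue_stage2 stage-2 e-value cutoff for both databases.
#' @param relaxed_k top-k for relaxed reciprocal best hits.
#' @param qcov_stage5 stage-5 coverage threshold (strictly above).
#' @param evalue_stage5 stage-5 e-value cutoff (strictly below).
#' @param exclude_self_hits drop query == subject rows at stage 5 (so the
#'   criterion demands a non-self paralog); default FALSE (a confident
#'   self-mapping satisfies it).
#' @param missing_annotation stage-4 behaviour for proteins without an
#'   annotation record: `"reject"` (default, fail-closed) or `"pass"`.
#' @param stage3_order rank subjects at stage 3 by `"bitscore"` (default) or
#'   `"evalue"`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(evalue_initial = 1e-5, qcov_stage1 = 0.70,
                            evalue_stage2 = 1e-5, relaxed_k = 5L,
                            qcov_stage5 = 0.75, evalue_stage5 = 1e-20,
                            exclude_self_hits = FALSE,
                            missing_annotation = c("reject", "pass"),
                            stage3_order = c("bitscore", "evalue")) {
  stopifnot(evalue_initial > 0, evalue_stage2 > 0, evalue_stage5 > 0,
            qcov_stage1 > 0, qcov_stage1 < 1,
            qcov_stage5 > 0, qcov_stage5 < 1, relaxed_k >= 1)
  structure(list(evalue_initial = evalue_initial, qcov_stage1 = qcov_stage1,
                 evalue_stage2 = evalue_stage2, relaxed_k = as.integer(relaxed_k),
                 qcov_stage5 = qcov_stage5, evalue_stage5 = evalue_stage5,
                 exclude_self_hits = exclude_self_hits,
                 missing_annotation = match.arg(missing_annotation),
                 stage3_order = match.arg(stage3_order)),
            class = "pipeline_config")
}

best_hit_per_query <- function(hits) {
  hits <- rank_hits(hits)
  hits[hits$rank == 1L, , drop = FALSE]
}

#' Stage 0: initial e-value screen
#'
#' @param hits `hit_table` of the proteome vs the toxin database.
#' @param cfg `pipeline_config`.
#' @return character vector of query ids with at least one hit with
#'   `evalue < cfg$evalue_initial`.
#' @export
stage0_evalue_filter <- function(hits, cfg = pipeline_config()) {
  sort(unique(hits$query_id[hits$evalue < cfg$evalue_initial]))
}

#' Strict reciprocal best hits
#'
#' @param hits_ab hits of set A queried against set B.
#' @param hits_ba hits of set B queried against set A.
#' @return data.frame `a_id`, `b_id`: pairs where each is the other's rank-1
#'   subject (rank ties broken by higher bitscore then lexicographic
#'   subject id).
#' @export
compute_rbbh <- function(hits_ab, hits_ba) {
  compute_relaxed_rbbh(hits_ab, hits_ba, k = 1L)
}

#' Relaxed reciprocal best hits (top-k both ways)
#'
#' @inheritParams compute_rbbh
#' @param k reciprocal rank window (k = 1 is strict RBBH; default 5).
#' @return data.frame `a_id`, `b_id` of pairs with `b` within `a`'s top k
#'   and `a` within `b`'s top k.
#' @export
compute_relaxed_rbbh <- function(hits_ab, hits_ba, k = 5L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ab <- rank_hits(hits_ab); ba <- rank_hits(hits_ba)
  ab <- ab[ab$rank <= k, c("query_id", "subject_id")]
  ba <- ba[ba$rank <= k, c("query_id", "subject_id")]
  m <- merge(ab, ba, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"))
  out <- data.frame(a_id = m$query_id, b_id = m$subject_id,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$a_id, out$b_id), , drop = FALSE]
}

#' Stage 1: reciprocal toxin-database support with coverage
#'
#' Retains a protein iff it has a strict or relaxed reciprocal best hit to
#' the toxin database and its best toxin hit has query coverage strictly
#' above `cfg$qcov_stage1`.
#'
#' @param proteins stage-0 survivors (character).
#' @param rbbh_pairs union of strict and relaxed RBBH pairs vs the toxin
#'   database (data.frame `a_id`, `b_id`).
#' @param hits the proteome-vs-toxin-database `hit_table`.
#' @param cfg `pipeline_config`.
#' @return list with `retained` (character) and `reason` (named character of
#'   rejection reasons: `no_rbbh` or `coverage`).
#' @export
stage1_toxdb_filter <- function(proteins, rbbh_pairs, hits,
                                cfg = pipeline_config()) {
  has_rbbh <- proteins %in% rbbh_pairs$a_id
  best <- best_hit_per_query(hits)
  cov <- setNames(best$query_coverage, best$query_id)[proteins]
  cov_ok <- !is.na(cov) & cov > cfg$qcov_stage1
  retained <- proteins[has_rbbh & cov_ok]
  reason <- setNames(ifelse(!has_rbbh, "no_rbbh", "coverage"),
                     proteins)[!(has_rbbh & cov_ok)]
  list(retained = retained, reason = reason)
}

# does protein a have a reciprocal pair whose forward hit clears the cutoff?
reciprocal_under_evalue <- function(proteins, rbbh_pairs, hits, cutoff) {
  h <- hits[hits$evalue < cutoff, c("query_id", "subject_id")]
  ok <- merge(rbbh_pairs, h, by.x = c("a_id", "b_id"),
              by.y = c("query_id", "subject_id"))
  proteins %in% ok$a_id
}

#' Stage 2: reciprocal support in both reference databases
#'
#' @param proteins stage-1 survivors.
#' @param rbbh_full,rbbh_cnid reciprocal pairs (strict union relaxed) vs the
#'   supplemented full database and the cnidarian-only database.
#' @param hits_full,hits_cnid forward hit tables vs the two databases.
#' @param cfg `pipeline_config`.
#' @return list `retained`, `reason` (`no_rbbh`).
#' @export
stage2_dual_database_filter <- function(proteins, rbbh_full, rbbh_cnid,
                                        hits_full, hits_cnid,
                                        cfg = pipeline_config()) {
  ok <- reciprocal_under_evalue(proteins, rbbh_full, hits_full,
                                cfg$evalue_stage2) &
    reciprocal_under_evalue(proteins, rbbh_cnid, hits_cnid,
                            cfg$evalue_stage2)
  list(retained = proteins[ok],
       reason = setNames(rep("no_rbbh", sum(!ok)), proteins[!ok]))
}

#' Stage 3: toxin-vs-non-toxin consistency
#'
#' A protein is discarded iff its best score over non-toxin subjects is
#' strictly greater than its best score over toxin subjects (equal best
#' scores retain). A protein with no toxin-subject hit is discarded.
#'
#' @param proteins stage-2 survivors.
#' @param hits annotated `hit_table` (supplemented full database) carrying a
#'   logical `is_toxin_subject` column, or supply `subject_is_toxin`.
#' @param subject_is_toxin optional named logical vector over subject ids.
#' @param cfg `pipeline_config`; `stage3_order` selects bitscore (default)
#'   or e-value ordering.
#' @return list `retained`, `reason` (`inconsistent`).
#' @export
stage3_consistency_filter <- function(proteins, hits,
                                      subject_is_toxin = NULL,
                                      cfg = pipeline_config()) {
  if (!is.null(subject_is_toxin))
    hits$is_toxin_subject <- unname(subject_is_toxin[hits$subject_id])
  if (is.null(hits$is_toxin_subject) || anyNA(hits$is_toxin_subject))
    stop("stage 3 requires is_toxin_subject for every hit subject",
         call. = FALSE)
  score <- if (cfg$stage3_order == "bitscore") hits$bitscore
           else -log10(pmax(hits$evalue, 1e-300))
  ok <- vapply(proteins, function(p) {
    h <- hits$query_id == p
    tox <- h & hits$is_toxin_subject
    non <- h & !hits$is_toxin_subject
    if (!any(tox)) return(FALSE)
    if (!any(non)) return(TRUE)
    !(max(score[non]) > max(score[tox]))
  }, TRUE)
  list(retained = proteins[ok],
       reason = setNames(rep("inconsistent", sum(!ok)), proteins[!ok]))
}

#' Stage 4: structural plausibility
#'
#' Discards proteins with `tm_count >= 2`, `domain_ok == FALSE`, or
#' `go_excluded == TRUE`. Proteins missing an annotation record are rejected
#' by default (fail-closed) or passed through with
#' `cfg$missing_annotation = "pass"`.
#'
#' @param proteins stage-3 survivors.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param cfg `pipeline_config`.
#' @return list `retained`, `reason` (`structure`).
#' @export
stage4_structure_filter <- function(proteins, annotations,
                                    cfg = pipeline_config()) {
  idx <- match(proteins, annotations$protein_id)
  missing <- is.na(idx)
  bad <- !missing & (annotations$tm_count[idx] >= 2L |
                       !annotations$domain_ok[idx] |
                       annotations$go_excluded[idx])
  drop <- bad | (missing & cfg$missing_annotation == "reject")
  list(retained = proteins[!drop],
       reason = setNames(rep("structure", sum(drop)), proteins[drop]))
}

#' Stage 5: confident self-genome support
#'
#' Retains a protein iff it has at least one hit against the organism's own
#' translated genome with query coverage strictly above `cfg$qcov_stage5`
#' and e-value strictly below `cfg$evalue_stage5`.
#'
#' @param proteins stage-4 survivors.
#' @param self_genome_hits `hit_table` of candidates vs the translated
#'   genome.
#' @param cfg `pipeline_config`; `exclude_self_hits` controls whether a
#'   query's hit to itself may satisfy the criterion.
#' @return list `retained`, `reason` (`no_paralog_support`).
#' @export
stage5_genome_support_filter <- function(proteins, self_genome_hits,
                                         cfg = pipeline_config()) {
  h <- self_genome_hits
  if (cfg$exclude_self_hits) h <- h[h$query_id != h$subject_id, , drop = FALSE]
  q <- h$query_id[h$query_coverage > cfg$qcov_stage5 &
                    h$evalue < cfg$evalue_stage5]
  ok <- proteins %in% q
  list(retained = proteins[ok],
       reason = setNames(rep("no_paralog_support", sum(!ok)),
                         proteins[!ok]))
}

#' Run the full five-stage filter
#'
#' @param hits_toxdb,hits_toxdb_rev forward/reverse hit tables vs the toxin
#'   database.
#' @param hits_fulldb,hits_fulldb_rev forward/reverse vs the supplemented
#'   full database; the forward table must be resolvable to toxin/non-toxin
#'   subjects via `subject_is_toxin` or an `is_toxin_subject` column.
#' @param hits_cniddb,hits_cniddb_rev forward/reverse vs the cnidarian-only
#'   database.
#' @param hits_selfgenome candidates vs the organism's translated genome.
#' @param annotations annotation table for stage 4.
#' @param subject_is_toxin named logical over database subject ids
#'   (stage 3); defaults to the `is_toxin_subject` column of `annotations`
#'   matched to subject ids.
#' @param cfg `pipeline_config`.
#' @return A `filter_report`: list with `candidates` (data.frame
#'   `protein_id`, `stage_reached`, `pass`, `rejection_reason`,
#'   `best_toxin_hit` columns), `report` (per-stage `stage`, `n_in`,
#'   `n_out`), `retained` (final candidate ids), `config`.
#' @export
run_toxin_pipeline <- function(hits_toxdb, hits_toxdb_rev,
                               hits_fulldb, hits_fulldb_rev,
                               hits_cniddb, hits_cniddb_rev,
                               hits_selfgenome, annotations,
                               subject_is_toxin = NULL,
                               cfg = pipeline_config()) {
  if (is.null(subject_is_toxin))
    subject_is_toxin <- setNames(annotations$is_toxin_subject,
                                 annotations$protein_id)
  universe <- sort(unique(hits_toxdb$query_id))
  reason <- setNames(rep(NA_character_, length(universe)), universe)
  stage_reached <- setNames(rep(0L, length(universe)), universe)

  s0 <- stage0_evalue_filter(hits_toxdb, cfg)
  reason[setdiff(universe, s0)] <- "evalue"

  rbbh_tox <- unique(rbind(compute_rbbh(hits_toxdb, hits_toxdb_rev),
                           compute_relaxed_rbbh(hits_toxdb, hits_toxdb_rev,
                                                cfg$relaxed_k)))
  s1r <- stage1_toxdb_filter(s0, rbbh_tox, hits_toxdb, cfg)
  stage_reached[s1r$retained] <- 1L
  reason[names(s1r$reason)] <- s1r$reason

  rbbh_full <- unique(rbind(compute_rbbh(hits_fulldb, hits_fulldb_rev),
                            compute_relaxed_rbbh(hits_fulldb,
                                                 hits_fulldb_rev,
                                                 cfg$relaxed_k)))
  rbbh_cnid <- unique(rbind(compute_rbbh(hits_cniddb, hits_cniddb_rev),
                            compute_relaxed_rbbh(hits_cniddb,
                                                 hits_cniddb_rev,
                                                 cfg$relaxed_k)))
  s2r <- stage2_dual_database_filter(s1r$retained, rbbh_full, rbbh_cnid,
                                     hits_fulldb, hits_cniddb, cfg)
  stage_reached[s2r$retained] <- 2L
  reason[names(s2r$reason)] <- s2r$reason

  s3r <- stage3_consistency_filter(s2r$retained, hits_fulldb,
                                   subject_is_toxin, cfg)
  stage_reached[s3r$retained] <- 3L
  reason[names(s3r$reason)] <- s3r$reason

  s4r <- stage4_structure_filter(s3r$retained, annotations, cfg)
  stage_reached[s4r$retained] <- 4L
  reason[names(s4r$reason)] <- s4r$reason

  s5r <- stage5_genome_support_filter(s4r$retained, hits_selfgenome, cfg)
  stage_reached[s5r$retained] <- 5L
  reason[names(s5r$reason)] <- s5r$reason
  # stage_reached counts cleared stages 1..5, so pass <=> stage_reached == 5;
  # stage-0 and stage-1 rejections both sit at 0, told apart by the reason
  pass <- setNames(universe %in% s5r$retained, universe)

  best <- best_hit_per_query(hits_toxdb)
  bidx <- match(universe, best$query_id)
  candidates <- data.frame(
    protein_id = universe,
    stage_reached = unname(stage_reached),
    pass = unname(pass),
    rejection_reason = unname(reason),
    best_hit_subject = best$subject_id[bidx],
    best_hit_evalue = best$evalue[bidx],
    best_hit_coverage = best$query_coverage[bidx],
    stringsAsFactors = FALSE)

  counts <- c(stage0 = length(s0), stage1 = length(s1r$retained),
              stage2 = length(s2r$retained), stage3 = length(s3r$retained),
              stage4 = length(s4r$retained), stage5 = length(s5r$retained))
  report <- data.frame(stage = names(counts),
                       n_in = c(length(universe), unname(counts[-6])),
                       n_out = unname(counts), stringsAsFactors = FALSE)
  structure(list(candidates = candidates, report = report,
                 retained = s5r$retained, config = cfg),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("five-stage toxin filter\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("candidates: %d\n", length(x$retained)))
  invisible(x)
}
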