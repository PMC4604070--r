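#' @name synthetic_fixtures
#' @title Seeded generators with planted ground truth
#'
#' @description
#' Every input the analysis modules consume can be generated synthetically
#' with a known answer: families of duplicated protein sequences at
#' controlled divergence (stand-in for a proteome with paralogs), neutral
#' coalescent alignments (oracle for Tajima's D), staged hit-table fixtures
#' for the five-stage filter, and peptide observations for a chosen
#' detectable subset. Generators are pure functions of their parameters and
#' seed; the planted truth is returned alongside and is only ever consumed
#' by tests.
NULL

#' Family simulation parameters
#'
#' @param n_families number of duplicated-gene families.
#' @param members_per_family duplicates per family.
#' @param ancestor_length residues in each family ancestor.
#' @param substitution_prob per-site substitution probability applied
#'   independently on each duplicate's edge from the ancestor (uniform
#'   replacement over the 19 alternative residues).
#' @param n_decoys unrelated random sequences added.
#' @param seed integer seed.
#' @return a `family_sim_spec`.
#' @export
family_sim_spec <- function(n_families = 4L, members_per_family = 5L,
                            ancestor_length = 150L,
                            substitution_prob = 0.10, n_decoys = 10L,
                            seed = 1L) {
  stopifnot(substitution_prob >= 0, substitution_prob < 1,
            n_families >= 0, members_per_family >= 0, n_decoys >= 0,
            ancestor_length >= 1)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_prob = substitution_prob,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
            class = "family_sim_spec")
}

mutate_seq <- function(chars, p) {
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), "")
  }
  chars
}

#' Simulate families of duplicated sequences plus decoys
#'
#' Each family is an ancestor of uniform random residues; members are
#' independent mutants of it (star topology) at the spec's per-site
#' substitution probability. Decoys are unrelated uniform random sequences.
#'
#' @param spec a `family_sim_spec`.
#' @return list with `sequences` (a `seq_set`; ids `famF_mM` and `decoyD`)
#'   and `truth` (data.frame `id`, `family`; decoys labelled `"decoy"`).
#' @export
simulate_family_set <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0); fam <- character(0)
    for (f in seq_len(spec$n_families)) {
      anc <- sample(AA20, spec$ancestor_length, replace = TRUE)
      for (m in seq_len(spec$members_per_family)) {
        ids <- c(ids, sprintf("fam%d_m%d", f, m))
        seqs <- c(seqs, paste(mutate_seq(anc, spec$substitution_prob),
                              collapse = ""))
        fam <- c(fam, sprintf("fam%d", f))
      }
    }
    for (d in seq_len(spec$n_decoys)) {
      ids <- c(ids, sprintf("decoy%d", d))
      seqs <- c(seqs, paste(sample(AA20, spec$ancestor_length,
                                   replace = TRUE), collapse = ""))
      fam <- c(fam, "decoy")
    }
    list(sequences = structure(
           data.frame(id = ids, description = "", residues = seqs,
                      stringsAsFactors = FALSE),
           class = c("seq_set", "data.frame")),
         truth = data.frame(id = ids, family = fam,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a neutral coalescent alignment (infinite sites)
#'
#' Standard Kingman coalescent genealogy for `n` lineages; mutations are
#' Poisson with mean theta/2 times total branch length, each creating a
#' unique binary-state column whose derived state marks the leaves under
#' the mutated branch.
#'
#' @param n number of sequences (>= 3).
#' @param theta population-scaled mutation rate (> 0).
#' @param seed integer seed.
#' @return an `msa` with binary columns (`A` ancestral, `T` derived); a
#'   monomorphic placeholder column is emitted when no mutation occurs so
#'   the alignment is never empty.
#' @export
simulate_neutral_alignment <- function(n, theta, seed = 1L) {
  stopifnot(n >= 3, theta > 0)
  with_seed(seed, {
    # lineages: list of leaf index sets; record (branch set, length) pairs
    active <- lapply(seq_len(n), identity)
    t_now <- 0
    segs_members <- list(); segs_len <- numeric(0)
    birth <- setNames(rep(0, n), seq_len(n))  # time each lineage began
    lineage_sets <- active
    lineage_birth <- rep(0, n)
    while (length(lineage_sets) > 1L) {
      k <- length(lineage_sets)
      t_now <- t_now + rexp(1, rate = k * (k - 1) / 2)
      pair <- sort(sample.int(k, 2L))
      for (idx in pair) {
        segs_members[[length(segs_members) + 1L]] <- lineage_sets[[idx]]
        segs_len <- c(segs_len, t_now - lineage_birth[idx])
      }
      merged <- sort(c(lineage_sets[[pair[1]]], lineage_sets[[pair[2]]]))
      lineage_sets <- c(lineage_sets[-pair], list(merged))
      lineage_birth <- c(lineage_birth[-pair], t_now)
    }
    total_len <- sum(segs_len)
    n_mut <- rpois(1, theta / 2 * total_len)
    m <- matrix("A", n, max(n_mut, 1L))
    if (n_mut > 0) {
      br <- sample.int(length(segs_len), n_mut, replace = TRUE,
                       prob = segs_len)
      for (k in seq_len(n_mut)) m[segs_members[[br[k]]], k] <- "T"
    }
    as_alignment(setNames(apply(m, 1, paste, collapse = ""),
                          sprintf("seq%d", seq_len(n))))
  })
}

#' Simulate a staged fixture for the five-stage filter
#'
#' Builds all seven hit tables and the annotation table so that exactly
#' `n_true` planted proteins survive stage 5 while each decoy fails at a
#' designed stage, assigned round-robin over the six rejection reasons
#' (`evalue`, `no_rbbh`, `coverage`, `inconsistent`, `structure`,
#' `no_paralog_support`).
#'
#' @param n_true number of planted true toxins.
#' @param n_decoys number of staged decoys.
#' @param seed integer seed (drives e-value/bitscore jitter only).
#' @return list with elements `hits_toxdb`, `hits_toxdb_rev`, `hits_fulldb`,
#'   `hits_fulldb_rev`, `hits_cniddb`, `hits_cniddb_rev`, `hits_selfgenome`,
#'   `annotations`, and `truth` (data.frame `protein_id`, `role`
#'   (`"true"`/`"decoy"`), `designed_reason`, `designed_fail_stage`).
#' @export
simulate_pipeline_fixture <- function(n_true = 12L, n_decoys = 40L,
                                      seed = 1L) {
  stopifnot(n_true >= 0, n_decoys >= 0)
  reasons <- c("evalue", "no_rbbh", "coverage", "inconsistent",
               "structure", "no_paralog_support")
  fail_stage <- c(evalue = 0L, no_rbbh = 1L, coverage = 1L,
                  inconsistent = 3L, structure = 4L,
                  no_paralog_support = 5L)
  ids <- c(if (n_true > 0) sprintf("true%02d", seq_len(n_true)),
           if (n_decoys > 0) sprintf("decoy%02d", seq_len(n_decoys)))
  role <- c(rep("true", n_true), rep("decoy", n_decoys))
  dreason <- c(rep(NA_character_, n_true),
               if (n_decoys > 0) reasons[(seq_len(n_decoys) - 1L) %%
                                           length(reasons) + 1L])

  with_seed(seed, {
    good_e <- function(k) 10^-runif(k, 10, 40)      # << 1e-5
    row <- function(q, s, e, cov, bits) data.frame(
      query_id = q, subject_id = s, percent_identity = 90,
      alignment_length = 100, mismatches = 10, gap_opens = 0,
      q_start = 1, q_end = 100, s_start = 1, s_end = 100,
      evalue = e, bitscore = bits, query_coverage = cov,
      stringsAsFactors = FALSE)

    tox <- full <- cnid <- list(); toxr <- fullr <- cnidr <- list()
    selfg <- list(); ann <- list()
    for (k in seq_along(ids)) {
      id <- ids[k]; rs <- dreason[k]
      tox_subject <- paste0("tx_", id)
      phys_subject <- paste0("ph_", id)
      # stage 0: a toxin-db hit; fails iff reason == evalue (boundary above)
      e0 <- if (!is.na(rs) && rs == "evalue") 1e-4 else good_e(1)
      cov1 <- if (!is.na(rs) && rs == "coverage") 0.60 else 0.90
      tox[[k]] <- row(id, tox_subject, e0, cov1, 300)
      # reciprocal hit unless reason == no_rbbh (reverse points elsewhere)
      back <- if (!is.na(rs) && rs == "no_rbbh") ids[1] else id
      toxr[[k]] <- row(tox_subject, back, good_e(1), 0.90, 300)
      # both reference databases reciprocate for everyone
      full[[length(full) + 1L]] <- row(id, tox_subject, good_e(1), 0.90, 300)
      fullr[[k]] <- row(tox_subject, id, good_e(1), 0.90, 300)
      cnid[[k]] <- row(id, tox_subject, good_e(1), 0.90, 280)
      cnidr[[k]] <- row(tox_subject, id, good_e(1), 0.90, 280)
      # stage 3: a weaker non-toxin hit, unless planted inconsistent
      non_bits <- if (!is.na(rs) && rs == "inconsistent") 400 else 150
      full[[length(full) + 1L]] <- row(id, phys_subject, good_e(1), 0.90,
                                       non_bits)
      # stage 4 annotations
      bad4 <- !is.na(rs) && rs == "structure"
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = id, tm_count = if (bad4) 2L else sample(0:1, 1),
        domain_ok = TRUE, go_excluded = FALSE, is_toxin_subject = FALSE,
        stringsAsFactors = FALSE)
      # stage 5 self-genome support
      e5 <- if (!is.na(rs) && rs == "no_paralog_support") 1e-10 else
        10^-runif(1, 25, 60)
      cov5 <- if (!is.na(rs) && rs == "no_paralog_support") 0.60 else 0.90
      selfg[[k]] <- row(id, paste0("paralog_", id), e5, cov5, 250)
    }
    subj_ann <- rbind(
      data.frame(protein_id = paste0("tx_", ids), tm_count = 0L,
                 domain_ok = TRUE, go_excluded = FALSE,
                 is_toxin_subject = TRUE, stringsAsFactors = FALSE),
      data.frame(protein_id = paste0("ph_", ids), tm_count = 0L,
                 domain_ok = TRUE, go_excluded = FALSE,
                 is_toxin_subject = FALSE, stringsAsFactors = FALSE))
    list(hits_toxdb = rank_hits(do.call(rbind, tox)),
         hits_toxdb_rev = rank_hits(do.call(rbind, toxr)),
         hits_fulldb = rank_hits(do.call(rbind, full)),
         hits_fulldb_rev = rank_hits(do.call(rbind, fullr)),
         hits_cniddb = rank_hits(do.call(rbind, cnid)),
         hits_cniddb_rev = rank_hits(do.call(rbind, cnidr)),
         hits_selfgenome = rank_hits(do.call(rbind, selfg)),
         annotations = rbind(do.call(rbind, ann), subj_ann),
         truth = data.frame(protein_id = ids, role = role,
                            designed_reason = dreason,
                            designed_fail_stage =
                              unname(fail_stage[dreason]),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate peptide observations for chosen detectable proteins
#'
#' Samples tryptic peptides (length >= 7) from the detectable proteins and
#' injects per-residue mismatches at the given rate; every other protein
#' receives at most one peptide so it cannot satisfy the two-peptide rule.
#'
#' @param proteins a `seq_set`.
#' @param detectable_ids subset of `proteins$id` to make detectable.
#' @param peptides_per_protein peptides sampled per detectable protein
#'   (default 3).
#' @param mismatch_rate per-residue substitution rate injected into
#'   observed peptides (default 0).
#' @param seed integer seed.
#' @return list with `peptides` (character) and `truth` (the detectable id
#'   set).
#' @export
simulate_peptide_observations <- function(proteins, detectable_ids,
                                          peptides_per_protein = 3L,
                                          mismatch_rate = 0, seed = 1L) {
  stopifnot(all(detectable_ids %in% proteins$id),
            peptides_per_protein >= 1, mismatch_rate >= 0,
            mismatch_rate < 1)
  with_seed(seed, {
    peps <- character(0)
    for (k in seq_len(nrow(proteins))) {
      id <- proteins$id[k]
      frags <- unique(tryptic_digest(proteins$residues[k], max_missed = 3L))
      frags <- frags[nchar(frags) >= 7L]
      if (!length(frags)) next
      take <- if (id %in% detectable_ids)
        min(peptides_per_protein, length(frags)) else
          sample(0:1, 1) * as.integer(length(frags) >= 1L)
      if (take == 0L) next
      sel <- sample(frags, take)
      peps <- c(peps, vapply(sel, function(p)
        paste(mutate_seq(strsplit(p, "")[[1]], mismatch_rate),
              collapse = ""), ""))
    }
    list(peptides = unname(peps), truth = sort(detectable_ids))
  })
}
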