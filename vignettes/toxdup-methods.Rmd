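---
title: "Methods: profile-HMM duplication clustering and toxin-candidate filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM duplication clustering and toxin-candidate filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Gene duplication is the dominant route by which venom toxin repertoires
diversify. Detecting duplications normally requires phylogenies across
many closely related species; when only a handful of distant genomes
exist (as for reef-building corals), an alternative is to cluster a
proteome's candidate toxins by profile-HMM similarity: pairs whose
profiles align with an extremely significant E-value are interpreted as
proxy paralogs. `toxdup` implements that chain — candidate filtering,
HMM–HMM clustering, proteome-level detection, and a per-group neutrality
test — as a tested library with seeded synthetic fixtures in place of the
genome-scale and mass-spectrometry inputs.

## Profile HMMs

`build_profile_hmm()` summarises an alignment as `L` match states:

* **Match columns** are those with strictly more than 50 % non-gap
  characters. The tie (exactly 50 %) falls to *insert*: a side had to be
  picked, and strictness is unit-tested so the convention cannot drift.
* **Match emissions** are pseudocount-smoothed weighted frequencies,
  `q_i(a) = (c_i(a) + w·f(a)) / (Σc_i + w)`, with uniform sequence
  weights by default (Henikoff position-based weights behind a flag) and
  uniform background `f(a) = 1/20` unless a table is supplied. Removing
  the external background dependency keeps the package self-contained;
  any residue-frequency table can be passed in.
* **Insert emissions** are fixed to the background, so inserts are
  scoring-neutral.
* **Transitions** are estimated from each sequence's observed
  match/insert/delete path with additive smoothing over each state's
  outgoing set. Forbidden plan-7 steps (D→I, I→D) contribute no counts
  but still switch state.

### The transition-smoothing regime

The one genuinely consequential free parameter is the transition
pseudocount. Add-one smoothing (the construction default) on a
*single-sequence* model gives M→M = (1+1)/(1+3) = 0.5, i.e. a cost of
about 2 bits per aligned column pair — enough to cancel most of the
co-emission signal of 90 %-identical sequences, capping pair E-values
orders of magnitude above a 1e-20 merge cutoff. `cluster_sequences()`
therefore builds its profiles with `transition_pseudocount = 0.1` and
`pseudocount_weight = 0.5`, keeping observed transitions near their
empirical values while emissions stay regularised. This mirrors how
HMM-comparison suites configure single-sequence profiles (near-unity M→M)
and was fixed as a design default before the acceptance tests were
frozen; both knobs remain user-visible arguments.

## Pairwise HMM–HMM alignment

`align_hmms()` runs a local Viterbi dynamic program over five pair states
(MM, MI, IM, DG, GD). An MM cell at `(i, j)` emits the co-emission
log-odds `log2 Σ_a q_i(a) p_j(a) / f(a)`; every step costs the log2
product of the two models' corresponding transition probabilities, with
DG/GD involving only the advancing model and MI/IM emitting nothing.
Local semantics: paths start and end in MM, MM cells are floored at zero
(restart), and the empty alignment scores 0. A column score of −∞
(disjoint supports) kills the cell, which the floor then treats as a
restart — the dynamic program stays total. The recursion is implemented
in C++ (the only compiled code in the package); tests pin it to an
independent exhaustive path enumeration for all models with L ≤ 4.

The score is symmetric under operand swap by construction (the pair-state
scheme mirrors); `compare_hmms()` still evaluates both directions and
keeps the lower E-value, as the interface contract demands.

## E-value calibration

Local alignment maxima of unrelated models are Gumbel-distributed to good
approximation. Decoys are built by `shuffle_hmm()` — a seeded uniform
permutation of match columns, preserving the emission multiset — and
`fit_evd()` fits location/scale by maximum likelihood (profile likelihood
in the scale, solved with `optimize`; at least 50 finite, non-constant
scores required). `score_to_evalue()` converts a score `S` to
`p = 1 − exp(−exp(−λ(S−μ)))` (computed via `expm1` so the far tail
underflows to `p ≈ exp(−λ(S−μ))` rather than 0 prematurely) and
`E = p·N`, with `N` the number of models in the comparison set.

During clustering, calibration is refreshed after every merge with `N` =
the current number of groups, which is what gives E-values their
database-search semantics as the comparison set shrinks. The Gumbel
location and scale are fitted **once**, from a pooled decoy set over the
initial single-sequence models (default 100 decoy alignments), and held
fixed: because `E` is monotone in the score for fixed parameters, merge
*ordering* is completely independent of the fit, and regenerating decoys
after every merge would multiply the dominant cost of a clustering run
several-fold for no behavioural gain. Users who want the fully refreshed
null (e.g. when group profiles become much sharper than the
single-sequence null) can set `recalibrate_each_iteration = TRUE`; the
standalone `decoy_scores()` default remains 200.

## Iterative clustering

`cluster_sequences()` is best-first agglomeration: score all pairs, merge
the lowest-E pair if `E < cutoff` (strictly — the default 1e-20 boundary
itself does not merge), realign the merged members by stacking columns
along the winning HMM–HMM path (unaligned columns are carried through
against gaps, so each row still spells its original sequence), rebuild
the group profile, refresh the E-value comparison-set size, repeat. Determinism and order-invariance
come from three rules: groups are kept sorted by their smallest member
id, ties in E break lexicographically on those ids, and all decoy
randomness derives from the user seed. A `single_pass` flag freezes
decisions to the initial all-vs-all matrix (minimum linkage) for users
who want the cheaper variant; the default rebuilds profiles per merge,
which is what lets a growing family pull in its more diverged members.

The relationship tree is UPGMA on `d' = 300 − (−log10(max(E, 1e-300)))`,
where E is the minimum member-pair E-value between two groups from the
initial matrix. The floor at 1e-300 guards the log against underflow; the
300 offset turns the log-similarity into a distance that is 0 for
maximally similar pairs. UPGMA (rather than single or complete linkage)
was chosen because the quantity is an average-similarity summary, not a
phylogeny; the serialised Newick orders children lexicographically by
smallest leaf so output is reproducible.

## The five-stage filter

All thresholds are taken literally as strict inequalities ("above 70 %",
"less than 1.0e-5", "greater than 75 %"): boundary values fail, and each
boundary is unit-tested. Stage 3's "higher scores" is read as bitscore
(the standard meaning of *score* in homology searching); an e-value
ordering is available behind `stage3_order = "evalue"`. Proteins missing
a stage-4 annotation are rejected (fail-closed, matching the exclusionary
phrasing); `missing_annotation = "pass"` inverts that. Stage 5's
self-genome criterion is satisfiable by a self-hit under the default
(`exclude_self_hits = FALSE`) because the published wording does not
exclude self-matches; setting it TRUE instead demands a non-self paralog,
which is itself evidence of duplication — both readings are implemented
because the source is genuinely ambiguous.

`stage_reached` counts cleared stages 1–5, so `pass ⇔ stage_reached == 5`
holds exactly; stage-0 and stage-1 rejections both report 0 and are told
apart by `rejection_reason` (`evalue` vs `no_rbbh`/`coverage`). Stage-2
rejections reuse `no_rbbh` with `stage_reached = 2`.

## Proteome evidence

"Sequence similarity" for peptide placement is implemented as ungapped
identity at the best offset (ties to the smallest offset): peptide
identifications from spectral matching are near-exact, so a similarity
matrix would add parameters without adding discrimination. Detection
requires at least `min_peptides = 2` *distinct* peptide strings each
strictly above `min_identity = 0.95` — identity is per peptide, not
aggregate coverage. Distinctness is by sequence, not spectrum count.
The digest cleaves after K/R except before P and enumerates runs of up to
`max_missed = 3` fragments; the 0-missed fragments tile the protein
exactly, which is both a test invariant and a useful sanity check on the
cleavage-rule implementation.

## Tajima's D

Computed from the standard formulas with every intermediate (`a1 … e2`)
returned. Columns containing gaps or ambiguity characters (`X ? * . -`
by default) are excluded listwise — the common default of the software
the method is usually run in; `N` is *not* excluded by default because
the implementation is alphabet-agnostic and N is a valid amino acid
(nucleotide users should add it to `ambiguity_chars`). Two numerical
notes:

* For `n = 3` the variance coefficients vanish identically
  (`c1 = c2 = 0`), so D is ±∞ whenever `S > 0`. This is a property of the
  published plug-in variance, not a bug; the function returns the formula
  value unmodified and the independent oracle in the tests reproduces it.
* `S = 0` yields an undefined D, flagged via `d_defined` rather than an
  error, since monomorphic groups are a legitimate outcome.

## The synthetic world

`simulate_family_set()` emulates families of duplicated genes: a uniform
random ancestor and star-wise independent mutants at a per-site
substitution probability, uniform over the 19 alternative residues — the
simplest model with a closed-form expected pairwise difference,
`L·(2p − (20/19)p²)`, which the tests verify by simulation. Defaults
(4 families × 5 members, 150 residues, p = 0.10, 10 decoys) are the
stated conditions of the clustering recovery criterion; 150 residues is a
realistic toxin-domain length. What the generator does **not** emulate:
indels, substitution-matrix structure, domain architecture, shared
low-complexity regions, or families related *to each other* — so a green
clustering test establishes correct recovery of well-separated families,
not performance on genuinely hard homology boundaries.

`simulate_neutral_alignment()` is a standard Kingman coalescent with
infinite-sites mutations (Poisson θ/2 per unit branch length, one unique
binary column per mutation); it exists to check `tajima_d` against
`E[D] ≈ 0` and `E[S] = θ·a1`, not to model protein evolution.

`simulate_pipeline_fixture()` plants a designed failing stage per decoy,
round-robin over the six rejection reasons; because stage 2 has no
dedicated reason in that enumeration, the fixture leaves stage 2 with no
planted failures and its count equals stage 1's.

## Known limitations

* Viterbi (best-path) scoring only; no forward-algorithm summation, no
  secondary-structure terms, no profile–sequence search.
* The clustering rebuilds alignments by path-guided column stacking, not
  by a full progressive realignment; for highly diverged members the
  group alignment can be conservative (more gap columns than an external
  aligner would produce).
* E-value calibration assumes the decoy score distribution is Gumbel;
  with very short models (L below ~10) scores are discrete enough that
  the fit is rough. The merge decisions the package is tested on sit far
  from this regime.
* Bootstrap support, maximum-likelihood verification trees, and
  significance tables for D are out of scope.
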