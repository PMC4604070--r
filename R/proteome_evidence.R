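#' @name proteome_evidence
#' @title Peptide-level detection of predicted toxins
#'
#' @description
#' Decides which predicted toxins are detected in a venom proteome from a
#' list of identified peptide sequences: in-silico tryptic digestion with
#' missed cleavages, ungapped best-placement identity of each peptide
#' against each protein, a two-peptide >95 % identity detection rule, and a
#' contaminant screen against an endosymbiont proteome.
NULL

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and enumerates
#' all peptides spanning at most `max_missed` internal cleavage sites.
#'
#' @param protein a residue string, or a single-row `seq_set`.
#' @param max_missed maximum internal missed cleavage sites (default 3).
#' @return character vector of peptides ordered by start position then
#'   span; the 0-missed subset concatenates to the input sequence.
#' @export
tryptic_digest <- function(protein, max_missed = 3L) {
  if (is.data.frame(protein)) protein <- protein$residues[1]
  stopifnot(is.character(protein), nchar(protein) > 0, max_missed >= 0)
  s <- strsplit(toupper(protein), "")[[1]]
  n <- length(s)
  cut_after <- which(s %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & s[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- c(0L, setdiff(cut_after, n), n)  # fragment boundaries
  nf <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + max_missed)) {
      out <- c(out, paste(s[(bounds[i] + 1L):bounds[j + 1L]],
                          collapse = ""))
    }
  }
  out
}

#' Best ungapped placement of a peptide in a protein
#'
#' Slides the peptide over every offset of the protein and scores exact
#' residue matches; no gaps, no similarity matrix.
#'
#' @param peptide residue string, length <= protein length (longer is an
#'   error).
#' @param protein residue string or single-row `seq_set`.
#' @param protein_id id recorded in the result.
#' @return A `peptide_match`: list with `peptide`, `protein_id`, `identity`
#'   (matches / peptide length at the best offset), `placement_start`
#'   (0-based; smallest offset on ties).
#' @export
best_peptide_identity <- function(peptide, protein, protein_id = NA_character_) {
  if (is.data.frame(protein)) {
    if (is.na(protein_id)) protein_id <- protein$id[1]
    protein <- protein$residues[1]
  }
  if (nchar(peptide) > nchar(protein))
    stop("peptide longer than protein", call. = FALSE)
  pe <- utf8ToInt(toupper(peptide))
  pr <- utf8ToInt(toupper(protein))
  r <- best_offset_identity_cpp(pe, pr)
  structure(list(peptide = toupper(peptide), protein_id = protein_id,
                 identity = r$identity, placement_start = r$offset),
            class = "peptide_match")
}

#' Detect proteins from observed peptides
#'
#' A protein is detected iff at least `min_peptides` distinct observed
#' peptides each place in it with identity strictly greater than
#' `min_identity`. A peptide may support several proteins. Peptides longer
#' than a protein simply cannot support it.
#'
#' @param observed_peptides character vector of identified peptides.
#' @param proteins a `seq_set`.
#' @param min_identity identity threshold (strict >; default 0.95).
#' @param min_peptides required distinct supporting peptides (default 2).
#' @return list with `detected` (character ids) and `support` (data.frame
#'   `protein_id`, `peptide`, `identity`, `placement_start` of qualifying
#'   matches).
#' @export
detect_proteins <- function(observed_peptides, proteins,
                            min_identity = 0.95, min_peptides = 2L) {
  peps <- unique(toupper(observed_peptides))
  peps <- peps[nzchar(peps)]
  rows <- list()
  for (k in seq_len(nrow(proteins))) {
    prot <- proteins$residues[k]
    for (p in peps) {
      if (nchar(p) > nchar(prot)) next
      m <- best_peptide_identity(p, prot, proteins$id[k])
      if (m$identity > min_identity)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteins$id[k], peptide = p,
          identity = m$identity, placement_start = m$placement_start,
          stringsAsFactors = FALSE)
    }
  }
  support <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), peptide = character(0),
               identity = numeric(0), placement_start = integer(0),
               stringsAsFactors = FALSE)
  tab <- table(support$protein_id)
  list(detected = sort(names(tab)[tab >= min_peptides]), support = support)
}

#' Screen detected proteins against a contaminant proteome
#'
#' @param detected character vector of detected protein ids.
#' @param contaminant_hits `hit_table` of detected proteins vs the
#'   contaminant proteome.
#' @param evalue_cutoff flagging cutoff (strict <; default 1e-20).
#' @return character vector of flagged protein ids (empty for a clean run).
#' @export
screen_contaminants <- function(detected, contaminant_hits,
                                evalue_cutoff = 1e-20) {
  flagged <- contaminant_hits$query_id[contaminant_hits$evalue <
                                         evalue_cutoff]
  sort(intersect(detected, unique(flagged)))
}
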