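#' @name formats_io
#' @title Readers and writers for the toolkit's external formats
#'
#' @description
#' Plain-text I/O with strict validation: FASTA sequence sets, aligned FASTA,
#' tab-separated homology-search hit tables (12-column tabular dialect plus an
#' appended query-coverage column), per-protein annotation tables, plain-text
#' peptide lists, and Newick trees. Every reader rejects a file violating the
#' type invariants with an error locating the offense; nothing is silently
#' coerced.
NULL

fmt_stop <- function(path, line, msg) {
  where <- if (is.null(line)) path else sprintf("%s:%d", path, line)
  stop(sprintf("format error [%s]: %s", where, msg), call. = FALSE)
}

#' Read a FASTA file
#'
#' @param path path to a text FASTA file.
#' @return A `seq_set`: a data.frame with columns `id`, `description`,
#'   `residues`, one row per record, in file order.
#' @details Record ids must be unique and sequences non-empty; violations
#'   raise a located format error. `'.'` gap characters are normalised to
#'   `'-'` on read so the package has a single gap convention.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) fmt_stop(path, NULL, "no FASTA records found")
  if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1)]))))
    fmt_stop(path, 1L, "text before first '>' header")
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(length(hdr)); desc <- character(length(hdr))
  res <- character(length(hdr))
  for (k in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[k]])
    ids[k] <- sub("\\s.*$", "", h)
    desc[k] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    if (!nzchar(ids[k])) fmt_stop(path, hdr[k], "empty sequence id")
    body <- lines[seq.int(hdr[k] + 1L, ends[k])]
    if (hdr[k] + 1L > ends[k]) body <- character(0)
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    seq <- chartr(".", "-", toupper(seq))
    if (!nzchar(seq))
      fmt_stop(path, hdr[k], sprintf("empty sequence for id '%s'", ids[k]))
    res[k] <- seq
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    fmt_stop(path, NULL, sprintf("duplicate sequence id '%s'", dup[1]))
  structure(data.frame(id = ids, description = desc, residues = res,
                       stringsAsFactors = FALSE),
            class = c("seq_set", "data.frame"))
}

#' Write a FASTA file
#'
#' @param x a `seq_set` (or data.frame with `id`, `residues`, optionally
#'   `description`).
#' @param path output path.
#' @param width line-wrap width for residues (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(x)), width >= 1L)
  con <- file(path, "wb")  # binary: byte-stable newlines
  on.exit(close(con))
  for (k in seq_len(nrow(x))) {
    d <- if ("description" %in% names(x) && nzchar(x$description[k]))
      paste0(" ", x$description[k]) else ""
    writeLines(paste0(">", x$id[k], d), con, sep = "\n")
    s <- x$residues[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Construct an alignment from gapped sequences
#'
#' @param x a `seq_set` whose residues (with `-` gaps) all have equal length,
#'   or a named character vector of gapped sequences.
#' @return An `msa` object: list with `ids`, `seqs` (gapped strings),
#'   `n_rows`, `n_cols`.
#' @export
as_alignment <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    x <- data.frame(id = ids, residues = unname(x), stringsAsFactors = FALSE)
  }
  seqs <- chartr(".", "-", toupper(x$residues))
  lens <- nchar(seqs)
  if (nrow(x) < 1L) stop("alignment must have at least one row", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  if (any(gsub("-", "", seqs) == ""))
    stop("alignment row is all gaps: ",
         x$id[which(gsub("-", "", seqs) == "")[1]], call. = FALSE)
  structure(list(ids = x$id, seqs = seqs,
                 n_rows = nrow(x), n_cols = lens[1]),
            class = "msa")
}

#' Read an aligned FASTA file
#' @inheritParams read_fasta
#' @return An `msa` object.
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))

#' Character matrix view of an alignment
#' @param aln an `msa`.
#' @return character matrix, rows = sequences (rownames = ids).
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Write an alignment as aligned FASTA
#' @param aln an `msa`.
#' @param path output path.
#' @param width wrap width.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  write_fasta(data.frame(id = aln$ids, residues = aln$seqs,
                         stringsAsFactors = FALSE), path, width = width)
}

HIT_COLS <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start",
              "s_end", "evalue", "bitscore", "query_coverage")

#' Read a homology-search hit table
#'
#' Tab-separated, 12 standard tabular columns plus a 13th query-coverage
#' column; no header by default.
#'
#' @param path path to the table.
#' @param header logical; skip a header line.
#' @param coverage_unit `"fraction"` (0-1, default) or `"percent"` (0-100,
#'   divided by 100 on read). Coverage is always a fraction internally.
#' @return A `hit_table` data.frame with the 13 named columns plus `rank`:
#'   the 1-based rank of each subject among its query's hits by ascending
#'   e-value (ties: higher bitscore, then lexicographic subject id).
#' @export
read_hit_table <- function(path, header = FALSE,
                           coverage_unit = c("fraction", "percent")) {
  coverage_unit <- match.arg(coverage_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  off <- if (header) 1L else 0L
  n <- length(lines)
  if (n == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 13), HIT_COLS))
    df$rank <- integer(0)
    return(structure(df, class = c("hit_table", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 13L))
    fmt_stop(path, which(nc != 13L)[1] + off,
             sprintf("expected 13 tab-separated columns, found %d",
                     nc[which(nc != 13L)[1]]))
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  for (k in 3:13) {
    v <- suppressWarnings(as.numeric(m[, k]))
    bad <- which(is.na(v))
    if (length(bad))
      fmt_stop(path, bad[1] + off,
               sprintf("non-numeric value '%s' in column %d (%s)",
                       m[bad[1], k], k, HIT_COLS[k]))
    df[[HIT_COLS[k]]] <- v
  }
  if (any(df$evalue < 0))
    fmt_stop(path, which(df$evalue < 0)[1] + off, "negative e-value")
  if (coverage_unit == "percent") df$query_coverage <- df$query_coverage / 100
  if (any(df$query_coverage < 0 | df$query_coverage > 1))
    fmt_stop(path, which(df$query_coverage < 0 | df$query_coverage > 1)[1] + off,
             "query coverage outside [0, 1]")
  rank_hits(df)
}

#' Recompute per-query hit ranks
#'
#' @param hits a hit-table data.frame.
#' @return the table with a `rank` column: 1-based per-query rank by
#'   ascending e-value, ties broken by descending bitscore then lexicographic
#'   subject id.
#' @export
rank_hits <- function(hits) {
  o <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  structure(hits, class = unique(c("hit_table", class(hits))))
}

#' Write a hit table
#' @param hits a `hit_table`.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- HIT_COLS[HIT_COLS %in% names(hits)]
  m <- hits[, cols, drop = FALSE]
  # render e-values/numbers compactly but losslessly
  fmt <- vapply(seq_len(nrow(m)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- m[[cn]][i]
      if (is.numeric(v)) format(v, digits = 15, scientific = NA, trim = TRUE)
      else as.character(v)
    }, ""), collapse = "\t")
  }, "")
  con <- file(path, "wb"); on.exit(close(con))
  if (length(fmt)) writeLines(fmt, con, sep = "\n")
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' Tab-separated with a header line: `protein_id`, `tm_count`, `domain_ok`,
#' `go_excluded`, `is_toxin_subject`.
#'
#' @param path path to the table.
#' @return data.frame with those columns; logicals parsed from TRUE/FALSE/1/0.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tm_count", "domain_ok", "go_excluded",
            "is_toxin_subject")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fmt_stop(path, 1L, paste("missing annotation columns:",
                             paste(miss, collapse = ", ")))
  if (anyDuplicated(df$protein_id))
    fmt_stop(path, NULL, sprintf("duplicate annotation for protein '%s'",
                                 df$protein_id[duplicated(df$protein_id)][1]))
  df$tm_count <- as.integer(df$tm_count)
  if (any(is.na(df$tm_count) | df$tm_count < 0))
    fmt_stop(path, NULL, "tm_count must be a non-negative integer")
  for (cn in c("domain_ok", "go_excluded", "is_toxin_subject"))
    df[[cn]] <- as.logical(df[[cn]])
  df[, need]
}

#' Read a plain-text peptide list (one peptide per line)
#' @param path path to the list.
#' @return character vector of uppercase peptides.
#' @export
read_peptides <- function(path) {
  p <- toupper(trimws(readLines(path, warn = FALSE)))
  p <- p[nzchar(p)]
  bad <- grep("[^A-Z]", p)
  if (length(bad)) fmt_stop(path, bad[1], "non-residue character in peptide")
  p
}

## ---- trees ------------------------------------------------------------

#' Tree node constructors
#'
#' Trees are nested lists: a leaf has a `label`; an internal node has
#' `children` and a `height` (ultrametric node height; branch length to a
#' child = height difference).
#'
#' @param label leaf label.
#' @param children list of child nodes.
#' @param height node height (>= every child's height).
#' @return a `dup_tree` node.
#' @export
tree_leaf <- function(label) {
  if (is.null(label) || !nzchar(label)) stop("unlabelled leaf", call. = FALSE)
  structure(list(label = label, height = 0), class = "dup_tree")
}

#' @rdname tree_leaf
#' @export
tree_node <- function(children, height) {
  stopifnot(length(children) >= 2, height >= 0)
  structure(list(children = children, height = height), class = "dup_tree")
}

tree_leaves <- function(node) {
  if (!is.null(node$label)) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' Serialise a tree to Newick
#'
#' Child ordering is deterministic: children are sorted lexicographically by
#' their smallest leaf label.
#'
#' @param tree a `dup_tree`.
#' @return a Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  rec <- function(node, parent_height) {
    bl <- parent_height - node$height
    if (!is.null(node$label)) {
      lab <- node$label
      if (is.null(parent_height)) return(lab)
      return(sprintf("%s:%s", lab, format(bl, digits = 10, trim = TRUE)))
    }
    keys <- vapply(node$children, function(ch) min(tree_leaves(ch)), "")
    kids <- node$children[order(keys)]
    inner <- paste(vapply(kids, rec, "", parent_height = node$height),
                   collapse = ",")
    if (is.null(parent_height)) return(sprintf("(%s)", inner))
    sprintf("(%s):%s", inner, format(bl, digits = 10, trim = TRUE))
  }
  if (!is.null(tree$label)) return(paste0(tree$label, ";"))
  paste0(rec(tree, NULL), ";")
}
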