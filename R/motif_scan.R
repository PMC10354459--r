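# RNP1/RNP2 consensus-motif scanning in candidate protein sequences. The
# RRM (RNA recognition motif) domain exposes two short ribonucleoprotein
# consensus sequences on its beta-sheet surface; flagging them in unique
# binders highlights candidates that plausibly contact RNA the way known
# m5C readers do.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default RNP1/RNP2 degenerate consensus patterns
#'
#' Literature consensus for the two ribonucleoprotein motifs of the RRM
#' beta-sheet: RNP1 (octamer, on beta3) `[RK]-G-[FY]-[GA]-[FY]-[ILVM]-x-[FY]`
#' and RNP2 (hexamer, on beta1) `[ILVM]-[FY]-[ILVM]-x-N-L`. `x` matches any
#' residue; bracketed classes list the allowed residues. Both patterns can
#' be overridden, e.g. via [read_motif_patterns()].
#'
#' @return Named character vector of degenerate patterns.
#' @export
default_rnp_patterns <- function() {
  c(RNP1 = "[RK]G[FY][GA][FY][ILVM]x[FY]",
    RNP2 = "[ILVM][FY][ILVM]xNL")
}

# degenerate pattern -> perl regex body ("x" -> ".")
pattern_to_regex <- function(pattern) gsub("x", ".", pattern, fixed = TRUE)

# number of positions a degenerate pattern spans (a class counts as one)
pattern_width <- function(pattern) {
  nchar(gsub("\\[[A-Z]+\\]", "Z", pattern))
}

validate_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern) ||
      !grepl("^(x|[A-Z]|\\[[A-Z]+\\])+$", pattern)) {
    abort_mr("malformed motif pattern '%s': use amino-acid letters, 'x', and bracketed classes", pattern)
  }
  letters_used <- unique(strsplit(gsub("\\[|\\]|x", "", pattern), "")[[1]])
  bad <- setdiff(letters_used, AA_LETTERS)
  if (length(bad) > 0) {
    abort_mr("pattern '%s' uses non-amino-acid letter(s): %s", pattern,
             paste(bad, collapse = ", "))
  }
  invisible(pattern)
}

#' Scan one protein sequence for RNP consensus motifs
#'
#' Reports every (possibly overlapping) match of each degenerate pattern,
#' left to right. The sequence must be over the 20-letter amino-acid
#' alphabet; `X` (unknown residue) is tolerated but never matches a
#' constrained position — it can only sit under an `x` (any-residue)
#' pattern position.
#'
#' @param sequence Amino-acid string.
#' @param patterns Named character vector of degenerate patterns (default
#'   [default_rnp_patterns()]).
#' @return Data frame with columns `motif`, `start` (0-based, half-open
#'   interval start) and `matched` (the matching substring). Zero rows if
#'   nothing matches.
#' @export
scan_rnp_motifs <- function(sequence, patterns = default_rnp_patterns()) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort_mr("sequence must be a single string")
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% c(AA_LETTERS, "X")))
  if (length(bad) > 0) {
    abort_mr("illegal character '%s' at position %d (1-based) in sequence",
             chars[bad[1]], bad[1])
  }
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    abort_mr("patterns must be named")
  }
  hits <- list()
  for (nm in names(patterns)) {
    validate_pattern(patterns[[nm]])
    width <- pattern_width(patterns[[nm]])
    # lookahead regex finds overlapping matches; X must not satisfy a
    # constrained position, and classes never contain X, so no special case
    rx <- paste0("(?=", pattern_to_regex(patterns[[nm]]), ")")
    m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (length(starts) == 0) next
    hits[[nm]] <- data.frame(
      motif = nm,
      start = starts - 1L,
      matched = substring(sequence, starts, starts + width - 1L),
      stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0) {
    return(data.frame(motif = character(0), start = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Read motif patterns from a pattern file
#'
#' One motif per line: `motif_name TAB degenerate_pattern`, with character
#' classes in brackets and `x` for any residue.
#'
#' @param path Pattern file path.
#' @return Named character vector of patterns.
#' @export
read_motif_patterns <- function(path) {
  if (!file.exists(path)) abort_mr("pattern file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort_mr("pattern file lines must be 'motif_name TAB pattern'")
  }
  pats <- vapply(parts, `[`, character(1), 2)
  names(pats) <- vapply(parts, `[`, character(1), 1)
  for (p in pats) validate_pattern(p)
  pats
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector; names are the FASTA ids truncated at the
#'   first whitespace.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort_mr("FASTA file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Flag RRM consensus motifs in unique-binder candidates
#'
#' Joins each unique-binder candidate to a supplied protein sequence by
#' gene name (exact match after case normalization) and reports whether
#' the sequence carries RNP1 and/or RNP2 consensus matches. Candidates
#' without a supplied sequence are reported as unmatched, not treated as
#' errors.
#'
#' @param unique_sets A [unique_binders()] result.
#' @param sequences Named character vector of amino-acid sequences (e.g.
#'   from [read_protein_fasta()]), names joinable to candidate gene names.
#' @param pg The matching [protein_groups()] object providing the
#'   `group_id -> gene_name` mapping.
#' @param patterns Degenerate patterns, default [default_rnp_patterns()].
#' @return List with `flags` (data frame: `group_id`, `gene_name`,
#'   `modification`, `has_RNP1`, `has_RNP2`) for candidates with a
#'   sequence, and `unmatched` (data frame: `group_id`, `gene_name`,
#'   `modification`) for those without.
#' @export
flag_rrm_candidates <- function(unique_sets, sequences, pg,
                                patterns = default_rnp_patterns()) {
  if (is.null(names(sequences))) abort_mr("sequences must be named")
  seq_names <- toupper(names(sequences))
  flag_rows <- list()
  unmatched_rows <- list()
  for (m in rna_modifications()) {
    for (gid in unique_sets$unique[[m]]) {
      gene <- pg$info$gene_name[match(gid, pg$info$group_id)]
      idx <- if (!is.na(gene) && nzchar(gene)) match(toupper(gene), seq_names) else NA_integer_
      if (is.na(idx)) {
        unmatched_rows[[length(unmatched_rows) + 1L]] <- data.frame(
          group_id = gid, gene_name = ifelse(is.na(gene), "", gene),
          modification = m, stringsAsFactors = FALSE)
        next
      }
      h <- scan_rnp_motifs(sequences[[idx]], patterns)
      flag_rows[[length(flag_rows) + 1L]] <- data.frame(
        group_id = gid, gene_name = gene, modification = m,
        has_RNP1 = "RNP1" %in% h$motif, has_RNP2 = "RNP2" %in% h$motif,
        stringsAsFactors = FALSE)
    }
  }
  empty_flags <- data.frame(group_id = character(0), gene_name = character(0),
                            modification = character(0), has_RNP1 = logical(0),
                            has_RNP2 = logical(0), stringsAsFactors = FALSE)
  empty_un <- data.frame(group_id = character(0), gene_name = character(0),
                         modification = character(0), stringsAsFactors = FALSE)
  list(flags = if (length(flag_rows)) do.call(rbind, flag_rows) else empty_flags,
       unmatched = if (length(unmatched_rows)) do.call(rbind, unmatched_rows) else empty_un)
}
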