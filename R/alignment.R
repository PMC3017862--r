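#' Family alignment objects
#'
#' A `family_alignment` holds one subfamily's ortholog alignment: a character
#' matrix of aligned residues (rows = sequences, columns = alignment columns,
#' `-` for gaps), row annotations (`seq_id`, `species`, `source`) and the index
#' of the single reference row. The reference row anchors every downstream
#' report: alignment columns are translated to reference residue numbers
#' (1-based) via [column_to_reference()].
#'
#' @param seqs Character vector of equal-length aligned sequences, or a
#'   character matrix of single residues.
#' @param seq_id,species,source Row annotations; `source` must contain the
#'   value `"reference"` exactly once.
#' @param family_id Name of the reference protein this family is anchored to.
#' @return An object of class `family_alignment`.
#' @examples
#' aln <- family_alignment(c("MAD-", "MAE-", "M-DC"),
#'   seq_id = c("ref", "s1", "s2"),
#'   species = c("A.thaliana", "sp1", "sp2"),
#'   source = c("reference", "blast", "blast"),
#'   family_id = "FAM1")
#' alignment_length(aln)
#' @export
family_alignment <- function(seqs, seq_id, species, source, family_id = "family") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort("all aligned sequences must have identical length (ragged input)")
    }
    mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  }
  n <- nrow(mat)
  stopifnot(length(seq_id) == n, length(species) == n, length(source) == n)
  if (anyDuplicated(seq_id)) abort("seq_id values must be unique")
  ref <- which(source == "reference")
  if (length(ref) != 1L) {
    abort(sprintf("expected exactly one row with source = 'reference', found %d",
                  length(ref)))
  }
  bad <- setdiff(unique(as.vector(mat)), c(AA20, GAP))
  if (length(bad)) {
    warn(sprintf("non-standard residue characters treated as gaps: %s",
                 paste(bad, collapse = " ")))
  }
  structure(
    list(family_id = family_id, seq_id = as.character(seq_id),
         species = as.character(species), source = as.character(source),
         seqs = mat, reference_row = ref),
    class = "family_alignment"
  )
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("<family_alignment> %s: %d sequences x %d columns (reference: %s)\n",
              x$family_id, nrow(x$seqs), ncol(x$seqs),
              x$seq_id[x$reference_row]))
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `family_alignment`.
#' @export
alignment_length <- function(aln) ncol(aln$seqs)

#' Number of sequences in an alignment
#' @param aln A `family_alignment` or `paired_alignment`.
#' @export
alignment_nrow <- function(aln) {
  if (inherits(aln, "paired_alignment")) nrow(aln$seqs_a) else nrow(aln$seqs)
}

#' Read an aligned FASTA file into a family_alignment
#'
#' Headers follow the dialect `seq_id|species|source` where source is one of
#' `interpro`, `blast`, `genome`, `reference`; exactly one row must be the
#' reference. All rows must have equal length (the file is an alignment, not a
#' sequence set).
#'
#' @param path Path to an aligned FASTA file.
#' @param family_id Family name; defaults to the reference row's seq_id.
#' @return A `family_alignment`.
#' @export
read_alignment <- function(path, family_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort("empty FASTA file")
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    abort("ragged FASTA: rows have unequal lengths, not a valid alignment")
  }
  fields <- stringr::str_split_fixed(names(set), stringr::fixed("|"), 3)
  if (any(fields[, 3] == "")) {
    abort("FASTA headers must follow the dialect seq_id|species|source")
  }
  aln <- family_alignment(as.character(set),
                          seq_id = fields[, 1], species = fields[, 2],
                          source = fields[, 3],
                          family_id = family_id %||% fields[fields[, 3] == "reference", 1][1])
  aln
}

#' Write a family_alignment to aligned FASTA
#'
#' @param aln A `family_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- paste(aln$seq_id, aln$species, aln$source, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' The residue number of a column is the count of non-gap reference characters
#' up to and including that column; columns where the reference has a gap map
#' to `NA`.
#'
#' @param aln A `family_alignment`.
#' @param column Integer vector of column indices (1-based).
#' @return Integer vector of reference residue numbers (`NA` at reference gaps).
#' @examples
#' aln <- family_alignment(c("M-AD", "MKAD"), c("r", "s"), c("at", "sp"),
#'                         c("reference", "blast"))
#' column_to_reference(aln, 1:4)  # 1 NA 2 3
#' @export
column_to_reference <- function(aln, column) {
  L <- alignment_length(aln)
  if (any(column < 1L | column > L)) {
    abort(sprintf("column out of range 1..%d", L))
  }
  ref <- aln$seqs[aln$reference_row, ]
  counts <- cumsum(ref != GAP)
  out <- counts[column]
  out[ref[column] == GAP] <- NA_integer_
  as.integer(out)
}

#' Map reference residue numbers to alignment columns
#'
#' Inverse of [column_to_reference()] on the reference's ungapped range.
#'
#' @param aln A `family_alignment`.
#' @param residue Integer vector of reference residue numbers.
#' @return Integer vector of alignment columns.
#' @export
reference_to_column <- function(aln, residue) {
  ref <- aln$seqs[aln$reference_row, ]
  cols <- which(ref != GAP)
  if (any(residue < 1L | residue > length(cols))) {
    abort(sprintf("residue out of range 1..%d", length(cols)))
  }
  cols[residue]
}

#' Ungapped length of the reference sequence
#' @param aln A `family_alignment`.
#' @export
reference_length <- function(aln) {
  sum(aln$seqs[aln$reference_row, ] != GAP)
}

#' Pairwise sequence identity over an aligned row pair
#'
#' Identity is the fraction of columns with identical residues among columns
#' where at least one row has a residue; a gap aligned to a residue counts as
#' non-identical, and gap-gap columns are excluded from the denominator by
#' default (set `count_gap_gap = TRUE` to count them as non-identical too).
#'
#' @param a,b Aligned sequences (equal-length strings or character vectors).
#' @param count_gap_gap Include gap-gap columns in the denominator?
#' @return Fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACD", "ACE")  # 2/3
#' pairwise_identity("A-C", "ABC")  # 2/3: the gap column counts, non-identical
#' @export
pairwise_identity <- function(a, b, count_gap_gap = FALSE) {
  a <- as_residue_vector(a)
  b <- as_residue_vector(b)
  if (length(a) != length(b)) abort("rows must have equal aligned length")
  both_gap <- a == GAP & b == GAP
  counted <- if (count_gap_gap) rep(TRUE, length(a)) else !both_gap
  if (!any(counted)) abort("identity undefined: both rows are all-gap")
  ident <- a == b & a != GAP
  sum(ident[counted]) / sum(counted)
}

as_residue_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1]] else x
}

#' Paired alignment of two interacting subfamilies
#'
#' One row per ortholog pair: the two members of a row share a species, and
#' positions are reported as (molecule, column) so the two column namespaces
#' stay disjoint. Built from two family alignments plus a table of row pairs.
#'
#' @param aln_a,aln_b `family_alignment` objects for the two subfamilies.
#' @param row_pairs Tibble with columns `seq_id_a`, `seq_id_b` selecting rows;
#'   defaults to the per-species Cartesian product
#'   (see [build_intermolecular_pairs()]).
#' @param interacting Logical label of the reference pair.
#' @return An object of class `paired_alignment`.
#' @export
pair_alignments <- function(aln_a, aln_b, row_pairs = NULL, interacting = TRUE) {
  if (is.null(row_pairs)) {
    row_pairs <- build_intermolecular_pairs(
      tibble(seq_id = aln_a$seq_id, species = aln_a$species),
      tibble(seq_id = aln_b$seq_id, species = aln_b$species)
    )
  }
  ia <- match(row_pairs$seq_id_a, aln_a$seq_id)
  ib <- match(row_pairs$seq_id_b, aln_b$seq_id)
  if (anyNA(ia) || anyNA(ib)) abort("row_pairs reference unknown seq_ids")
  sp_a <- aln_a$species[ia]
  sp_b <- aln_b$species[ib]
  if (!all(sp_a == sp_b)) abort("both members of a row pair must share a species")
  ref <- which(ia == aln_a$reference_row & ib == aln_b$reference_row)
  structure(
    list(family_ids = c(aln_a$family_id, aln_b$family_id),
         seq_id_a = aln_a$seq_id[ia], seq_id_b = aln_b$seq_id[ib],
         species = sp_a,
         seqs_a = aln_a$seqs[ia, , drop = FALSE],
         seqs_b = aln_b$seqs[ib, , drop = FALSE],
         reference_row = if (length(ref)) ref[1] else NA_integer_,
         ref_a = aln_a$seqs[aln_a$reference_row, ],
         ref_b = aln_b$seqs[aln_b$reference_row, ],
         interacting = isTRUE(interacting)),
    class = "paired_alignment"
  )
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat(sprintf("<paired_alignment> %s - %s: %d row pairs (%d + %d columns), %s\n",
              x$family_ids[1], x$family_ids[2], nrow(x$seqs_a),
              ncol(x$seqs_a), ncol(x$seqs_b),
              if (x$interacting) "interacting" else "non-interacting"))
  invisible(x)
}

# Column -> reference residue maps for a paired alignment, one per molecule.
paired_reference_positions <- function(pa) {
  ref_map <- function(ref) {
    counts <- cumsum(ref != GAP)
    out <- counts
    out[ref == GAP] <- NA_integer_
    as.integer(out)
  }
  list(a = ref_map(pa$ref_a), b = ref_map(pa$ref_b))
}
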