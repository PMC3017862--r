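#' Read motif annotations
#'
#' TSV with header `motif_id protein start end partner_motif_id`; intervals are
#' closed and 1-based in reference residue coordinates. The partner relation
#' pairs complementary motifs across the two proteins of an interaction and
#' must be symmetric.
#'
#' @param path File path.
#' @return A tibble of motifs.
#' @export
read_motifs <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         motif_id = "c", protein = "c", start = "i",
                         end = "i", partner_motif_id = "c"))
  validate_motifs(m)
}

validate_motifs <- function(m) {
  if (any(m$start > m$end)) abort("motif intervals must satisfy start <= end")
  if ("partner_motif_id" %in% names(m)) {
    has <- !is.na(m$partner_motif_id)
    back <- m$partner_motif_id[match(m$motif_id[has], m$motif_id)]
    partner_of_partner <- m$partner_motif_id[match(m$partner_motif_id[has], m$motif_id)]
    if (any(is.na(partner_of_partner)) ||
        any(partner_of_partner != m$motif_id[has])) {
      abort("partner_motif_id relation must be symmetric")
    }
  }
  m
}

#' Read SNP records
#'
#' TSV with header `protein position class` (class is `synonymous` or
#' `non-synonymous`); an optional `set` column labels the analysis set the
#' protein belongs to (for example `interacting` / `non-interacting`).
#'
#' @param path File path.
#' @return A tibble of SNP records.
#' @export
read_snps <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  s$position <- as.integer(s$position)
  bad <- setdiff(unique(s$class), c("synonymous", "non-synonymous"))
  if (length(bad)) {
    abort(sprintf("invalid SNP class values: %s", paste(bad, collapse = ", ")))
  }
  s
}

#' Read per-residue coiled-coil probability tracks
#'
#' TSV with header `protein position probability`; probabilities in \[0, 1\].
#'
#' @param path File path.
#' @return A tibble with one row per residue.
#' @export
read_coil_tracks <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         protein = "c", position = "i", probability = "d"))
  if (any(t$probability < 0 | t$probability > 1)) {
    abort("coil probabilities must lie in [0, 1]")
  }
  t
}

#' Write annotation tables
#'
#' Thin TSV writers mirroring [read_motifs()], [read_snps()] and
#' [read_coil_tracks()].
#'
#' @param x Tibble to write.
#' @param path File path.
#' @export
write_annotation <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
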