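#' Homology map from a master alignment of the reference proteins
#'
#' The master alignment (one aligned row per reference protein) defines which
#' residues of different family members are homologous: residue `r` of protein
#' X and residue `s` of protein Y are homologous when they sit in the same
#' master column. The map is a bijection between each protein's residues and
#' its non-gap master columns.
#'
#' @param master Named character vector of equal-length aligned reference
#'   sequences (names = protein ids), or a `family_alignment` whose `seq_id`s
#'   are the protein ids.
#' @return Tibble of class `homology_map`: `protein`, `residue`, `column`.
#' @export
build_homology_map <- function(master) {
  if (inherits(master, "family_alignment")) {
    seqs <- apply(master$seqs, 1, paste, collapse = "")
    names(seqs) <- master$seq_id
    master <- seqs
  }
  if (is.null(names(master)) || any(names(master) == "")) {
    abort("master alignment rows must be named by protein")
  }
  if (length(unique(nchar(master))) != 1L) abort("ragged master alignment")
  out <- purrr::imap_dfr(master, function(seq, prot) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    cols <- which(chars != GAP)
    tibble(protein = prot, residue = seq_along(cols), column = cols)
  })
  class(out) <- c("homology_map", class(out))
  out
}

#' Map residues of one protein to homologous residues of another
#'
#' @param hmap A `homology_map`.
#' @param protein_from,protein_to Protein ids.
#' @param residue Integer vector of residues of `protein_from`.
#' @return Integer vector of residues of `protein_to` (`NA` where the master
#'   column is a gap in `protein_to`, i.e. unmappable).
#' @export
map_homologous_position <- function(hmap, protein_from, residue, protein_to) {
  from <- hmap[hmap$protein == protein_from, ]
  to <- hmap[hmap$protein == protein_to, ]
  cols <- from$column[match(residue, from$residue)]
  to$residue[match(cols, to$column)]
}

#' Classify conservation of correlated pairs across family members
#'
#' A correlated pair (p, q) of protein X is `conserved` in protein Y when both
#' positions map through the master alignment and the mapped pair is itself a
#' correlated pair of Y; `not_conserved` when both map but the pair is absent;
#' `unmappable` when either position falls on a gap in Y.
#'
#' @param pairs_by_protein Tibble of intramolecular pairs with columns
#'   `protein`, `pos_1`, `pos_2` (reference residue coordinates); typically
#'   built by stacking [detect_correlated_pairs()] results over proteins.
#' @param hmap A `homology_map` covering the analyzed proteins.
#' @param proteins Proteins to compare against; default: all proteins present
#'   in `pairs_by_protein`.
#' @return Tibble of class `conservation_calls`: `protein`, `pos_1`, `pos_2`,
#'   `other_protein`, `status`.
#' @export
classify_conservation <- function(pairs_by_protein, hmap, proteins = NULL) {
  proteins <- proteins %||% unique(pairs_by_protein$protein)
  pair_key <- function(prot, a, b) paste(prot, pmin(a, b), pmax(a, b))
  all_keys <- pair_key(pairs_by_protein$protein,
                       pairs_by_protein$pos_1, pairs_by_protein$pos_2)
  purrr::map_dfr(seq_len(nrow(pairs_by_protein)), function(i) {
    x <- pairs_by_protein$protein[i]
    p <- pairs_by_protein$pos_1[i]
    q <- pairs_by_protein$pos_2[i]
    others <- setdiff(proteins, x)
    purrr::map_dfr(others, function(y) {
      mp <- map_homologous_position(hmap, x, p, y)
      mq <- map_homologous_position(hmap, x, q, y)
      status <- if (is.na(mp) || is.na(mq)) {
        "unmappable"
      } else if (pair_key(y, mp, mq) %in% all_keys) {
        "conserved"
      } else {
        "not_conserved"
      }
      tibble(protein = x, pos_1 = p, pos_2 = q, other_protein = y,
             status = status)
    })
  }) |>
    structure(class = c("conservation_calls", class(tibble())))
}

#' Summarise conservation calls per pair and overall
#'
#' @param calls A `conservation_calls` tibble.
#' @return List with `per_pair` (one row per pair: `conserved_any`,
#'   `n_conserved`, `n_mappable`), `fraction_conserved` (fraction of pairs,
#'   among those mappable in at least one other protein, conserved in at least
#'   one) and `n_excluded` (pairs unmappable everywhere).
#' @export
summarize_conservation <- function(calls) {
  per_pair <- calls |>
    dplyr::group_by(.data$protein, .data$pos_1, .data$pos_2) |>
    dplyr::summarise(
      n_conserved = sum(.data$status == "conserved"),
      n_mappable = sum(.data$status != "unmappable"),
      conserved_any = .data$n_conserved > 0, .groups = "drop")
  mappable <- per_pair[per_pair$n_mappable > 0, ]
  list(per_pair = per_pair,
       fraction_conserved = mean(mappable$conserved_any),
       n_excluded = sum(per_pair$n_mappable == 0))
}

#' Shannon entropy of an alignment column
#'
#' `S_k = -sum_j P_jk ln P_jk` over the 20 amino acids, where `P_jk` is the
#' frequency of amino acid `j` at column `k` among non-gap residues (gaps are
#' excluded and the frequencies renormalised). Reported in nats; range
#' 0 to ln 20.
#'
#' @param aln A `family_alignment`.
#' @param column Column index (vectorised).
#' @return Numeric entropy values.
#' @export
column_entropy <- function(aln, column) {
  vapply(column, function(k) {
    residues <- aln$seqs[, k]
    residues <- residues[residues %in% AA20]
    if (length(residues) == 0L) abort(sprintf("column %d is all-gap", k))
    p <- table(residues) / length(residues)
    -sum(p * log(p))
  }, numeric(1))
}

#' Entropy comparison between conserved and non-conserved correlated positions
#'
#' For every correlated position p of protein X and every other protein Y in
#' which the homologous position maps but carries no correlated mutation, one
#' case is recorded: the entropy of p's column in X versus the entropy of the
#' homologous column in Y. Cases are summarised separately for positions
#' belonging to at least one conserved pair (`conserved`) and for positions of
#' never-conserved pairs (`not_conserved`): mean and sd of both entropies and
#' the fraction of cases where the correlated position is strictly more
#' variable than its homolog.
#'
#' @param calls A `conservation_calls` tibble.
#' @param alignments Named list of `family_alignment`s keyed by protein.
#' @param hmap The `homology_map` used for the calls.
#' @return List with `cases` (one row per case) and `summary` (one row per
#'   conservation class) of class `entropy_comparison`.
#' @export
entropy_comparison <- function(calls, alignments, hmap) {
  per_pair <- summarize_conservation(calls)$per_pair
  # position-level conservation: a position is 'conserved' when it belongs to
  # >= 1 pair conserved in >= 1 other protein
  pos_class <- dplyr::bind_rows(
    dplyr::transmute(per_pair, protein = .data$protein,
                     position = .data$pos_1, conserved = .data$conserved_any),
    dplyr::transmute(per_pair, protein = .data$protein,
                     position = .data$pos_2, conserved = .data$conserved_any)
  ) |>
    dplyr::group_by(.data$protein, .data$position) |>
    dplyr::summarise(conserved = any(.data$conserved), .groups = "drop")

  cm_pos_key <- paste(pos_class$protein, pos_class$position)
  proteins <- unique(calls$other_protein)
  entropy_at <- function(prot, residue) {
    aln <- alignments[[prot]]
    column_entropy(aln, reference_to_column(aln, residue))
  }
  cases <- purrr::map_dfr(seq_len(nrow(pos_class)), function(i) {
    x <- pos_class$protein[i]
    p <- pos_class$position[i]
    purrr::map_dfr(setdiff(proteins, x), function(y) {
      mp <- map_homologous_position(hmap, x, p, y)
      if (is.na(mp) || paste(y, mp) %in% cm_pos_key) return(tibble())
      tibble(protein = x, position = p,
             conserved = pos_class$conserved[i],
             other_protein = y, homolog_position = mp,
             entropy_self = entropy_at(x, p),
             entropy_homolog = entropy_at(y, mp))
    })
  })
  summary <- cases |>
    dplyr::group_by(class = ifelse(.data$conserved, "conserved", "not_conserved")) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      mean_self = mean(.data$entropy_self), sd_self = sd(.data$entropy_self),
      mean_homolog = mean(.data$entropy_homolog),
      sd_homolog = sd(.data$entropy_homolog),
      frac_self_higher = mean(.data$entropy_self > .data$entropy_homolog),
      .groups = "drop")
  structure(list(cases = cases, summary = summary),
            class = "entropy_comparison")
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat("<entropy_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' Conserved groups of intermolecular correlated positions
#'
#' Intermolecular correlated position pairs are mapped into master coordinates
#' through the homology map; a conserved group is a mapped position pair
#' observed in more than one interaction pair. Groups are counted separately
#' for the interacting and the non-interacting analysis sets, alongside the
#' total number of correlated pairs per set.
#'
#' @param pairs Tibble with `interaction_id`, `interacting` (logical),
#'   `protein_1`, `pos_1`, `protein_2`, `pos_2`.
#' @param hmap A `homology_map` covering all proteins involved.
#' @return List with `groups` (one row per conserved group: `set`,
#'   `master_pos_1`, `master_pos_2`, `n_interaction_pairs`, `members`) and
#'   `counts` (per set: `n_groups`, `n_pairs_total`, `groups_per_pair_pct`).
#' @export
intermolecular_conserved_groups <- function(pairs, hmap) {
  to_master <- function(prot, res) {
    sub <- hmap[hmap$protein == prot, ]
    sub$column[match(res, sub$residue)]
  }
  m1 <- purrr::map2_int(pairs$protein_1, pairs$pos_1, function(p, r) {
    v <- to_master(p, r); if (length(v) == 0 || is.na(v)) NA_integer_ else as.integer(v)
  })
  m2 <- purrr::map2_int(pairs$protein_2, pairs$pos_2, function(p, r) {
    v <- to_master(p, r); if (length(v) == 0 || is.na(v)) NA_integer_ else as.integer(v)
  })
  mapped <- !is.na(m1) & !is.na(m2)
  df <- tibble(
    set = ifelse(pairs$interacting, "interacting", "non-interacting"),
    interaction_id = pairs$interaction_id,
    master_pos_1 = pmin(m1, m2), master_pos_2 = pmax(m1, m2)
  )[mapped, ]
  groups <- df |>
    dplyr::distinct() |>
    dplyr::group_by(.data$set, .data$master_pos_1, .data$master_pos_2) |>
    dplyr::summarise(n_interaction_pairs = dplyr::n(),
                     members = paste(sort(.data$interaction_id), collapse = ";"),
                     .groups = "drop") |>
    dplyr::filter(.data$n_interaction_pairs > 1)
  counts <- tibble(set = c("interacting", "non-interacting")) |>
    dplyr::left_join(dplyr::count(groups, .data$set, name = "n_groups"),
                     by = "set") |>
    dplyr::left_join(
      dplyr::count(tibble(set = ifelse(pairs$interacting, "interacting",
                                       "non-interacting")),
                   .data$set, name = "n_pairs_total"), by = "set") |>
    dplyr::mutate(n_groups = dplyr::coalesce(.data$n_groups, 0L),
                  n_pairs_total = dplyr::coalesce(.data$n_pairs_total, 0L),
                  groups_per_pair_pct = ifelse(.data$n_pairs_total > 0,
                                               100 * .data$n_groups / .data$n_pairs_total,
                                               NA_real_))
  list(groups = groups, counts = counts)
}
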