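#' Resampling p-value from random subsets of a background set
#'
#' Draws `reps` random subsets of size `k` from the background values, applies
#' the statistic to each, and returns the add-one empirical p-value
#' `p = (1 + #\{replicates >= observed\}) / (1 + reps)`; `p` is never 0 and the
#' test is conservative (super-uniform under the null).
#'
#' @param observed Observed statistic.
#' @param background Vector (or data frame) of background units to resample.
#' @param k Subset size (the number of observed units).
#' @param statistic Function applied to a subset of `background`.
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed (local to this call).
#' @return Object of class `randomization_test`: list with `observed`, `null`
#'   (replicate statistics), `p_value`, `reps`.
#' @export
random_subset_pvalue <- function(observed, background, k, statistic,
                                 reps = 1000, seed = NULL) {
  if (reps < 1) abort("reps must be >= 1")
  n_bg <- if (is.data.frame(background)) nrow(background) else length(background)
  if (k > n_bg) abort("subset size k exceeds background size")
  draw <- function() {
    idx <- sample.int(n_bg, k)
    sub <- if (is.data.frame(background)) background[idx, , drop = FALSE] else background[idx]
    statistic(sub)
  }
  null <- with_optional_seed(seed, vapply(seq_len(reps), function(i) draw(), numeric(1)))
  new_randomization_test("random_subset", observed, null)
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

new_randomization_test <- function(method, observed, null, extra = list()) {
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  structure(c(list(method = method, observed = observed, null = null,
                   p_value = p, reps = length(null)), extra),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("<randomization_test: %s> observed = %.4g, reps = %d, p = %.4g\n",
              x$method, x$observed, x$reps, x$p_value))
  invisible(x)
}

#' Short-distance enrichment of correlated pairs in a structure
#'
#' Fraction of correlated residue pairs whose minimum heavy-atom distance is
#' within each threshold, against the background fraction over all residue
#' pairs of the structure, with a random-subset p-value (subsets of the
#' background of the same size as the evaluated set). Correlated pairs that do
#' not map to a residue pair in the distance table (for example outside the
#' structure-mapped range) are dropped and counted.
#'
#' @param cm_pairs A `correlated_pairs` tibble (reference residue coordinates).
#' @param distances A `structure_distances` tibble in the same coordinates.
#' @param thresholds Distance thresholds in Angstrom (default 15 and 10).
#' @param reps Resampling replicates (default 1000).
#' @param seed Optional seed.
#' @return Tibble of class `enrichment_result`: one row per threshold with
#'   `threshold`, `n_evaluated`, `n_unmapped`, `observed_fraction`,
#'   `background_fraction`, `p_value`.
#' @export
distance_enrichment <- function(cm_pairs, distances, thresholds = c(15, 10),
                                reps = 1000, seed = NULL) {
  mode <- unique(cm_pairs$mode)
  ptype <- if (length(mode) == 1 && mode == "inter") "inter" else "intra"
  bg <- distances[distances$pair_type == ptype, , drop = FALSE]
  if (nrow(bg) == 0L) abort("no background residue pairs of the required type")

  obs_d <- lookup_pair_distances(cm_pairs, bg, ptype)
  n_unmapped <- sum(is.na(obs_d))
  obs_d <- obs_d[!is.na(obs_d)]
  if (length(obs_d) == 0L) abort("zero correlated pairs map into the structure")

  out <- purrr::map_dfr(thresholds, function(thr) {
    stat <- function(d) mean(d <= thr)
    test <- random_subset_pvalue(stat(obs_d), bg$distance, length(obs_d),
                                 stat, reps = reps, seed = seed)
    tibble(threshold = thr, n_evaluated = length(obs_d),
           n_unmapped = n_unmapped,
           observed_fraction = stat(obs_d),
           background_fraction = stat(bg$distance),
           p_value = test$p_value)
  })
  class(out) <- c("enrichment_result", class(out))
  out
}

# Distance lookup for correlated pairs. Intra: unordered residue pair within
# one chain; inter: ref_pos_1 indexes the first chain, ref_pos_2 the second.
lookup_pair_distances <- function(cm_pairs, bg, ptype) {
  if (ptype == "intra") {
    lo <- pmin(cm_pairs$ref_pos_1, cm_pairs$ref_pos_2)
    hi <- pmax(cm_pairs$ref_pos_1, cm_pairs$ref_pos_2)
    key <- paste(lo, hi)
    bg_key <- paste(pmin(bg$res_i, bg$res_j), pmax(bg$res_i, bg$res_j))
  } else {
    key <- paste(cm_pairs$ref_pos_1, cm_pairs$ref_pos_2)
    bg_key <- paste(bg$res_i, bg$res_j)
  }
  bg$distance[match(key, bg_key)]
}

#' Permute the partner rows of a paired alignment
#'
#' Helper for the pairing-shuffle null: rows of molecule B are permuted
#' against the rows of molecule A, destroying the ortholog pairing while
#' preserving both single-molecule alignments.
#'
#' @param pa A `paired_alignment`.
#' @param perm Integer permutation of the row indices.
#' @return A `paired_alignment` with permuted B rows.
#' @export
permute_partner <- function(pa, perm) {
  stopifnot(length(perm) == nrow(pa$seqs_b),
            all(sort(perm) == seq_len(nrow(pa$seqs_b))))
  pa$seqs_b <- pa$seqs_b[perm, , drop = FALSE]
  pa$seq_id_b <- pa$seq_id_b[perm]
  pa
}

#' Pairing-shuffle null for intermolecular correlated mutations
#'
#' The sequence pairing that forms the intermolecular input is randomly
#' shuffled (B rows permuted against A rows) and the correlated-mutation
#' detection re-run per replicate; genuine intermolecular coevolution is
#' destroyed by the shuffle while single-molecule signal survives.
#'
#' @param pa A `paired_alignment`.
#' @param reps Replicates (default 100; each replicate re-runs the engine).
#' @param seed Optional seed.
#' @param statistic Function of the replicate's `correlated_pairs` tibble;
#'   default: the number of detected pairs.
#' @param ... Passed to [detect_correlated_pairs()].
#' @return A `randomization_test` (with `null_pairs` counts as the statistic
#'   vector).
#' @export
shuffle_pairing_null <- function(pa, reps = 100, seed = NULL,
                                 statistic = nrow, ...) {
  if (reps < 1) abort("reps must be >= 1")
  observed <- statistic(detect_correlated_pairs(pa, ...))
  n <- nrow(pa$seqs_b)
  null <- with_optional_seed(seed, vapply(seq_len(reps), function(i) {
    statistic(detect_correlated_pairs(permute_partner(pa, sample.int(n)), ...))
  }, numeric(1)))
  new_randomization_test("shuffle_pairing", observed, null)
}

# Fast position-set overlap core shared by motif_overlap and the
# position-randomisation null: positions and motif intervals per protein are
# reduced to integer sets keyed by protein.
motif_position_sets <- function(motifs) {
  split(
    unlist(Map(seq.int, motifs$start, motifs$end)),
    rep(motifs$protein, motifs$end - motifs$start + 1L)
  ) |> lapply(unique)
}

overlap_coverages <- function(positions, motif_sets) {
  # positions: tibble(protein, position), already distinct
  by_prot <- split(positions$position, positions$protein)
  n_motif <- sum(lengths(motif_sets))
  n_cm <- length(positions$position)
  hit_motif <- 0L
  hit_cm <- 0L
  for (prot in names(motif_sets)) {
    cm <- by_prot[[prot]]
    if (!is.null(cm)) hit_motif <- hit_motif + sum(motif_sets[[prot]] %in% cm)
  }
  for (prot in names(by_prot)) {
    ms <- motif_sets[[prot]]
    if (!is.null(ms)) hit_cm <- hit_cm + sum(by_prot[[prot]] %in% ms)
  }
  c(coverage_motif = hit_motif / n_motif, coverage_cm = hit_cm / n_cm)
}

#' Harmonic mean of two coverage fractions (F-score)
#'
#' `F = 2ab / (a + b)`, with `F = 0` when either coverage is 0.
#'
#' @param a,b Coverage fractions.
#' @export
harmonic_f <- function(a, b) {
  ifelse(a + b == 0, 0, 2 * a * b / (a + b))
}

#' Position-level overlap between correlated positions and motifs
#'
#' Coverage of motif positions by correlated positions (fraction of motif
#' residues overlapped by at least one correlated position), coverage of
#' correlated positions by motifs (fraction falling inside any motif of their
#' protein), and their harmonic mean (F-score). Overlap is evaluated at
#' single-residue resolution in reference coordinates.
#'
#' @param cm_positions Tibble `protein`, `position` (e.g. from
#'   [correlated_positions()]).
#' @param motifs Motif tibble (`motif_id`, `protein`, `start`, `end`).
#' @return One-row tibble of class `overlap_result`: `coverage_motif`,
#'   `coverage_cm`, `f_score`, `n_motif_positions`, `n_cm_positions`.
#' @export
motif_overlap <- function(cm_positions, motifs) {
  if (nrow(motifs) == 0L) abort("empty motif set: coverages undefined")
  if (nrow(cm_positions) == 0L) abort("no correlated positions to compare")
  cm_positions <- dplyr::distinct(cm_positions, .data$protein, .data$position)
  sets <- motif_position_sets(motifs)
  cov <- overlap_coverages(cm_positions, sets)
  out <- tibble(coverage_motif = cov[["coverage_motif"]],
                coverage_cm = cov[["coverage_cm"]],
                f_score = harmonic_f(cov[["coverage_motif"]], cov[["coverage_cm"]]),
                n_motif_positions = sum(lengths(sets)),
                n_cm_positions = nrow(cm_positions))
  class(out) <- c("overlap_result", class(out))
  out
}

#' Consistent overlap between correlated pairs and complementary motif pairs
#'
#' A correlated pair is consistent with a motif pair when its two positions
#' fall inside the two member motifs respectively, molecule-matched: the
#' position in protein X inside the motif annotated on X, the position in
#' protein Y inside the partner motif on Y. Counts, per motif pair, the number
#' of interaction pairs in which such consistent overlap occurs.
#'
#' @param cm_pairs Tibble with `interaction_id`, `protein_1`, `pos_1`,
#'   `protein_2`, `pos_2` (reference coordinates).
#' @param motifs Motif tibble with symmetric `partner_motif_id`.
#' @return Tibble: `motif_id_1`, `motif_id_2`, `n_interaction_pairs`,
#'   `n_cm_pairs`.
#' @export
consistent_overlap <- function(cm_pairs, motifs) {
  motifs <- validate_motifs(motifs)
  paired <- motifs[!is.na(motifs$partner_motif_id), , drop = FALSE]
  partner <- paired[match(paired$partner_motif_id, paired$motif_id), ]
  if (any(paired$protein == partner$protein)) {
    abort("motif pair spanning a single molecule: partners must lie on two proteins")
  }
  # one row per unordered motif pair
  keep <- paired$motif_id < paired$partner_motif_id
  mp <- paired[keep, , drop = FALSE]
  mp_partner <- partner[keep, , drop = FALSE]

  purrr::map_dfr(seq_len(nrow(mp)), function(i) {
    ma <- mp[i, ]; mb <- mp_partner[i, ]
    fwd <- cm_pairs$protein_1 == ma$protein & cm_pairs$protein_2 == mb$protein &
      cm_pairs$pos_1 >= ma$start & cm_pairs$pos_1 <= ma$end &
      cm_pairs$pos_2 >= mb$start & cm_pairs$pos_2 <= mb$end
    rev <- cm_pairs$protein_1 == mb$protein & cm_pairs$protein_2 == ma$protein &
      cm_pairs$pos_1 >= mb$start & cm_pairs$pos_1 <= mb$end &
      cm_pairs$pos_2 >= ma$start & cm_pairs$pos_2 <= ma$end
    hit <- fwd | rev
    tibble(motif_id_1 = ma$motif_id, motif_id_2 = mb$motif_id,
           n_interaction_pairs = dplyr::n_distinct(cm_pairs$interaction_id[hit]),
           n_cm_pairs = sum(hit))
  })
}

#' Position-randomisation p-value for the motif overlap F-score
#'
#' Each distinct correlated position is replaced by a random position of its
#' protein; a position occurring in several correlated pairs is replaced by the
#' same random position in all of them (the per-replicate map is an injection
#' per protein). The F-score is recomputed per replicate and the add-one
#' p-value returned.
#'
#' @param cm_pairs Tibble with `protein_1`, `pos_1`, `protein_2`, `pos_2`.
#' @param protein_lengths Named integer vector of reference lengths.
#' @param motifs Motif tibble.
#' @param reps Replicates (default 1000).
#' @param seed Optional seed.
#' @return A `randomization_test` with the observed and null F-scores.
#' @export
randomize_positions_pvalue <- function(cm_pairs, protein_lengths, motifs,
                                       reps = 1000, seed = NULL) {
  positions <- dplyr::distinct(dplyr::bind_rows(
    tibble(protein = cm_pairs$protein_1, position = cm_pairs$pos_1),
    tibble(protein = cm_pairs$protein_2, position = cm_pairs$pos_2)
  ))
  missing <- setdiff(unique(positions$protein), names(protein_lengths))
  if (length(missing)) {
    abort(sprintf("protein_lengths missing: %s", paste(missing, collapse = ", ")))
  }
  sets <- motif_position_sets(motifs)
  observed <- {
    cov <- overlap_coverages(positions, sets)
    harmonic_f(cov[["coverage_motif"]], cov[["coverage_cm"]])
  }
  by_prot <- split(seq_len(nrow(positions)), positions$protein)
  null <- with_optional_seed(seed, vapply(seq_len(reps), function(i) {
    rnd <- positions
    for (prot in names(by_prot)) {
      idx <- by_prot[[prot]]
      rnd$position[idx] <- sample.int(protein_lengths[[prot]], length(idx))
    }
    cov <- overlap_coverages(rnd, sets)
    harmonic_f(cov[["coverage_motif"]], cov[["coverage_cm"]])
  }, numeric(1)))
  new_randomization_test("randomize_positions", observed, null)
}

#' Overlap of SNPs with correlated mutation positions
#'
#' A SNP overlaps when its residue position is a correlated-mutation position
#' of the same protein in the analysis set under consideration. Counts and
#' fractions are reported per SNP class (and per `set` if both inputs carry a
#' `set` column); counts are conserved: overlap + no overlap = input count.
#'
#' @param snps SNP tibble (`protein`, `position`, `class`, optional `set`).
#' @param cm_positions Tibble `protein`, `position` (optional `set`).
#' @return Tibble of class `snp_overlap_result`: per class (x set):
#'   `n_overlap`, `n_no_overlap`, `fraction` (NA when the class is empty).
#' @export
snp_overlap <- function(snps, cm_positions) {
  use_set <- "set" %in% names(snps) && "set" %in% names(cm_positions)
  if (!use_set) {
    snps$set <- "all"
    cm_positions$set <- "all"
  }
  cm_key <- paste(cm_positions$set, cm_positions$protein, cm_positions$position)
  snps$overlap <- paste(snps$set, snps$protein, snps$position) %in% cm_key
  out <- snps |>
    dplyr::group_by(.data$set, .data$class) |>
    dplyr::summarise(n_overlap = sum(.data$overlap),
                     n_no_overlap = sum(!.data$overlap), .groups = "drop") |>
    dplyr::mutate(fraction = ifelse(.data$n_overlap + .data$n_no_overlap > 0,
                                    .data$n_overlap /
                                      (.data$n_overlap + .data$n_no_overlap),
                                    NA_real_))
  if (!use_set) out$set <- NULL
  class(out) <- c("snp_overlap_result", class(out))
  out
}
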