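#' Poisson-corrected amino-acid distance between two aligned sequences
#'
#' The fraction `p` of differing residues is computed over columns where both
#' rows have a residue; the Poisson correction `t = -ln(1 - p)` estimates the
#' expected number of substitutions per site. Identical sequences give `t = 0`;
#' `p = 1` is outside the model's domain and raises an error.
#'
#' @param a,b Aligned sequences (equal-length strings or character vectors).
#' @return Non-negative numeric distance.
#' @examples
#' poisson_distance("ACDE", "ACDE")   # 0
#' poisson_distance("ACDE", "ACKR")   # -log(1 - 0.5)
#' @export
poisson_distance <- function(a, b) {
  a <- as_residue_vector(a)
  b <- as_residue_vector(b)
  if (length(a) != length(b)) abort("rows must have equal aligned length")
  shared <- a != GAP & b != GAP
  if (!any(shared)) abort("no shared non-gap columns")
  p <- mean(a[shared] != b[shared])
  if (p >= 1) abort("Poisson distance undefined at p = 1 (no shared identity)")
  -log(1 - p)
}

# Pairwise Poisson distances for all row pairs (ii, jj) of an integer-coded
# alignment matrix; returns NA (with a warning) where undefined.
pairwise_poisson <- function(codes, ii, jj) {
  A <- codes[ii, , drop = FALSE]
  B <- codes[jj, , drop = FALSE]
  shared <- !is.na(A) & !is.na(B)
  ns <- rowSums(shared)
  nd <- rowSums((A != B) & shared, na.rm = TRUE)
  p <- ifelse(ns > 0, nd / ns, NA_real_)
  t <- ifelse(!is.na(p) & p < 1, -log(1 - p), NA_real_)
  if (anyNA(t)) {
    warn(sprintf("%d sequence pair(s) have undefined Poisson distance and are dropped",
                 sum(is.na(t))))
  }
  t
}

# Core of the engine: the (sequence-pair x column) variability matrix.
# Entry [(i,j), k] starts as blosum(a_ik, a_jk), is centred per column over
# its defined pairs (variability relative to the mean variability of the
# site), optionally divided by the pair's divergence time, and re-centred so
# the mean-zero invariant holds after normalisation. Centring before the time
# normalisation keeps constant columns at an exact all-zero vector even when
# divergence times vary. NA marks undefined entries (gap in either row,
# dropped pair, skipped column).
variability_matrix <- function(codes, ii, jj, Bm, time = NULL,
                               max_gap_frac = 0.1) {
  np <- length(ii)
  Ci <- codes[ii, , drop = FALSE]
  Cj <- codes[jj, , drop = FALSE]
  V <- matrix(Bm[cbind(as.vector(Ci), as.vector(Cj))], nrow = np)
  tt <- NULL
  if (!is.null(time)) {
    tt <- ifelse(!is.na(time) & time > 0, time, NA_real_)
    V[is.na(tt), ] <- NA_real_
  }
  gap_frac <- colMeans(is.na(codes))
  V[, gap_frac > max_gap_frac] <- NA_real_
  defined <- colSums(!is.na(V))
  V[, defined < 2L] <- NA_real_
  V <- centre_columns(V)
  if (!is.null(tt)) V <- centre_columns(V / tt)
  V
}

centre_columns <- function(V) {
  centre <- colMeans(V, na.rm = TRUE)
  centre[is.nan(centre)] <- 0
  V - matrix(centre, nrow(V), ncol(V), byrow = TRUE)
}

pair_indices <- function(n) {
  idx <- combn(n, 2L)
  list(ii = idx[1L, ], jj = idx[2L, ])
}

#' Site variability vector for one alignment column
#'
#' For every pair of sequences with a residue at the column, the BLOSUM score
#' of the residue pair, centred by subtracting the mean over the defined pairs
#' (variability relative to the site's mean variability), optionally
#' normalised by the pair's Poisson divergence time (pairs at time 0 are
#' dropped) and re-centred. Centring before the time normalisation keeps
#' constant columns at an exact all-zero vector. This is the per-site
#' statistic whose across-pair correlation between two columns defines
#' coevolution.
#'
#' @param aln A `family_alignment`.
#' @param column Column index.
#' @param time_correction Normalise by divergence time?
#' @param blosum BLOSUM matrix identifier (see [get_blosum()]).
#' @param max_gap_frac Columns with a larger gap fraction are skipped.
#' @return Object of class `site_variability`: list with `column`, `entries`
#'   (named numeric, names `"i:j"` over defined pairs) and `n_rows`.
#' @export
site_variability_vector <- function(aln, column, time_correction = FALSE,
                                    blosum = "62", max_gap_frac = 0.1) {
  L <- alignment_length(aln)
  if (column < 1L || column > L) abort(sprintf("column out of range 1..%d", L))
  codes <- encode_residues(aln$seqs)
  pp <- pair_indices(nrow(codes))
  time <- if (time_correction) pairwise_poisson(codes, pp$ii, pp$jj) else NULL
  V <- variability_matrix(codes, pp$ii, pp$jj, get_blosum(blosum),
                          time = time, max_gap_frac = max_gap_frac)
  v <- V[, column]
  names(v) <- paste(pp$ii, pp$jj, sep = ":")
  structure(list(column = column, entries = v[!is.na(v)],
                 n_rows = nrow(codes)),
            class = "site_variability")
}

#' Correlation between two site variability vectors
#'
#' Pearson correlation over the sequence pairs defined in both vectors.
#' Returns `NA` (the pair is skipped, not reported) when the common support is
#' smaller than `min_pairs` or either restriction is constant.
#'
#' @param vec_a,vec_b `site_variability` objects.
#' @param min_pairs Minimum common defined pairs.
#' @return Correlation coefficient, or `NA`.
#' @export
site_pair_correlation <- function(vec_a, vec_b, min_pairs = 2L) {
  common <- intersect(names(vec_a$entries), names(vec_b$entries))
  if (length(common) < max(2L, min_pairs)) return(NA_real_)
  x <- vec_a$entries[common]
  y <- vec_b$entries[common]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

default_min_pairs <- function(n_pairs_total) {
  max(10L, floor(n_pairs_total / 2))
}

#' Detect correlated mutation position pairs
#'
#' The coevolution screen: site variability vectors (BLOSUM pair scores,
#' optionally Poisson time-normalised, centred per column) are correlated
#' between all column pairs, and pairs whose correlation coefficient reaches
#' the cutoff are reported. For a `family_alignment` all within-molecule column
#' pairs are scanned (intramolecular mode); for a `paired_alignment` only
#' columns of molecule A against columns of molecule B (intermolecular mode).
#'
#' Correlations are computed over the intersection of the defined sequence
#' pairs of the two columns and require at least `min_pairs` of them (default
#' `max(10, n_pairs/2)`), guarding against spurious coefficients on small
#' overlaps; columns with gap fraction above `max_gap_frac` are skipped.
#'
#' @param x A `family_alignment` or `paired_alignment`.
#' @param cutoff Correlation coefficient cutoff (default 0.4); applied to the
#'   signed coefficient unless `use_abs = TRUE`.
#' @param time_correction Normalise BLOSUM scores by Poisson divergence time
#'   (for paired alignments, the divergence of the concatenated row pair).
#' @param blosum BLOSUM matrix identifier.
#' @param max_gap_frac Maximum column gap fraction.
#' @param min_pairs Minimum common defined sequence pairs per correlation;
#'   `NULL` for the default rule.
#' @param use_abs Threshold `|r|` instead of signed `r`.
#' @param groups_only Keep only pairs belonging to a correlated group with more
#'   than one pair (default `FALSE`: all threshold-passing pairs are kept and
#'   annotated with their group).
#' @param ... Unused.
#' @return A tibble of class `correlated_pairs`: `molecule_1`, `column_1`,
#'   `ref_pos_1`, `molecule_2`, `column_2`, `ref_pos_2`, `r`, `n_pairs_used`,
#'   `mode`, `time_corrected`, `group_id`. Attributes: `n_scanned` (column
#'   pairs tested), `cutoff`.
#' @export
detect_correlated_pairs <- function(x, ...) {
  UseMethod("detect_correlated_pairs")
}

#' @rdname detect_correlated_pairs
#' @export
detect_correlated_pairs.family_alignment <- function(x, cutoff = 0.4,
                                                     time_correction = TRUE,
                                                     blosum = "62",
                                                     max_gap_frac = 0.1,
                                                     min_pairs = NULL,
                                                     use_abs = FALSE,
                                                     groups_only = FALSE, ...) {
  codes <- encode_residues(x$seqs)
  n <- nrow(codes)
  pp <- pair_indices(n)
  min_pairs <- min_pairs %||% default_min_pairs(length(pp$ii))
  time <- if (time_correction) pairwise_poisson(codes, pp$ii, pp$jj) else NULL
  V <- variability_matrix(codes, pp$ii, pp$jj, get_blosum(blosum),
                          time = time, max_gap_frac = max_gap_frac)
  R <- suppressWarnings(cor(V, use = "pairwise.complete.obs"))
  N <- crossprod(!is.na(V))
  testable <- is.finite(R) & N >= min_pairs
  testable[lower.tri(testable, diag = TRUE)] <- FALSE
  score <- if (use_abs) abs(R) else R
  hit <- testable & score >= cutoff
  idx <- which(hit, arr.ind = TRUE)
  refpos <- column_to_reference(x, seq_len(alignment_length(x)))
  out <- tibble(
    molecule_1 = x$family_id, column_1 = as.integer(idx[, 1]),
    ref_pos_1 = refpos[idx[, 1]],
    molecule_2 = x$family_id, column_2 = as.integer(idx[, 2]),
    ref_pos_2 = refpos[idx[, 2]],
    r = R[idx], n_pairs_used = as.integer(N[idx]),
    mode = "intra", time_corrected = time_correction
  )
  finish_pairs(out, n_scanned = sum(testable), cutoff = cutoff,
               groups_only = groups_only)
}

#' @rdname detect_correlated_pairs
#' @export
detect_correlated_pairs.paired_alignment <- function(x, cutoff = 0.4,
                                                     time_correction = TRUE,
                                                     blosum = "62",
                                                     max_gap_frac = 0.1,
                                                     min_pairs = NULL,
                                                     use_abs = FALSE,
                                                     groups_only = FALSE, ...) {
  codes_a <- encode_residues(x$seqs_a)
  codes_b <- encode_residues(x$seqs_b)
  n <- nrow(codes_a)
  pp <- pair_indices(n)
  min_pairs <- min_pairs %||% default_min_pairs(length(pp$ii))
  time <- if (time_correction) {
    # one joint divergence per ortholog-pair row pair, computed on the
    # concatenation of the paired rows
    pairwise_poisson(cbind(codes_a, codes_b), pp$ii, pp$jj)
  } else NULL
  Bm <- get_blosum(blosum)
  Va <- variability_matrix(codes_a, pp$ii, pp$jj, Bm, time = time,
                           max_gap_frac = max_gap_frac)
  Vb <- variability_matrix(codes_b, pp$ii, pp$jj, Bm, time = time,
                           max_gap_frac = max_gap_frac)
  R <- suppressWarnings(cor(Va, Vb, use = "pairwise.complete.obs"))
  N <- crossprod(!is.na(Va) + 0, !is.na(Vb) + 0)
  testable <- is.finite(R) & N >= min_pairs
  score <- if (use_abs) abs(R) else R
  hit <- testable & score >= cutoff
  idx <- which(hit, arr.ind = TRUE)
  refs <- paired_reference_positions(x)
  out <- tibble(
    molecule_1 = x$family_ids[1], column_1 = as.integer(idx[, 1]),
    ref_pos_1 = refs$a[idx[, 1]],
    molecule_2 = x$family_ids[2], column_2 = as.integer(idx[, 2]),
    ref_pos_2 = refs$b[idx[, 2]],
    r = R[idx], n_pairs_used = as.integer(N[idx]),
    mode = "inter", time_corrected = time_correction
  )
  finish_pairs(out, n_scanned = sum(testable), cutoff = cutoff,
               groups_only = groups_only)
}

finish_pairs <- function(out, n_scanned, cutoff, groups_only) {
  out <- dplyr::arrange(out, .data$column_1, .data$column_2)
  groups <- correlated_groups(out)
  if (nrow(out)) {
    key1 <- paste(out$molecule_1, out$column_1)
    key2 <- paste(out$molecule_2, out$column_2)
    gkey <- paste(groups$molecule, groups$column)
    out$group_id <- groups$group_id[match(key1, gkey)]
    stopifnot(all(out$group_id == groups$group_id[match(key2, gkey)]))
  } else {
    out$group_id <- integer(0)
  }
  if (groups_only && nrow(out)) {
    sizes <- table(out$group_id)
    keep_groups <- as.integer(names(sizes)[sizes > 1])
    out <- out[out$group_id %in% keep_groups, , drop = FALSE]
  }
  attr(out, "n_scanned") <- n_scanned
  attr(out, "cutoff") <- cutoff
  class(out) <- c("correlated_pairs", class(out))
  out
}

#' Correlated groups: connected components of the pair graph
#'
#' Positions are nodes, threshold-passing correlated pairs are edges; groups
#' are the connected components.
#'
#' @param pairs A `correlated_pairs` tibble (or any tibble with `molecule_1`,
#'   `column_1`, `molecule_2`, `column_2`).
#' @return Tibble: `group_id`, `molecule`, `column`.
#' @export
correlated_groups <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(group_id = integer(0), molecule = character(0),
                  column = integer(0)))
  }
  from <- paste(pairs$molecule_1, pairs$column_1, sep = "\r")
  to <- paste(pairs$molecule_2, pairs$column_2, sep = "\r")
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE)
  comp <- igraph::components(g)
  nodes <- names(comp$membership)
  parts <- stringr::str_split_fixed(nodes, "\r", 2)
  tibble(group_id = as.integer(comp$membership),
         molecule = parts[, 1], column = as.integer(parts[, 2])) |>
    dplyr::arrange(.data$group_id, .data$molecule, .data$column)
}

#' Distinct correlated positions from a pair table
#'
#' Convenience: the unique (protein, reference position) records across both
#' ends of a `correlated_pairs` table, for overlap-style comparisons.
#'
#' @param pairs A `correlated_pairs` tibble.
#' @param use_ref Use reference residue coordinates (default) or alignment
#'   columns.
#' @return Tibble: `protein`, `position`.
#' @export
correlated_positions <- function(pairs, use_ref = TRUE) {
  p1 <- tibble(protein = pairs$molecule_1,
               position = if (use_ref) pairs$ref_pos_1 else pairs$column_1)
  p2 <- tibble(protein = pairs$molecule_2,
               position = if (use_ref) pairs$ref_pos_2 else pairs$column_2)
  dplyr::distinct(dplyr::filter(dplyr::bind_rows(p1, p2),
                                !is.na(.data$position)))
}
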