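#' Assign candidate sequences to reference proteins by best hit
#'
#' Each candidate is assigned to the reference protein with which it has the
#' highest pairwise identity. For candidates whose `source` is listed in
#' `bidirectional_sources` (by default the sequenced-genome source, where the
#' full sequence complement is known) the criterion is applied bidirectionally:
#' the candidate is kept only if it is in turn the best hit of its assigned
#' reference within its own species-and-source pool. Identity ties between
#' references are broken towards the lexicographically smaller reference id,
#' with a warning.
#'
#' @param candidates Tibble with columns `seq_id`, `species`, `source`, `seq`
#'   (sequences aligned to the shared reference coordinate frame, so that
#'   `identity_fn` applies directly).
#' @param references Tibble with columns `seq_id`, `seq`.
#' @param identity_fn Function `(a, b) -> fraction`; default [pairwise_identity()].
#' @param bidirectional_sources Sources subject to the bidirectional rule.
#' @return Tibble: `seq_id`, `species`, `source`, `best_reference`, `identity`,
#'   `bidirectional_confirmed` (TRUE rows are retained downstream).
#' @export
assign_best_hits <- function(candidates, references,
                             identity_fn = pairwise_identity,
                             bidirectional_sources = "genome") {
  if (nrow(references) == 0L) abort("empty reference set")
  if (anyDuplicated(candidates$seq_id)) abort("candidate seq_ids must be unique")

  idm <- matrix(0, nrow(candidates), nrow(references),
                dimnames = list(candidates$seq_id, references$seq_id))
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(references))) {
      idm[i, j] <- identity_fn(candidates$seq[i], references$seq[j])
    }
  }
  # argmax with lexicographic tie-break on reference id
  ord <- order(colnames(idm))
  best_j <- apply(idm[, ord, drop = FALSE], 1, which.max)
  best_ref <- colnames(idm)[ord][best_j]
  best_id <- idm[cbind(seq_len(nrow(idm)), match(best_ref, colnames(idm)))]
  n_tied <- rowSums(idm == best_id)
  if (any(n_tied > 1)) {
    warn(sprintf("%d candidate(s) tied between references; assigned to the lexicographically smaller id",
                 sum(n_tied > 1)))
  }

  out <- tibble(
    seq_id = candidates$seq_id, species = candidates$species,
    source = candidates$source,
    best_reference = best_ref, identity = unname(best_id),
    bidirectional_confirmed = TRUE
  )

  bi <- out$source %in% bidirectional_sources
  if (any(bi)) {
    for (k in which(bi)) {
      pool <- which(bi &
                      out$species == out$species[k] &
                      out$source == out$source[k])
      ids_to_ref <- idm[pool, out$best_reference[k]]
      out$bidirectional_confirmed[k] <-
        out$identity[k] >= max(ids_to_ref)
    }
  }
  out
}

#' Greedy within-species identity clustering
#'
#' Removes within-species redundancy among sequences sharing a species and a
#' best-hit reference: members are processed in input order; a member joins the
#' first cluster whose centroid (founding member) has identity at least
#' `cutoff` with it, otherwise it founds a new cluster.
#'
#' @param members Tibble with columns `seq_id`, `seq` (and anything else, kept).
#' @param cutoff Identity cutoff, default 0.95.
#' @param identity_fn Identity function, default [pairwise_identity()].
#' @return `members` with an added `cluster` column (integer) whose centroid is
#'   the cluster's first member.
#' @export
cluster_within_species <- function(members, cutoff = 0.95,
                                   identity_fn = pairwise_identity) {
  n <- nrow(members)
  cluster <- integer(n)
  centroids <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      if (identity_fn(members$seq[i], members$seq[centroids[ci]]) >= cutoff) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      cluster[i] <- length(centroids)
    }
  }
  members$cluster <- cluster
  members
}

#' Select one representative per cluster
#'
#' Representatives are chosen by source priority `genome` > `interpro` >
#' `blast`; ties within the top priority class are broken by a random draw
#' (seed the session RNG for reproducibility).
#'
#' @param cluster Tibble with columns `seq_id`, `source` (one cluster's members).
#' @return The chosen `seq_id`.
#' @export
select_representative <- function(cluster) {
  if (nrow(cluster) == 0L) abort("empty cluster")
  priority <- c(genome = 1L, interpro = 2L, blast = 3L, reference = 0L)
  p <- priority[cluster$source]
  p[is.na(p)] <- 4L
  best <- which(p == min(p))
  if (length(best) > 1L) best <- sample(best, 1L)
  cluster$seq_id[best]
}

#' Drop candidates below a minimum identity to their reference
#'
#' The threshold is inclusive: identity exactly at the threshold is kept.
#'
#' @param assignment Tibble with an `identity` column (e.g. from
#'   [assign_best_hits()]).
#' @param threshold Minimum identity, default 0.25.
#' @export
filter_min_identity <- function(assignment, threshold = 0.25) {
  assignment[assignment$identity >= threshold, , drop = FALSE]
}

#' Per-species Cartesian pairing of co-orthologs
#'
#' For each species present in both ortholog sets, all combinations of
#' A-orthologs and B-orthologs are formed (two co-orthologs on each side give
#' 2 x 2 = 4 ortholog pairs); the union over species is returned.
#'
#' @param orthos_a,orthos_b Tibbles with columns `seq_id`, `species`.
#' @return Tibble `seq_id_a`, `seq_id_b`, `species`.
#' @export
build_intermolecular_pairs <- function(orthos_a, orthos_b) {
  species <- intersect(unique(orthos_a$species), unique(orthos_b$species))
  purrr::map_dfr(species, function(sp) {
    a <- orthos_a$seq_id[orthos_a$species == sp]
    b <- orthos_b$seq_id[orthos_b$species == sp]
    tidyr::expand_grid(seq_id_a = a, seq_id_b = b) |>
      dplyr::mutate(species = sp)
  })
}

#' Minimum-size filter for analysis sets
#'
#' A family (or set of ortholog pairs) enters the correlated-mutation analysis
#' only if it has at least `minimum` rows.
#'
#' @param n_rows Number of sequences (or sequence pairs).
#' @param minimum Threshold, default 30 (inclusive).
#' @return Logical: keep?
#' @export
apply_min_rows <- function(n_rows, minimum = 30L) {
  n_rows >= minimum
}

#' Assemble an ortholog set: best hits, identity filter, clustering, representatives
#'
#' Runs the full dataset-construction chain for one candidate set: best-hit
#' assignment (with the bidirectional rule for genome-derived sequences), the
#' minimum-identity filter, within-species greedy clustering per (species,
#' reference) group, and representative selection. Deterministic under a fixed
#' RNG seed.
#'
#' @inheritParams assign_best_hits
#' @param min_identity Minimum identity to the assigned reference (default 0.25).
#' @param cluster_cutoff Within-species clustering cutoff (default 0.95).
#' @return The assignment tibble restricted to retained representatives, with
#'   `cluster` and `representative` columns.
#' @export
assemble_orthologs <- function(candidates, references,
                               identity_fn = pairwise_identity,
                               bidirectional_sources = "genome",
                               min_identity = 0.25,
                               cluster_cutoff = 0.95) {
  asg <- assign_best_hits(candidates, references, identity_fn,
                          bidirectional_sources)
  asg <- asg[asg$bidirectional_confirmed, , drop = FALSE]
  asg <- filter_min_identity(asg, min_identity)
  asg$seq <- candidates$seq[match(asg$seq_id, candidates$seq_id)]

  asg |>
    dplyr::group_by(.data$species, .data$best_reference) |>
    dplyr::group_modify(function(g, key) {
      g <- cluster_within_species(g, cutoff = cluster_cutoff,
                                  identity_fn = identity_fn)
      g |>
        dplyr::group_by(.data$cluster) |>
        dplyr::group_modify(function(cl, k) {
          rep_id <- select_representative(cl)
          dplyr::mutate(cl, representative = .data$seq_id == rep_id)
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$representative) |>
    dplyr::select(-"seq")
}
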