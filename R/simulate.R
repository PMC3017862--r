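#' Synthetic ortholog families with planted compensatory column pairs
#'
#' Sequences descend from a random ancestor along a star phylogeny: each row is
#' an independent leaf, so shared-ancestry correlation is absent by
#' construction and planted compensation is the only source of coevolution
#' signal. Background columns substitute independently per leaf (uniform
#' replacement among the 20 amino acids, at a per-site probability solved so
#' that the expected pairwise Poisson distance between leaves matches
#' `depth`). Planted column pairs evolve jointly over a two-state
#' compatible-state system: when the first position toggles its state, the
#' partner adopts the compatible state with probability `q` and evolves
#' independently otherwise.
#'
#' @param n_seq Number of sequences (default 60; families below 30 would not
#'   pass [apply_min_rows()]).
#' @param n_col Alignment columns (default 100).
#' @param depth Target mean pairwise Poisson distance between leaves
#'   (default 0.7).
#' @param planted Tibble with `pos_1`, `pos_2` (distinct columns) and
#'   optionally `q`; `NULL` for no planted pairs.
#' @param q Default compensation strength in \[0, 1\].
#' @param family_id Family name.
#' @param seed Integer seed (mandatory: generation is fully deterministic).
#' @param state_rate Per-leaf toggle probability of planted states; default
#'   `min(0.5, 1 - exp(-depth))`, matching the background per-site
#'   substitution pressure while keeping both states common.
#' @param compatible_states List of two length-2 character vectors: the state
#'   alphabet of the first and second member of every planted pair
#'   (state k of position 1 is compatible with state k of position 2).
#' @return A `family_alignment` with the realised `planted` table attached as
#'   an attribute.
#' @export
simulate_family <- function(n_seq = 60, n_col = 100, depth = 0.7,
                            planted = NULL, q = 0.9, family_id = "FAM1",
                            seed, state_rate = NULL,
                            compatible_states = list(c("K", "D"), c("E", "R"))) {
  withr::with_seed(seed, {
    mat <- simulate_rows(n_seq, n_col, depth, planted, q, state_rate,
                         compatible_states)
    sources <- c("reference",
                 sample(c("interpro", "blast", "genome"), n_seq - 1, replace = TRUE))
    aln <- family_alignment(
      mat,
      seq_id = c(paste0(family_id, "_ref"),
                 sprintf("%s_s%03d", family_id, seq_len(n_seq - 1))),
      species = c("A.thaliana", sprintf("sp%03d", seq_len(n_seq - 1))),
      source = sources, family_id = family_id)
    attr(aln, "planted") <- normalise_planted(planted, q, n_col)
    aln
  })
}

normalise_planted <- function(planted, q, n_col) {
  if (is.null(planted) || nrow(planted) == 0L) {
    return(tibble(pos_1 = integer(0), pos_2 = integer(0), q = numeric(0)))
  }
  if (!"q" %in% names(planted)) planted$q <- q
  pos <- c(planted$pos_1, planted$pos_2)
  if (anyDuplicated(pos)) abort("planted positions must be distinct")
  if (any(pos < 1 | pos > n_col)) abort("planted positions outside the alignment")
  if (any(planted$q < 0 | planted$q > 1)) abort("q must lie in [0, 1]")
  planted
}

# Per-leaf substitution probability whose expected leaf-leaf difference
# fraction matches the target Poisson depth. Replacement is uniform over the
# 20 amino acids, so two leaves agree with probability
# (1 - 19s/20)^2 + 19 (s/20)^2.
solve_site_rate <- function(depth) {
  if (depth < 0) abort("depth must be non-negative")
  if (depth == 0) return(0)
  p_target <- 1 - exp(-depth)
  p_max <- 0.95  # s = 1 limit
  if (p_target >= p_max) {
    abort(sprintf("depth %.2f exceeds the saturation of the uniform model", depth))
  }
  pfun <- function(s) 1 - ((1 - 19 * s / 20)^2 + 19 * (s / 20)^2) - p_target
  uniroot(pfun, c(0, 1), tol = 1e-10)$root
}

simulate_rows <- function(n_seq, n_col, depth, planted, q, state_rate,
                          compatible_states) {
  s <- solve_site_rate(depth)
  ancestor <- sample(AA20, n_col, replace = TRUE)
  mat <- matrix(rep(ancestor, each = n_seq), nrow = n_seq)
  mutate_mask <- matrix(runif(n_seq * n_col) < s, n_seq, n_col)
  mat[mutate_mask] <- sample(AA20, sum(mutate_mask), replace = TRUE)

  planted <- normalise_planted(planted, q, n_col)
  ps <- state_rate %||% min(0.5, 1 - exp(-depth))
  for (i in seq_len(nrow(planted))) {
    st1 <- 1L + (runif(n_seq) < ps)                  # state of position 1
    follow <- runif(n_seq) < planted$q[i]
    st2 <- ifelse(follow, st1, 1L + (runif(n_seq) < ps))
    mat[, planted$pos_1[i]] <- compatible_states[[1]][st1]
    mat[, planted$pos_2[i]] <- compatible_states[[2]][st2]
  }
  mat
}

#' Simulate a set of family alignments with shared and private planted pairs
#'
#' Emulates a protein family whose members share part of their coevolving
#' pairs: `n_shared` planted pairs sit at identical positions in every family
#' (conserved correlated mutations), `n_private` pairs are unique to each
#' family, at positions disjoint from all other planted positions. All
#' families have ungapped references of equal length, so the master alignment
#' of the references is the identity mapping.
#'
#' @inheritParams simulate_family
#' @param n_families Number of family members.
#' @param n_shared,n_private Planted pairs shared by all members / private to
#'   each member.
#' @return Named list of `family_alignment`s (ids `FAM1`, `FAM2`, ...).
#' @export
simulate_family_set <- function(n_families = 2, n_shared = 5, n_private = 3,
                                n_seq = 60, n_col = 100, depth = 0.7, q = 0.9,
                                seed) {
  need <- 2 * (n_shared + n_families * n_private)
  if (need > n_col) abort("not enough columns for the requested planted pairs")
  withr::with_seed(seed, {
    pool <- sample.int(n_col, need)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    shared <- tibble(pos_1 = take(n_shared), pos_2 = take(n_shared),
                     shared = rep(TRUE, n_shared))
    fams <- lapply(seq_len(n_families), function(f) {
      private <- tibble(pos_1 = take(n_private), pos_2 = take(n_private),
                        shared = rep(FALSE, n_private))
      planted <- dplyr::bind_rows(shared, private)
      aln <- simulate_family(n_seq = n_seq, n_col = n_col, depth = depth,
                             planted = planted[c("pos_1", "pos_2")], q = q,
                             family_id = paste0("FAM", f),
                             seed = sample.int(.Machine$integer.max, 1))
      attr(aln, "planted") <- dplyr::mutate(attr(aln, "planted"),
                                            shared = planted$shared)
      aln
    })
    names(fams) <- paste0("FAM", seq_len(n_families))
    fams
  })
}

#' Reference sequences of a list of family alignments
#'
#' Named character vector of each family's (ungapped-as-aligned) reference
#' row, usable as a master alignment for [build_homology_map()] when all
#' references share one coordinate frame.
#'
#' @param families Named list of `family_alignment`s.
#' @export
reference_sequences <- function(families) {
  vapply(families, function(aln) {
    paste(aln$seqs[aln$reference_row, ], collapse = "")
  }, character(1))
}

#' Simulate interacting and non-interacting paired alignments
#'
#' Each interacting pair carries `n_planted` intermolecular compensatory
#' column pairs between molecule A and molecule B; non-interacting pairs share
#' the identical background process but carry none. Rows are
#' species-consistent ortholog pairs (one leaf per species in both
#' molecules).
#'
#' @inheritParams simulate_family
#' @param n_interacting,n_noninteracting Number of paired alignments per set
#'   (defaults 34 and 34, the scale of the reference-species interaction
#'   screen this emulates).
#' @param n_col_a,n_col_b Columns of the two molecules.
#' @param n_planted Planted intermolecular pairs per interacting alignment.
#' @param shared_planted Use the same planted positions in every interacting
#'   pair (emulates conserved intermolecular correlated mutations)?
#' @return List with elements `interacting` and `noninteracting`, each a list
#'   of `paired_alignment`s with the planted table (`pos_1` in A coordinates,
#'   `pos_2` in B coordinates) attached.
#' @export
simulate_interaction_set <- function(n_interacting = 34, n_noninteracting = 34,
                                     n_seq = 60, n_col_a = 100, n_col_b = 100,
                                     n_planted = 3, q = 0.9, depth = 0.7,
                                     shared_planted = FALSE, seed) {
  withr::with_seed(seed, {
    shared <- tibble(pos_1 = sample.int(n_col_a, n_planted),
                     pos_2 = sample.int(n_col_b, n_planted))
    make_pair <- function(idx, interacting) {
      planted <- if (!interacting) {
        NULL
      } else if (shared_planted) {
        shared
      } else {
        tibble(pos_1 = sample.int(n_col_a, n_planted),
               pos_2 = sample.int(n_col_b, n_planted))
      }
      simulate_paired(idx, interacting, planted, n_seq, n_col_a, n_col_b,
                      q, depth)
    }
    list(
      interacting = lapply(seq_len(n_interacting), make_pair, interacting = TRUE),
      noninteracting = lapply(seq_len(n_noninteracting), make_pair,
                              interacting = FALSE)
    )
  })
}

simulate_paired <- function(idx, interacting, planted, n_seq, n_col_a,
                            n_col_b, q, depth) {
  tag <- if (interacting) "I" else "N"
  id_a <- sprintf("%s%02d_A", tag, idx)
  id_b <- sprintf("%s%02d_B", tag, idx)
  seed_a <- sample.int(.Machine$integer.max, 1)
  seed_b <- sample.int(.Machine$integer.max, 1)
  aln_a <- simulate_family(n_seq, n_col_a, depth, planted = NULL,
                           family_id = id_a, seed = seed_a)
  aln_b <- simulate_family(n_seq, n_col_b, depth, planted = NULL,
                           family_id = id_b, seed = seed_b)
  # overwrite the planted columns with the coupled two-state process
  if (!is.null(planted) && nrow(planted)) {
    ps <- min(0.5, 1 - exp(-depth))
    states <- list(c("K", "D"), c("E", "R"))
    for (i in seq_len(nrow(planted))) {
      st1 <- 1L + (runif(n_seq) < ps)
      follow <- runif(n_seq) < q
      st2 <- ifelse(follow, st1, 1L + (runif(n_seq) < ps))
      aln_a$seqs[, planted$pos_1[i]] <- states[[1]][st1]
      aln_b$seqs[, planted$pos_2[i]] <- states[[2]][st2]
    }
  }
  # match rows 1:1 by construction (same species ladder in both families)
  row_pairs <- tibble(seq_id_a = aln_a$seq_id, seq_id_b = aln_b$seq_id)
  pa <- pair_alignments(aln_a, aln_b, row_pairs, interacting = interacting)
  attr(pa, "planted") <- planted %||% tibble(pos_1 = integer(0),
                                             pos_2 = integer(0))
  pa
}

#' Toy structure placing planted pairs in spatial contact
#'
#' Residues are laid out along an extended, gently jittered chain (consecutive
#' residues about 4 Angstrom apart), one chain per molecule with chains well
#' separated, so residue pairs distant in sequence are typically far apart
#' (beyond 15 Angstrom). Each planted pair's second residue is then relocated
#' next to its partner, within `contact_distance`. Every residue gets a CA and
#' a CB pseudo-atom; the emitted distances are exact minimum heavy-atom
#' distances over those atoms.
#'
#' @param n_res Residues in chain A.
#' @param planted_pairs Tibble `pos_1`, `pos_2`: intramolecular contacts when
#'   `n_res_b` is `NULL`, otherwise contacts of chain-A residue `pos_1` with
#'   chain-B residue `pos_2`.
#' @param n_res_b Residues in chain B (`NULL` for a single chain).
#' @param contact_distance Maximum planted-pair distance in Angstrom
#'   (default 8).
#' @param seed Integer seed.
#' @return Object of class `toy_structure`: list with `atoms` (tibble `chain`,
#'   `resno`, `atom`, `x`, `y`, `z`) and `distances` (a `structure_distances`
#'   tibble).
#' @export
make_toy_structure <- function(n_res, planted_pairs = NULL, n_res_b = NULL,
                               contact_distance = 8, seed) {
  withr::with_seed(seed, {
    chain_coords <- function(n, y_offset) {
      cbind(x = 4 * seq_len(n) + rnorm(n, 0, 0.3),
            y = y_offset + rnorm(n, 0, 1),
            z = rnorm(n, 0, 1))
    }
    ca <- list(A = chain_coords(n_res, 0))
    if (!is.null(n_res_b)) ca$B <- chain_coords(n_res_b, 60)
    if (!is.null(planted_pairs) && nrow(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        p1 <- planted_pairs$pos_1[i]
        p2 <- planted_pairs$pos_2[i]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        target <- ca$A[p1, ] + (contact_distance - 3.5) * u
        if (is.null(n_res_b)) ca$A[p2, ] <- target else ca$B[p2, ] <- target
      }
    }
    cb_offset <- function(n) {
      u <- matrix(rnorm(3 * n), n, 3)
      1.5 * u / sqrt(rowSums(u^2))
    }
    atoms <- purrr::imap_dfr(ca, function(xyz, ch) {
      n <- nrow(xyz)
      dplyr::bind_rows(
        tibble(chain = ch, resno = seq_len(n), atom = "CA",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
        tibble(chain = ch, resno = seq_len(n), atom = "CB") |>
          dplyr::bind_cols(as_tibble(xyz + cb_offset(n)) |>
                             stats::setNames(c("x", "y", "z")))
      )
    })
    structure(list(atoms = atoms, distances = toy_distances(atoms)),
              class = "toy_structure")
  })
}

# Exact minimum distances over the CA/CB atoms of every residue pair.
toy_distances <- function(atoms) {
  cross_min <- function(a1, a2) {
    X <- as.matrix(a1[, c("x", "y", "z")])
    Y <- as.matrix(a2[, c("x", "y", "z")])
    D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    D2[D2 < 0] <- 0
    r1 <- a1$resno; r2 <- a2$resno
    n1 <- max(r1); n2 <- max(r2)
    M <- matrix(Inf, n1, n2)
    for (k in seq_along(r1)) {
      M[r1[k], ] <- pmin(M[r1[k], ], tapply(sqrt(D2[k, ]), r2, min)[as.character(seq_len(n2))])
    }
    M
  }
  chains <- unique(atoms$chain)
  out <- list()
  for (ci in seq_along(chains)) {
    for (cj in ci:length(chains)) {
      a1 <- atoms[atoms$chain == chains[ci], ]
      a2 <- atoms[atoms$chain == chains[cj], ]
      M <- cross_min(a1, a2)
      if (ci == cj) {
        idx <- which(upper.tri(M), arr.ind = TRUE)
        out[[length(out) + 1L]] <- tibble(
          chain_i = chains[ci], res_i = idx[, 1],
          chain_j = chains[cj], res_j = idx[, 2],
          pair_type = "intra", distance = M[idx])
      } else {
        idx <- which(is.finite(M), arr.ind = TRUE)
        out[[length(out) + 1L]] <- tibble(
          chain_i = chains[ci], res_i = idx[, 1],
          chain_j = chains[cj], res_j = idx[, 2],
          pair_type = "inter", distance = M[idx])
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("structure_distances", class(res))
  res
}

#' Write a toy structure as a minimal PDB file
#'
#' Single-model ATOM records (CA and CB pseudo-atoms, alanine residues),
#' readable by any PDB parser; exercises the real structure reader in tests.
#'
#' @param structure A `toy_structure`.
#' @param path Output path.
#' @export
write_toy_pdb <- function(structure, path) {
  at <- dplyr::arrange(structure$atoms, .data$chain, .data$resno,
                       dplyr::desc(.data$atom == "CA"))
  lines <- sprintf(
    "ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(at)), at$atom, at$chain, at$resno, at$x, at$y, at$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Synthetic motif, SNP and coil-track annotations around planted pairs
#'
#' Emulates the external annotation sources the validation stage consumes.
#' With probability `fidelity` a planted pair receives a complementary motif
#' pair centred on its two positions (otherwise the motif pair is placed at
#' random), non-synonymous SNPs avoid planted positions (otherwise they are
#' uniform), and coil tracks mark the declared helix regions with high
#' probability.
#'
#' @param planted Tibble `protein_1`, `pos_1`, `protein_2`, `pos_2` of planted
#'   (intermolecular) pairs.
#' @param protein_lengths Named integer vector of reference lengths.
#' @param fidelity Probability in \[0, 1\] that an annotation tracks the
#'   planted signal (default 1).
#' @param seed Integer seed.
#' @param motif_halfwidth Motif interval half-width (default 2).
#' @param n_snps_per_class SNPs per protein and class (default 20).
#' @param helix_regions Tibble `protein`, `start`, `end`; default: one
#'   14-residue region per protein at around 55 percent of its length.
#' @return List with `motifs`, `snps`, `tracks` tibbles.
#' @export
make_annotations <- function(planted, protein_lengths, fidelity = 1, seed,
                             motif_halfwidth = 2, n_snps_per_class = 20,
                             helix_regions = NULL) {
  withr::with_seed(seed, {
    clamp <- function(x, L) pmax(1L, pmin(as.integer(x), L))
    motifs <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      mk <- function(prot, pos, tag) {
        L <- protein_lengths[[prot]]
        centre <- if (runif(1) < fidelity) pos else sample.int(L, 1)
        tibble(motif_id = sprintf("m%03d%s", i, tag), protein = prot,
               start = clamp(centre - motif_halfwidth, L),
               end = clamp(centre + motif_halfwidth, L))
      }
      a <- mk(planted$protein_1[i], planted$pos_1[i], "a")
      b <- mk(planted$protein_2[i], planted$pos_2[i], "b")
      a$partner_motif_id <- b$motif_id
      b$partner_motif_id <- a$motif_id
      dplyr::bind_rows(a, b)
    })
    planted_pos <- dplyr::bind_rows(
      tibble(protein = planted$protein_1, position = planted$pos_1),
      tibble(protein = planted$protein_2, position = planted$pos_2))
    snps <- purrr::map_dfr(names(protein_lengths), function(prot) {
      L <- protein_lengths[[prot]]
      avoid <- planted_pos$position[planted_pos$protein == prot]
      free <- setdiff(seq_len(L), avoid)
      ns <- vapply(seq_len(n_snps_per_class), function(i) {
        if (runif(1) < fidelity && length(free)) sample(free, 1) else sample.int(L, 1)
      }, integer(1))
      dplyr::bind_rows(
        tibble(protein = prot, position = as.integer(ns), class = "non-synonymous"),
        tibble(protein = prot,
               position = sample.int(L, n_snps_per_class, replace = TRUE),
               class = "synonymous"))
    })
    if (is.null(helix_regions)) {
      helix_regions <- purrr::map_dfr(names(protein_lengths), function(prot) {
        L <- protein_lengths[[prot]]
        s <- max(1L, min(L - 13L, as.integer(0.55 * L)))
        tibble(protein = prot, start = s, end = min(L, s + 13L))
      })
    }
    tracks <- purrr::map_dfr(names(protein_lengths), function(prot) {
      L <- protein_lengths[[prot]]
      p <- rep(0.1, L)
      hr <- helix_regions[helix_regions$protein == prot, ]
      for (i in seq_len(nrow(hr))) p[hr$start[i]:hr$end[i]] <- 0.85
      tibble(protein = prot, position = seq_len(L), probability = p)
    })
    list(motifs = motifs, snps = snps, tracks = tracks)
  })
}
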