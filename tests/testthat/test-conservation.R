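test_that("homology maps are gap-skipping bijections that round-trip", {
  master <- c(P1 = "M-AD", P2 = "MKAD", P3 = "MK-D")
  hmap <- build_homology_map(master)
  # P1 residue 2 sits in master column 3
  expect_equal(hmap$column[hmap$protein == "P1" & hmap$residue == 2], 3L)
  # round trip within each protein
  for (p in names(master)) {
    sub <- hmap[hmap$protein == p, ]
    expect_equal(sub$residue, seq_len(nrow(sub)))
    expect_false(any(duplicated(sub$column)))
  }
  # P1 residue 2 (column 3) is homologous to P2 residue 3, unmappable in P3
  expect_equal(map_homologous_position(hmap, "P1", 2, "P2"), 3L)
  expect_true(is.na(map_homologous_position(hmap, "P1", 2, "P3")))
  expect_error(build_homology_map(c(P1 = "MAD", P2 = "MADE")), "ragged")
})

test_that("conservation classification separates shared from private planted pairs", {
  fams <- simulate_family_set(n_families = 3, n_shared = 4, n_private = 2,
                              n_seq = 40, n_col = 60, seed = 31)
  # ground-truth planted pairs as the per-protein pair lists
  pairs_by <- purrr::map_dfr(fams, function(f) {
    p <- attr(f, "planted")
    tibble::tibble(protein = f$family_id, pos_1 = p$pos_1, pos_2 = p$pos_2,
                   shared = p$shared)
  })
  hmap <- build_homology_map(reference_sequences(fams))
  calls <- classify_conservation(pairs_by[, 1:3], hmap)
  s <- summarize_conservation(calls)
  per <- dplyr::left_join(s$per_pair, pairs_by,
                          by = c("protein", "pos_1", "pos_2"))
  expect_true(all(per$conserved_any[per$shared]))
  expect_false(any(per$conserved_any[!per$shared]))
  expect_equal(s$fraction_conserved, 4 / 6)

  # symmetry on twins: FAM1's shared pair conserved in FAM2 implies the
  # mapped pair in FAM2 is conserved in FAM1
  c12 <- calls[calls$protein == "FAM1" & calls$other_protein == "FAM2", ]
  c21 <- calls[calls$protein == "FAM2" & calls$other_protein == "FAM1", ]
  key <- function(d) paste(pmin(d$pos_1, d$pos_2), pmax(d$pos_1, d$pos_2))
  expect_setequal(key(c12[c12$status == "conserved", ]),
                  key(c21[c21$status == "conserved", ]))
})

test_that("pairs hitting reference gaps are unmappable and excluded from the fraction", {
  master <- c(P1 = "ACDEF", P2 = "AC-EF")
  hmap <- build_homology_map(master)
  pairs <- tibble::tibble(protein = "P1", pos_1 = c(1L, 1L), pos_2 = c(3L, 5L))
  calls <- classify_conservation(pairs, hmap, proteins = c("P1", "P2"))
  expect_equal(calls$status[calls$pos_2 == 3], "unmappable")
  expect_equal(calls$status[calls$pos_2 == 5], "not_conserved")
  s <- summarize_conservation(calls)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$fraction_conserved, 0)
})

test_that("column entropy matches closed forms and a brute-force oracle", {
  single <- aln_from_strings(c("A", "A", "A", "A"),
                             species = c("A.thaliana", "s1", "s2", "s3"))
  expect_equal(column_entropy(single, 1), 0)
  half <- aln_from_strings(c("A", "A", "C", "C"),
                           species = c("A.thaliana", "s1", "s2", "s3"))
  expect_equal(column_entropy(half, 1), log(2))
  all20 <- aln_from_strings(as.list(corrmut:::AA20) |> unlist(),
                            species = c("A.thaliana", paste0("s", 1:19)))
  expect_equal(column_entropy(all20, 1), log(20))

  # gaps excluded, frequencies renormalised
  gapped <- aln_from_strings(c("A", "C", "-", "-"),
                             species = c("A.thaliana", "s1", "s2", "s3"))
  expect_equal(column_entropy(gapped, 1), log(2))
  allgap <- aln_from_strings(c("A-", "C-", "D-"))
  expect_error(column_entropy(allgap, 2), "all-gap")

  withr::with_seed(55, {
    for (rep in 1:10) {
      aln <- random_test_alignment(20, 3, gap_prob = 0.1)
      for (k in 1:3) {
        col <- aln$seqs[, k]
        col <- col[col != "-"]
        if (!length(col)) next
        freq <- table(col) / length(col)
        expect_equal(column_entropy(aln, k), -sum(freq * log(freq)),
                     tolerance = 1e-12)
      }
    }
  })
  # invariance under residue relabeling
  aln <- aln_from_strings(c("AAC", "AAC", "CAD", "DAC"),
                          species = c("A.thaliana", "s1", "s2", "s3"))
  relabel <- aln
  relabel$seqs <- matrix(c(W = "W", A = "Y", C = "K", D = "M")[aln$seqs],
                         nrow = 4)
  relabel$seqs[is.na(relabel$seqs)] <- "-"
  expect_equal(column_entropy(aln, 1), column_entropy(relabel, 1))
})

test_that("entropy comparison flags variable correlated sites against constant homologs", {
  # P1 carries a correlated pair at variable columns 1-2; P2's homologous
  # columns are near-constant, P3 shares the correlated pair.
  mk <- function(c1, c2, id) {
    rows <- cbind(c1, c2, rep("G", 8), rep("H", 8))
    aln_from_strings(apply(rows, 1, paste, collapse = ""),
                     species = c("A.thaliana", paste0("s", 1:7)),
                     family_id = id)
  }
  var1 <- c("K", "K", "D", "D", "K", "D", "K", "D")
  var2 <- c("E", "E", "R", "R", "E", "R", "E", "R")
  const <- rep("A", 8)
  alns <- list(P1 = mk(var1, var2, "P1"),
               P2 = mk(const, const, "P2"),
               P3 = mk(var1, var2, "P3"))
  hmap <- build_homology_map(reference_sequences(alns))
  pairs <- tibble::tibble(protein = c("P1", "P3"), pos_1 = 1L, pos_2 = 2L)
  calls <- classify_conservation(pairs, hmap, proteins = names(alns))
  ec <- entropy_comparison(calls, alns, hmap)
  sm <- ec$summary
  expect_equal(sm$class, "conserved")
  expect_equal(sm$frac_self_higher, 1)
  expect_gt(sm$mean_self, sm$mean_homolog)

  # degenerate: identical alignments give equal entropies; strict inequality
  # counts ties as not-higher
  alns_eq <- list(P1 = mk(var1, var2, "P1"), P2 = mk(var1, var2, "P2"))
  hm2 <- build_homology_map(reference_sequences(alns_eq))
  calls2 <- classify_conservation(tibble::tibble(protein = "P1", pos_1 = 1L,
                                                 pos_2 = 2L),
                                  hm2, proteins = c("P1", "P2"))
  # pair not correlated in P2 -> cases exist, entropies tie
  ec2 <- entropy_comparison(calls2, alns_eq, hm2)
  expect_equal(ec2$summary$frac_self_higher, 0)
})

test_that("intermolecular conserved groups require recurrence across interaction pairs", {
  hmap <- build_homology_map(c(A1 = "ACDEF", A2 = "ACDEF",
                               B1 = "KLMNP", B2 = "KLMNP"))
  pairs <- tibble::tibble(
    interaction_id = c("A1-B1", "A2-B2", "A1-B1"),
    interacting = TRUE,
    protein_1 = c("A1", "A2", "A1"), pos_1 = c(2L, 2L, 4L),
    protein_2 = c("B1", "B2", "B1"), pos_2 = c(3L, 3L, 5L))
  out <- intermolecular_conserved_groups(pairs, hmap)
  # the (2, 3) pair recurs in two interaction pairs; (4, 5) does not
  expect_equal(nrow(out$groups), 1L)
  expect_equal(out$groups$n_interaction_pairs, 2L)
  expect_equal(out$counts$n_groups[out$counts$set == "interacting"], 1L)
  expect_equal(out$counts$n_pairs_total[out$counts$set == "interacting"], 3L)

  none <- intermolecular_conserved_groups(pairs[c(1, 3), ], hmap)
  expect_equal(nrow(none$groups), 0L)
})
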