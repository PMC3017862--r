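cm_tbl <- function(p1, p2, mode = "intra") {
  tibble::tibble(molecule_1 = "X", column_1 = p1, ref_pos_1 = p1,
                 molecule_2 = if (mode == "intra") "X" else "Y",
                 column_2 = p2, ref_pos_2 = p2, r = 0.5,
                 n_pairs_used = 100L, mode = mode, time_corrected = TRUE)
}

test_that("add-one subset p-values hit the extreme cases", {
  bg <- 1:100
  # observed below every replicate statistic -> p = 1
  t_low <- random_subset_pvalue(-1, bg, 5, statistic = mean, reps = 50, seed = 1)
  expect_equal(t_low$p_value, 1)
  # observed above every replicate -> p = 1 / (reps + 1)
  t_high <- random_subset_pvalue(1e9, bg, 5, statistic = mean, reps = 1000,
                                 seed = 1)
  expect_equal(t_high$p_value, 1 / 1001)
  expect_error(random_subset_pvalue(1, bg, 500, mean, reps = 5), "exceeds")
})

test_that("distance enrichment reproduces the identity cases", {
  d <- tibble::tibble(chain_i = "A", res_i = c(1L, 1L, 2L),
                      chain_j = "A", res_j = c(2L, 3L, 3L),
                      pair_type = "intra", distance = c(4, 5, 6))
  # all evaluated pairs below threshold
  en <- distance_enrichment(cm_tbl(1L, 2L), d, thresholds = 15, reps = 20,
                            seed = 2)
  expect_equal(en$observed_fraction, 1)
  # evaluated set identical to the background set -> fractions equal
  en2 <- distance_enrichment(cm_tbl(c(1L, 1L, 2L), c(2L, 3L, 3L)), d,
                             thresholds = 5, reps = 20, seed = 2)
  expect_equal(en2$observed_fraction, en2$background_fraction)
  # unmapped pairs are dropped and counted
  en3 <- distance_enrichment(cm_tbl(c(1L, 7L), c(2L, 9L)), d, thresholds = 15,
                             reps = 20, seed = 2)
  expect_equal(en3$n_unmapped, 1L)
  expect_error(distance_enrichment(cm_tbl(7L, 9L), d, reps = 5), "zero")
})

test_that("planted contacts give significant enrichment", {
  planted <- tibble::tibble(pos_1 = c(4L, 20L, 40L), pos_2 = c(60L, 33L, 77L))
  ts <- make_toy_structure(n_res = 90, planted_pairs = planted, seed = 17)
  en <- distance_enrichment(cm_tbl(planted$pos_1, planted$pos_2),
                            ts$distances, thresholds = c(15, 10),
                            reps = 1000, seed = 3)
  expect_true(all(en$observed_fraction > en$background_fraction))
  expect_true(all(en$p_value <= 0.01))
})

test_that("shuffling the pairing destroys planted intermolecular signal", {
  sets <- simulate_interaction_set(n_interacting = 1, n_noninteracting = 0,
                                   n_seq = 50, n_col_a = 40, n_col_b = 40,
                                   n_planted = 3, seed = 23)
  pa <- sets$interacting[[1]]
  test <- shuffle_pairing_null(pa, reps = 15, seed = 4)
  expect_lt(mean(test$null), test$observed)
  # the identity permutation reproduces the observed statistic
  expect_equal(nrow(detect_correlated_pairs(
    permute_partner(pa, seq_len(alignment_nrow(pa))))), test$observed)
  # fixed seed -> identical null
  test2 <- shuffle_pairing_null(pa, reps = 15, seed = 4)
  expect_identical(test$null, test2$null)
})

test_that("motif overlap coverages and F-score follow the definitions", {
  motifs <- tibble::tibble(motif_id = c("m1", "m2"), protein = c("X", "Y"),
                           start = c(1L, 5L), end = c(4L, 8L))
  cm <- tibble::tibble(protein = c("X", "X", "Y"), position = c(2L, 20L, 6L))
  ov <- motif_overlap(cm, motifs)
  expect_equal(ov$coverage_motif, 2 / 8)
  expect_equal(ov$coverage_cm, 2 / 3)
  expect_equal(ov$f_score, harmonic_f(2 / 8, 2 / 3))

  # full coverage on both sides
  full <- motif_overlap(tibble::tibble(protein = "X", position = 1:4),
                        motifs[1, ])
  expect_equal(full$f_score, 1)
  # zero coverage
  none <- motif_overlap(tibble::tibble(protein = "X", position = 9L),
                        motifs[1, ])
  expect_equal(none$f_score, 0)
  expect_error(motif_overlap(cm, motifs[0, ]), "empty")

  expect_equal(harmonic_f(0.55, 0.39), 2 * 0.55 * 0.39 / 0.94)
  expect_equal(harmonic_f(0.3, 0.7), harmonic_f(0.7, 0.3))
  expect_lte(harmonic_f(0.3, 0.7), mean(c(0.3, 0.7)))
})

test_that("consistent overlap is molecule-matched and counted per interaction pair", {
  motifs <- tibble::tibble(
    motif_id = c("mA", "mB"), protein = c("X", "Y"),
    start = c(10L, 40L), end = c(14L, 44L),
    partner_motif_id = c("mB", "mA"))
  pairs <- tibble::tibble(
    interaction_id = c("i1", "i2", "i3", "i4", "i5"),
    protein_1 = "X", pos_1 = c(11L, 12L, 13L, 11L, 11L),
    protein_2 = "Y", pos_2 = c(41L, 42L, 43L, 44L, 70L))
  out <- consistent_overlap(pairs, motifs)
  expect_equal(out$n_interaction_pairs, 4L)   # i5 is inconsistent (pos_2 outside)
  expect_equal(out$n_cm_pairs, 4L)

  bad <- dplyr::mutate(motifs, protein = "X")
  expect_error(consistent_overlap(pairs, bad), "single molecule")
})

test_that("position randomization respects saturation and shared-position consistency", {
  lengths <- c(X = 50L, Y = 50L)
  pairs <- tibble::tibble(protein_1 = "X", pos_1 = c(3L, 3L, 9L),
                          protein_2 = "Y", pos_2 = c(30L, 31L, 30L))
  # motifs covering everything: F invariant under randomization, p ~ 1
  all_motifs <- tibble::tibble(motif_id = c("a", "b"), protein = c("X", "Y"),
                               start = 1L, end = 50L)
  sat <- randomize_positions_pvalue(pairs, lengths, all_motifs, reps = 50,
                                    seed = 5)
  expect_equal(sat$p_value, 1)
  expect_true(all(sat$null == sat$observed))

  # sparse motifs sitting exactly on the observed positions: p small
  exact <- tibble::tibble(motif_id = c("a", "b", "c"),
                          protein = c("X", "X", "Y"),
                          start = c(3L, 9L, 30L), end = c(3L, 9L, 31L))
  hit <- randomize_positions_pvalue(pairs, lengths, exact, reps = 400, seed = 6)
  expect_lt(hit$p_value, 0.05)
})

test_that("SNP overlap counts are conserved and fractions match hand values", {
  snps <- tibble::tibble(protein = "X",
                         position = c(1L, 2L, 3L, 4L),
                         class = c("non-synonymous", "non-synonymous",
                                   "synonymous", "synonymous"))
  cm <- tibble::tibble(protein = "X", position = c(2L, 3L))
  out <- snp_overlap(snps, cm)
  expect_equal(out$n_overlap + out$n_no_overlap, c(2L, 2L))
  expect_equal(out$fraction[out$class == "non-synonymous"], 0.5)

  empty <- snp_overlap(snps[snps$class == "none", ], cm)
  expect_equal(nrow(empty), 0L)

  # per-set accounting with the set column on both sides
  snps2 <- dplyr::mutate(snps, set = c("int", "int", "non", "non"))
  cm2 <- dplyr::mutate(cm, set = c("int", "non"))
  out2 <- snp_overlap(snps2, cm2)
  expect_equal(sum(out2$n_overlap), 2L)
})
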