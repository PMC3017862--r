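ref_set <- tibble::tibble(
  seq_id = c("refX", "refY"),
  seq = c("AAAAAAAAAA", "CCCCCCCCCC")
)

test_that("candidates are assigned to their maximum-identity reference", {
  cands <- tibble::tibble(
    seq_id = c("c1", "c2"),
    species = c("sp1", "sp1"),
    source = c("blast", "blast"),
    seq = c("AAAAAACCCC",   # 0.6 to refX, 0.4 to refY
            "CCCCCCCCCA")   # 0.9 to refY
  )
  asg <- assign_best_hits(cands, ref_set)
  expect_equal(asg$best_reference, c("refX", "refY"))
  expect_equal(asg$identity, c(0.6, 0.9))
  expect_true(all(asg$bidirectional_confirmed))
})

test_that("ties go to the lexicographically smaller reference with a warning", {
  cands <- tibble::tibble(seq_id = "c1", species = "sp1", source = "blast",
                          seq = "AAAAACCCCC")
  expect_warning(asg <- assign_best_hits(cands, ref_set), "tied")
  expect_equal(asg$best_reference, "refX")
})

test_that("the bidirectional rule drops genome candidates that are not the reference's best hit", {
  # g1 best-hits refX, but refX's best genome hit in sp1 is g2
  cands <- tibble::tibble(
    seq_id = c("g1", "g2"),
    species = "sp1", source = "genome",
    seq = c("AAAAAACCCC",   # 0.6 to refX
            "AAAAAAAACC")   # 0.8 to refX
  )
  asg <- assign_best_hits(cands, ref_set)
  expect_equal(asg$best_reference, c("refX", "refX"))
  expect_equal(asg$bidirectional_confirmed, c(FALSE, TRUE))
  # same sequences from a unidirectional source are both kept
  asg2 <- assign_best_hits(dplyr::mutate(cands, source = "blast"), ref_set)
  expect_true(all(asg2$bidirectional_confirmed))
})

test_that("degenerate best-hit inputs behave", {
  expect_error(assign_best_hits(
    tibble::tibble(seq_id = "c", species = "s", source = "blast", seq = "AA"),
    ref_set[0, ]), "empty")
  one <- assign_best_hits(
    tibble::tibble(seq_id = "c", species = "s", source = "blast",
                   seq = "AAAAAAAAAA"),
    ref_set[1, ])
  expect_equal(one$best_reference, "refX")
})

test_that("greedy centroid clustering follows input order and the cutoff", {
  two_same <- tibble::tibble(seq_id = c("a", "b"),
                             seq = c("AAAAAAAAAAAAAAAAAAAA",
                                     "AAAAAAAAAAAAAAAAAAAA"))
  expect_equal(cluster_within_species(two_same)$cluster, c(1L, 1L))

  far <- tibble::tibble(seq_id = c("a", "b"),
                        seq = c("AAAAAAAAAAAAAAAAAAAA",
                                "AAAAAAAAAACCCCCCCCCC"))
  expect_equal(cluster_within_species(far)$cluster, c(1L, 2L))

  # identities to centroid a: b 0.95, c 0.95; b and c join a's cluster even
  # though (b, c) alone would be below the cutoff
  abc <- tibble::tibble(
    seq_id = c("a", "b", "c"),
    seq = c("AAAAAAAAAAAAAAAAAAAA",
            "CAAAAAAAAAAAAAAAAAAA",
            "AAAAAAAAAAAAAAAAAAAC"))
  got <- cluster_within_species(abc, cutoff = 0.95)
  expect_equal(got$cluster, c(1L, 1L, 1L))
  expect_equal(pairwise_identity(abc$seq[2], abc$seq[3]), 0.9)
})

test_that("representative selection honours source priority, seeded ties", {
  expect_equal(select_representative(
    tibble::tibble(seq_id = c("b", "g"), source = c("blast", "genome"))), "g")
  expect_equal(select_representative(
    tibble::tibble(seq_id = c("i", "b"), source = c("interpro", "blast"))), "i")
  cl <- tibble::tibble(seq_id = c("b1", "b2"), source = c("blast", "blast"))
  pick1 <- withr::with_seed(3, select_representative(cl))
  pick2 <- withr::with_seed(3, select_representative(cl))
  expect_identical(pick1, pick2)
  expect_error(select_representative(cl[0, ]), "empty")
})

test_that("the minimum-identity filter is inclusive and idempotent", {
  asg <- tibble::tibble(seq_id = c("a", "b", "c"),
                        identity = c(0.24, 0.25, 0.9))
  kept <- filter_min_identity(asg)
  expect_equal(kept$seq_id, c("b", "c"))
  expect_equal(filter_min_identity(kept), kept)
  expect_equal(nrow(filter_min_identity(asg[0, ])), 0L)
})

test_that("co-ortholog pairing is the per-species Cartesian product", {
  a <- tibble::tibble(seq_id = c("a1", "a2", "a3"),
                      species = c("sp1", "sp1", "sp2"))
  b <- tibble::tibble(seq_id = c("b1", "b2"),
                      species = c("sp1", "sp1"))
  pairs <- build_intermolecular_pairs(a, b)
  expect_equal(nrow(pairs), 4L)  # 2 co-orthologs each side: 2 * 2 combinations
  expect_equal(nrow(build_intermolecular_pairs(a[3, ], b[0, ])), 0L)
  one <- build_intermolecular_pairs(a[1, ], b[1, ])
  expect_equal(nrow(one), 1L)

  # oracle: brute-force enumeration per species
  withr::with_seed(11, {
    for (rep in 1:5) {
      na <- sample(0:4, 3, replace = TRUE)
      nb <- sample(0:4, 3, replace = TRUE)
      sp <- paste0("s", 1:3)
      A <- tibble::tibble(seq_id = paste0("a", seq_len(sum(na))),
                          species = rep(sp, na))
      B <- tibble::tibble(seq_id = paste0("b", seq_len(sum(nb))),
                          species = rep(sp, nb))
      expect_equal(nrow(build_intermolecular_pairs(A, B)), sum(na * nb))
    }
  })
})

test_that("the minimum-rows threshold is inclusive at 30", {
  expect_true(apply_min_rows(30))
  expect_false(apply_min_rows(29))
  expect_false(apply_min_rows(0))
  expect_true(apply_min_rows(5, minimum = 5))
})

test_that("full assembly keeps only filtered cluster representatives, reproducibly", {
  withr::with_seed(5, {
    base_x <- paste(sample(c("A", "C", "D", "E"), 40, replace = TRUE), collapse = "")
    mutate_seq <- function(s, k) {
      v <- strsplit(s, "")[[1]]
      idx <- sample(length(v), k)
      v[idx] <- sample(c("F", "G", "H"), k, replace = TRUE)
      paste(v, collapse = "")
    }
    refs <- tibble::tibble(seq_id = c("refX", "refY"),
                           seq = c(base_x, mutate_seq(base_x, 25)))
    cands <- tibble::tibble(
      seq_id = paste0("c", 1:6),
      species = c("sp1", "sp1", "sp1", "sp2", "sp2", "sp2"),
      source = c("blast", "interpro", "blast", "genome", "blast", "blast"),
      seq = c(mutate_seq(base_x, 1), mutate_seq(base_x, 1), mutate_seq(base_x, 12),
              mutate_seq(base_x, 2), mutate_seq(base_x, 2),
              paste(rep("W", 40), collapse = ""))  # below 25% to anything
    )
  })
  run <- function() {
    withr::with_seed(42, suppressWarnings(assemble_orthologs(cands, refs)))
  }
  out1 <- run(); out2 <- run()
  expect_identical(out1, out2)                      # deterministic under seed
  expect_false("c6" %in% out1$seq_id)               # identity filter
  expect_true(all(out1$identity >= 0.25))
  expect_true(all(out1$representative))
  # within sp1/refX, c1 and c2 are near-identical: one representative survives,
  # and it is the interpro member by priority
  sp1 <- out1[out1$species == "sp1", ]
  expect_true("c2" %in% sp1$seq_id)
})
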