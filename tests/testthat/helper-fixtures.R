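# Builders and independent oracles shared across the suite.

aln_from_strings <- function(strings, species = NULL, source = NULL,
                             family_id = "TST") {
  n <- length(strings)
  family_alignment(
    strings,
    seq_id = sprintf("%s_r%02d", family_id, seq_len(n)),
    species = species %||% c("A.thaliana", sprintf("sp%02d", seq_len(n - 1))),
    source = source %||% c("reference", rep("blast", n - 1)),
    family_id = family_id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for the engine: explicit loops, no matrix algebra shared
# with the implementation. Returns the correlation of the site variability
# vectors of two columns, or NA where the engine should skip the pair.
brute_force_column_correlation <- function(mat, col_a, col_b,
                                           time_correction = FALSE,
                                           blosum = corrmut:::get_blosum("62"),
                                           max_gap_frac = 0.1,
                                           min_pairs = 2L) {
  n <- nrow(mat)
  gap_frac <- function(k) mean(!(mat[, k] %in% rownames(blosum)))
  if (gap_frac(col_a) > max_gap_frac || gap_frac(col_b) > max_gap_frac) {
    return(NA_real_)
  }
  vec <- function(k) {
    v <- c(); lab <- c(); tv <- c()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ai <- mat[i, k]; aj <- mat[j, k]
        if (!(ai %in% rownames(blosum)) || !(aj %in% rownames(blosum))) next
        t <- 1
        if (time_correction) {
          both <- mat[i, ] %in% rownames(blosum) & mat[j, ] %in% rownames(blosum)
          p <- mean(mat[i, both] != mat[j, both])
          if (p >= 1) next
          t <- -log(1 - p)
          if (t <= 0) next
        }
        v <- c(v, blosum[ai, aj]); tv <- c(tv, t); lab <- c(lab, paste(i, j))
      }
    }
    # centre the raw scores over the defined pairs, normalise by divergence
    # time, re-centre (mirrors the stated definition, in loop form)
    v <- (v - mean(v)) / tv
    stats::setNames(v - mean(v), lab)
  }
  va <- vec(col_a); vb <- vec(col_b)
  common <- intersect(names(va), names(vb))
  if (length(common) < min_pairs) return(NA_real_)
  x <- va[common]; y <- vb[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Engine-facing wrapper: full correlation matrix from detect's internals is
# not exposed, so recompute a single pair through exported pieces.
engine_column_correlation <- function(aln, col_a, col_b,
                                      time_correction = FALSE) {
  va <- site_variability_vector(aln, col_a, time_correction = time_correction)
  vb <- site_variability_vector(aln, col_b, time_correction = time_correction)
  site_pair_correlation(va, vb)
}

random_test_alignment <- function(n_seq, n_col, gap_prob = 0) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  mat <- matrix(sample(aa, n_seq * n_col, replace = TRUE), n_seq, n_col)
  if (gap_prob > 0) {
    mat[matrix(stats::runif(n_seq * n_col) < gap_prob, n_seq, n_col)] <- "-"
  }
  aln_from_strings(apply(mat, 1, paste, collapse = ""))
}

# Brute-force all-atom minimum-distance scan reading a PDB file with base
# string tools only (independent of both bio3d and the generator's tables).
brute_force_pdb_distances <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  chain <- substr(lines, 22, 22)
  resno <- as.integer(substr(lines, 23, 26))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  key <- paste(chain, resno)
  res <- unique(key)
  out <- list()
  for (i in seq_along(res)[-length(res)]) {
    for (j in (i + 1):length(res)) {
      ai <- which(key == res[i]); aj <- which(key == res[j])
      best <- Inf
      for (a in ai) for (b in aj) {
        d <- sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2 + (z[a] - z[b])^2)
        if (d < best) best <- d
      }
      out[[length(out) + 1]] <- data.frame(key_i = res[i], key_j = res[j],
                                           distance = best)
    }
  }
  do.call(rbind, out)
}

pair_keys <- function(pairs) {
  paste(pmin(pairs$column_1, pairs$column_2),
        pmax(pairs$column_1, pairs$column_2))
}

planted_keys <- function(planted) {
  paste(pmin(planted$pos_1, planted$pos_2),
        pmax(planted$pos_1, planted$pos_2))
}
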