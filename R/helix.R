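#' Call helix intervals from a coiled-coil probability track
#'
#' Maximal runs of consecutive residues with coil probability at least `pmin`
#' and run length at least `minlen` (the thresholds used to turn per-residue
#' coiled-coil predictor output into helix intervals).
#'
#' @param track Numeric vector of per-residue probabilities, or a tibble with
#'   `position` and `probability` columns (positions must be consecutive).
#' @param pmin Minimum probability (default 0.5, inclusive).
#' @param minlen Minimum run length (default 4).
#' @return Tibble: `helix_id`, `start`, `end`, `length` (positions in the
#'   track's coordinate system; intervals closed, sorted, non-overlapping).
#' @export
call_helices <- function(track, pmin = 0.5, minlen = 4L) {
  if (is.data.frame(track)) {
    ord <- order(track$position)
    if (!all(diff(track$position[ord]) == 1L)) {
      abort("track positions must be consecutive")
    }
    offset <- track$position[ord][1] - 1L
    prob <- track$probability[ord]
  } else {
    offset <- 0L
    prob <- track
  }
  if (any(prob < 0 | prob > 1)) abort("probabilities must lie in [0, 1]")
  r <- rle(prob >= pmin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minlen
  out <- tibble(start = starts[keep] + offset, end = ends[keep] + offset) |>
    dplyr::mutate(helix_id = dplyr::row_number(),
                  length = .data$end - .data$start + 1L) |>
    dplyr::select("helix_id", "start", "end", "length")
  out
}

# index of the helix containing each position (NA if none)
helix_of <- function(position, helices) {
  vapply(position, function(p) {
    hit <- which(helices$start <= p & helices$end >= p)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Histogram of within-helix sequence separations of correlated pairs
#'
#' Intramolecular correlated pairs with both positions inside the same helix
#' are binned by sequence separation `d = |i - j|` (reference residue
#' coordinates); pairs straddling helices or outside all helices are excluded.
#' With `protein` columns in both inputs, pairs are matched to their protein's
#' helices and pooled.
#'
#' @param cm_pairs Tibble with `pos_1`, `pos_2` (optional `protein`).
#' @param helices Helix tibble from [call_helices()] (optional `protein`).
#' @return Tibble of class `separation_histogram`: `separation`, `count`,
#'   `pct` (percentages sum to 100 over observed separations). Attributes
#'   `n_total` (eligible pairs) and `n_excluded`.
#' @export
separation_histogram <- function(cm_pairs, helices) {
  by_protein <- "protein" %in% names(cm_pairs) && "protein" %in% names(helices)
  sep <- if (by_protein) {
    unlist(purrr::map(unique(cm_pairs$protein), function(prot) {
      eligible_separations(cm_pairs[cm_pairs$protein == prot, ],
                           helices[helices$protein == prot, ])
    }))
  } else {
    eligible_separations(cm_pairs, helices)
  }
  n_pairs <- nrow(cm_pairs)
  out <- if (length(sep)) {
    tibble(separation = as.integer(names(table(sep))),
           count = as.integer(table(sep))) |>
      dplyr::mutate(pct = 100 * .data$count / sum(.data$count))
  } else {
    tibble(separation = integer(0), count = integer(0), pct = numeric(0))
  }
  attr(out, "n_total") <- length(sep)
  attr(out, "n_excluded") <- n_pairs - length(sep)
  class(out) <- c("separation_histogram", class(out))
  out
}

eligible_separations <- function(cm_pairs, helices) {
  if (nrow(cm_pairs) == 0L || nrow(helices) == 0L) return(integer(0))
  h1 <- helix_of(cm_pairs$pos_1, helices)
  h2 <- helix_of(cm_pairs$pos_2, helices)
  same <- !is.na(h1) & !is.na(h2) & h1 == h2
  d <- abs(cm_pairs$pos_1 - cm_pairs$pos_2)[same]
  d[d >= 1]
}

#' Helix periodicity statistic: i,i+4 versus i,i+2 preference
#'
#' The difference, in percentage points, between the share of within-helix
#' correlated pairs at sequence separation 4 (one helical turn) and at
#' separation 2 (opposite helix face): `delta = pct(d = 4) - pct(d = 2)`.
#'
#' @param hist A `separation_histogram`.
#' @param d_high,d_low Separations compared (defaults 4 and 2).
#' @return Numeric difference in \[-100, 100\].
#' @export
periodicity_statistic <- function(hist, d_high = 4L, d_low = 2L) {
  if (attr(hist, "n_total") %||% sum(hist$count) == 0L) {
    abort("empty separation histogram: statistic undefined")
  }
  pct_at <- function(d) {
    i <- match(d, hist$separation)
    if (is.na(i)) 0 else hist$pct[i]
  }
  pct_at(d_high) - pct_at(d_low)
}

#' Random-stretch null for the helix periodicity statistic
#'
#' Per replicate, sequence stretches with the same number and lengths as the
#' called helices are placed uniformly at random, without overlap, within the
#' analyzed region; the periodicity statistic is recomputed against the same
#' correlated pairs and the add-one p-value of the observed statistic
#' returned. With `protein` columns present, stretch placement and the
#' statistic are pooled across proteins.
#'
#' @param cm_pairs Intramolecular pairs (`pos_1`, `pos_2`, optional `protein`).
#' @param helices Helix tibble (optional `protein`).
#' @param region Length of the analyzed region, or `c(start, end)`; with
#'   proteins, a tibble `protein`, `start`, `end`.
#' @param reps Replicates (default 1000).
#' @param seed Optional seed.
#' @param d_high,d_low Separations compared (defaults 4 and 2).
#' @return Object of class `periodicity_test` (a `randomization_test` with the
#'   observed separation histogram attached).
#' @export
random_stretch_null <- function(cm_pairs, helices, region, reps = 1000,
                                seed = NULL, d_high = 4L, d_low = 2L) {
  if (reps < 1) abort("reps must be >= 1")
  by_protein <- "protein" %in% names(cm_pairs) && "protein" %in% names(helices)
  regions <- normalise_regions(region, by_protein,
                               if (by_protein) unique(helices$protein))
  obs_hist <- separation_histogram(cm_pairs, helices)
  observed <- periodicity_statistic(obs_hist, d_high, d_low)

  one_rep <- function() {
    rh <- if (by_protein) {
      purrr::map_dfr(unique(helices$protein), function(prot) {
        reg <- regions[regions$protein == prot, ]
        h <- helices[helices$protein == prot, ]
        place_stretches(h$length, reg$start, reg$end) |>
          dplyr::mutate(protein = prot)
      })
    } else {
      place_stretches(helices$length, regions$start, regions$end)
    }
    hist <- separation_histogram(cm_pairs, rh)
    if ((attr(hist, "n_total") %||% 0L) == 0L) return(0)
    periodicity_statistic(hist, d_high, d_low)
  }
  null <- with_optional_seed(seed, vapply(seq_len(reps), function(i) one_rep(),
                                          numeric(1)))
  test <- new_randomization_test("random_stretch", observed, null,
                                 extra = list(histogram = obs_hist,
                                              d_high = d_high, d_low = d_low))
  class(test) <- c("periodicity_test", class(test))
  test
}

normalise_regions <- function(region, by_protein, proteins = NULL) {
  if (is.data.frame(region)) return(region)
  se <- if (length(region) == 1L) c(1L, region) else region
  if (by_protein) {
    tibble(protein = proteins, start = se[1], end = se[2])
  } else {
    tibble(start = se[1], end = se[2])
  }
}

# Uniformly place non-overlapping stretches of the given lengths in
# [region_start, region_end]; stretch order is shuffled per call.
place_stretches <- function(lengths, region_start, region_end) {
  lengths <- sample(lengths)
  k <- length(lengths)
  n <- region_end - region_start + 1L
  slack <- n - sum(lengths)
  if (slack < 0) abort("stretches cannot be placed without overlap in the region")
  v <- sort(sample.int(slack + k, k))
  starts <- region_start + (v - seq_len(k)) +
    c(0L, cumsum(lengths))[seq_len(k)]
  tibble(helix_id = seq_len(k), start = as.integer(starts),
         end = as.integer(starts + lengths - 1L), length = lengths)
}

#' Tabulate correlated pairs by helix or domain bins
#'
#' Counts correlated pairs whose two positions fall in a pair of declared
#' intervals (helices, or named domains such as the DNA-binding and
#' intervening regions). Intramolecular mode uses one bin set and counts
#' unordered bin pairs; intermolecular mode bins position 1 against `bins_1`
#' and position 2 against `bins_2`.
#'
#' @param cm_pairs Tibble with `pos_1`, `pos_2`.
#' @param bins_1 Tibble `name`, `start`, `end` (non-overlapping intervals).
#' @param bins_2 Second bin set for intermolecular mode; `NULL` (default) for
#'   intramolecular mode.
#' @return Tibble of class `contact_table`: `bin_1`, `bin_2`, `count` over the
#'   full bin grid; attribute `n_unbinned` counts pairs with a position
#'   outside all bins.
#' @export
helix_contact_table <- function(cm_pairs, bins_1, bins_2 = NULL) {
  intra <- is.null(bins_2)
  if (intra) bins_2 <- bins_1
  bin_at <- function(pos, bins) {
    i <- vapply(pos, function(p) {
      hit <- which(bins$start <= p & bins$end >= p)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    bins$name[i]
  }
  b1 <- bin_at(cm_pairs$pos_1, bins_1)
  b2 <- bin_at(cm_pairs$pos_2, bins_2)
  ok <- !is.na(b1) & !is.na(b2)
  if (intra) {
    o1 <- match(b1, bins_1$name); o2 <- match(b2, bins_1$name)
    swap <- ok & o1 > o2
    tmp <- b1[swap]; b1[swap] <- b2[swap]; b2[swap] <- tmp
  }
  grid <- tidyr::expand_grid(bin_1 = bins_1$name, bin_2 = bins_2$name)
  if (intra) {
    grid <- grid[match(grid$bin_1, bins_1$name) <= match(grid$bin_2, bins_1$name), ]
  }
  counts <- dplyr::count(tibble(bin_1 = b1[ok], bin_2 = b2[ok]),
                         .data$bin_1, .data$bin_2, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("bin_1", "bin_2")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(out, "n_unbinned") <- sum(!ok)
  class(out) <- c("contact_table", class(out))
  out
}

#' Default domain intervals for MIKC-type reference coordinates
#'
#' Declared intervals for the DNA-binding (MADS) and intervening (I) domains
#' used when tabulating helix-to-domain contacts; coordinates are configurable
#' because domain boundaries vary between proteins.
#'
#' @param mads_end Last residue of the MADS domain (default 58).
#' @param i_end Last residue of the I domain (default 89).
#' @return Bin tibble usable as `bins_1`/`bins_2` in [helix_contact_table()].
#' @export
default_domain_bins <- function(mads_end = 58L, i_end = 89L) {
  tibble(name = c("MADS", "I"),
         start = c(1L, mads_end + 1L),
         end = c(mads_end, i_end))
}
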