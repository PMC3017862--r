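#' Minimum heavy-atom distances between residue pairs of a PDB structure
#'
#' For every residue pair within each requested chain and across each pair of
#' requested chains, computes the minimum Euclidean distance over all pairs of
#' heavy atoms (hydrogens are ignored). Alternate locations keep the first
#' altloc; insertion-coded residues are skipped with a warning.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain_ids Character vector of chains to use; default: all chains.
#' @return A tibble of class `structure_distances` with columns `chain_i`,
#'   `res_i`, `chain_j`, `res_j`, `pair_type` (`"intra"` or `"inter"`) and
#'   `distance` (Angstrom). Each unordered pair appears once (`res_i < res_j`
#'   within a chain; `chain_i < chain_j` across chains).
#' @export
min_heavy_atom_distances <- function(pdb_path, chain_ids = NULL) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_ids)) chain_ids <- sort(unique(at$chain))
  missing <- setdiff(chain_ids, unique(at$chain))
  if (length(missing)) {
    abort(sprintf("chain(s) not present in structure: %s",
                  paste(missing, collapse = ", ")))
  }
  at <- at[at$chain %in% chain_ids, , drop = FALSE]
  # heavy atoms only
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "", at$elety[is.na(elem) | elem == ""]), 1, 1)
  at <- at[toupper(trimws(elem)) != "H", , drop = FALSE]
  # first altloc only
  at <- at[at$alt %in% c("", "A", NA), , drop = FALSE]
  # skip insertion-coded residues
  ins <- !(at$insert %in% c("", " ", NA))
  if (any(ins)) {
    warn(sprintf("skipping %d atoms in insertion-coded residues",
                 sum(ins)))
    at <- at[!ins, , drop = FALSE]
  }
  if (nrow(at) == 0L) abort("no heavy atoms found")

  key <- paste(at$chain, at$resno, sep = ":")
  groups <- split(seq_len(nrow(at)), key)
  info <- do.call(rbind, strsplit(names(groups), ":", fixed = TRUE))
  res_chain <- info[, 1]
  res_no <- as.integer(info[, 2])
  ord <- order(res_chain, res_no)
  groups <- groups[ord]; res_chain <- res_chain[ord]; res_no <- res_no[ord]
  xyz <- as.matrix(at[, c("x", "y", "z")])

  n <- length(groups)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    ci <- xyz[groups[[i]], , drop = FALSE]
    js <- (i + 1L):n
    d <- vapply(js, function(j) {
      cj <- xyz[groups[[j]], , drop = FALSE]
      # min over all heavy-atom pairs
      dx <- outer(ci[, 1], cj[, 1], "-")
      dy <- outer(ci[, 2], cj[, 2], "-")
      dz <- outer(ci[, 3], cj[, 3], "-")
      sqrt(min(dx * dx + dy * dy + dz * dz))
    }, numeric(1))
    out[[i]] <- tibble(
      chain_i = res_chain[i], res_i = res_no[i],
      chain_j = res_chain[js], res_j = res_no[js],
      distance = d
    )
  }
  res <- dplyr::bind_rows(out)
  res$pair_type <- ifelse(res$chain_i == res$chain_j, "intra", "inter")
  # canonical ordering of each unordered pair
  swap <- (res$pair_type == "intra" & res$res_i > res$res_j) |
    (res$pair_type == "inter" & res$chain_i > res$chain_j)
  if (any(swap)) {
    tmp_c <- res$chain_i[swap]; tmp_r <- res$res_i[swap]
    res$chain_i[swap] <- res$chain_j[swap]; res$res_i[swap] <- res$res_j[swap]
    res$chain_j[swap] <- tmp_c; res$res_j[swap] <- tmp_r
  }
  res <- res[, c("chain_i", "res_i", "chain_j", "res_j", "pair_type", "distance")]
  class(res) <- c("structure_distances", class(res))
  res
}

#' Renumber structure residues into reference-protein coordinates
#'
#' Applies a structure-residue to reference-residue mapping table (for example
#' built from a pairwise alignment of the reference sequence to the structure
#' sequence). Residue pairs with either residue outside the mapped range are
#' dropped.
#'
#' @param distances A `structure_distances` tibble.
#' @param mapping Tibble with columns `structure_res` and `reference_res`
#'   (injective over the mapped range), optionally `chain`.
#' @return The distance tibble with `res_i`/`res_j` renumbered.
#' @export
map_structure_residues <- function(distances, mapping) {
  if (anyDuplicated(mapping$structure_res)) {
    abort("mapping must be injective: duplicated structure_res")
  }
  lut <- setNames(mapping$reference_res, mapping$structure_res)
  ri <- unname(lut[as.character(distances$res_i)])
  rj <- unname(lut[as.character(distances$res_j)])
  keep <- !is.na(ri) & !is.na(rj)
  out <- distances[keep, , drop = FALSE]
  out$res_i <- as.integer(ri[keep])
  out$res_j <- as.integer(rj[keep])
  swap <- out$pair_type == "intra" & out$res_i > out$res_j
  if (any(swap)) {
    tmp <- out$res_i[swap]; out$res_i[swap] <- out$res_j[swap]; out$res_j[swap] <- tmp
  }
  out
}

#' Read / write residue-pair distance tables
#'
#' TSV with header `chain_i res_i chain_j res_j pair_type distance`.
#'
#' @param path File path.
#' @return A `structure_distances` tibble.
#' @export
read_distances <- function(path) {
  res <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chain_i = "c", res_i = "i", chain_j = "c",
                           res_j = "i", pair_type = "c", distance = "d"))
  if (any(res$distance <= 0)) abort("distances must be positive")
  class(res) <- c("structure_distances", class(res))
  res
}

#' @rdname read_distances
#' @param distances A `structure_distances` tibble.
#' @export
write_distances <- function(distances, path) {
  readr::write_tsv(distances, path)
  invisible(path)
}
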