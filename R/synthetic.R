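#' Generate synthetic protein families by per-site mutation
#'
#' Draws a uniform-random common ancestor, derives one root sequence per
#' family by mutating the ancestor at `between_divergence` per site (each
#' selected site is replaced by a uniform draw from the 20-letter alphabet,
#' so it may keep its residue with probability 1/20), then derives
#' `seqs_per_family` descendants from each root at `within_divergence` per
#' site.  Two descendants of one root therefore differ at an expected
#' fraction of roughly `2 * w * 19/20` of sites for small within-divergence
#' `w`.  Ids encode family membership as `F<family>_S<seq>`.
#'
#' The defaults (3 families of 5 sequences, 300 residues, 5% within / 40%
#' between divergence) give families that are tight relative to their
#' separation - the regime in which family recovery by a distance-based tree
#' is expected to succeed.
#'
#' @param n_families Number of families.
#' @param seqs_per_family Descendants per family.
#' @param root_length Sequence length in residues.
#' @param within_divergence Per-site substitution probability within a
#'   family, in `[0, 1]`.
#' @param between_divergence Per-site substitution probability between the
#'   ancestor and each family root, in `[0, 1]`; should exceed
#'   `within_divergence` for a meaningful family structure.
#' @param seed Integer seed; the generator is fully reproducible and leaves
#'   the caller's RNG stream untouched.
#' @return A data frame with columns `id`, `description`, `sequence` (same
#'   shape as [read_fasta()] output).
#' @examples
#' fam <- generate_synthetic_families(seed = 1)
#' table(sub("_.*", "", fam$id))
#' @export
generate_synthetic_families <- function(n_families = 3L,
                                        seqs_per_family = 5L,
                                        root_length = 300L,
                                        within_divergence = 0.05,
                                        between_divergence = 0.4,
                                        seed = 1L) {
  stopifnot(n_families >= 1L, seqs_per_family >= 1L, root_length >= 1L,
            within_divergence >= 0, within_divergence <= 1,
            between_divergence >= 0, between_divergence <= 1)
  if (within_divergence >= between_divergence &&
      !(within_divergence == 0 && between_divergence == 0)) {
    warning("within_divergence >= between_divergence: ",
            "families will not be separable")
  }
  with_local_seed(seed, {
    mutate <- function(res, p) {
      hit <- stats::runif(length(res)) < p
      res[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      res
    }
    ancestor <- sample(AA_ALPHABET, root_length, replace = TRUE)
    rows <- list()
    for (f in seq_len(n_families)) {
      root <- mutate(ancestor, between_divergence)
      for (s in seq_len(seqs_per_family)) {
        child <- mutate(root, within_divergence)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("F%d_S%d", f, s),
          description = sprintf("synthetic family %d member %d", f, s),
          sequence = paste(child, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic catalog of tie-free amino-acid scales
#'
#' Produces `n_indices` complete indices whose 20 values are i.i.d. standard
#' normal draws (resampled in the measure-zero event of a tie), each
#' inducing a distinct random arrangement of the amino acids on the unit
#' circle.  This is a synthetic stand-in for a curated physicochemical
#' catalog, sized by default like the 158-scale working set that yields
#' 632-dimensional feature vectors; it carries no biochemical meaning.
#'
#' @param n_indices Number of indices (default 158).
#' @param seed Integer seed (reproducible, RNG-stream safe).
#' @return An `aaindex_catalog` of complete, tie-free indices with
#'   accessions `SYNT0001..`.
#' @export
synthetic_catalog <- function(n_indices = 158L, seed = 20190620L) {
  stopifnot(n_indices >= 1L)
  with_local_seed(seed, {
    indices <- lapply(seq_len(n_indices), function(i) {
      repeat {
        values <- stats::rnorm(20)
        if (!anyDuplicated(values)) break
      }
      names(values) <- AA_ALPHABET
      list(accession = sprintf("SYNT%04d", i),
           description = sprintf("synthetic random scale %d", i),
           values = values,
           complete = TRUE)
    })
    new_aaindex_catalog(indices)
  })
}
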