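# Fold enrichment of genuine tissue-specific switch-like genes among
# disease gene lists, with a resampling null.

#' Fold enrichment of a gene set among a disease list
#'
#' `fold = (|C ∩ Z| / |C|) / (|G ∩ Z| / |G|)`: how much more often the
#' genes of interest C overlap the disease list Z than the testing
#' universe G does.
#'
#' @param C [gene_set()] of interest (must be a subset of G, non-empty).
#' @param Z disease [gene_set()].
#' @param G universe [gene_set()].
#' @return fold enrichment (>= 0).
#' @export
fold_enrichment <- function(C, Z, G) {
  stopifnot(inherits(C, "GeneSet"), inherits(Z, "GeneSet"),
            inherits(G, "GeneSet"))
  if (!all(C$members %in% G$members))
    stopf("C must be a subset of the universe G")
  gz <- length(intersect(G$members, Z$members))
  if (gz == 0L) stopf("no overlap between the universe and '%s'", Z$name)
  cz <- length(intersect(C$members, Z$members))
  (cz / length(C$members)) / (gz / length(G$members))
}

#' Permutation p-value for an enrichment
#'
#' Draws `n_perm` random gene samples of size |C| from the universe G
#' (uniformly, with replacement by default, matching the resampling null
#' as stated; `replace = FALSE` gives the hypergeometric-exact variant) and
#' reports the fraction of samples whose overlap with Z strictly exceeds
#' the observed |C ∩ Z|.  Overlaps are counted over distinct genes.  A zero
#' exceedance count is reported as `p_value = 0` together with the bound
#' `p_bound = 1/n_perm` (headline convention "p < 1/n_perm").
#'
#' @inheritParams fold_enrichment
#' @param n_perm number of random samples (default 10000).
#' @param seed RNG seed.
#' @param replace sample with replacement (default TRUE).
#' @return list: `p_value` (raw exceedance fraction), `p_bound`
#'   (max(p_value, 1/n_perm)), `observed_overlap`, `n_perm`.
#' @export
permutation_pvalue <- function(C, Z, G, n_perm = 10000L, seed = 1L,
                               replace = TRUE) {
  stopifnot(inherits(C, "GeneSet"), inherits(Z, "GeneSet"),
            inherits(G, "GeneSet"))
  if (!all(C$members %in% G$members))
    stopf("C must be a subset of the universe G")
  nC <- length(C$members)
  obs <- length(intersect(C$members, Z$members))
  in_z <- G$members %in% Z$members
  exceed <- with_seed(seed, {
    n_exc <- 0L
    for (j in seq_len(n_perm)) {
      idx <- sample.int(length(in_z), nC, replace = replace)
      if (replace) idx <- unique(idx)  # q_j ∩ Z is a set intersection
      if (sum(in_z[idx]) > obs) n_exc <- n_exc + 1L
    }
    n_exc
  })
  p <- exceed / n_perm
  list(p_value = p, p_bound = max(p, 1 / n_perm), observed_overlap = obs,
       n_perm = as.integer(n_perm))
}

#' Enrichment of a genuine switch-like gene set among a disease list
#'
#' Convenience wrapper combining [fold_enrichment()] and
#' [permutation_pvalue()] into one result row.
#'
#' @inheritParams permutation_pvalue
#' @param tissue_id label recorded in the result.
#' @return one-row data.frame `tissue_id, disease, n_C, n_Z, n_G, overlap,
#'   fold, p_perm, p_bound, n_perm`.
#' @export
enrichment_test <- function(C, Z, G, tissue_id = NA_character_,
                            n_perm = 10000L, seed = 1L, replace = TRUE) {
  fold <- fold_enrichment(C, Z, G)
  pp <- permutation_pvalue(C, Z, G, n_perm = n_perm, seed = seed,
                           replace = replace)
  data.frame(tissue_id = tissue_id, disease = Z$name,
             n_C = length(C$members), n_Z = length(Z$members),
             n_G = length(G$members), overlap = pp$observed_overlap,
             fold = fold, p_perm = pp$p_value, p_bound = pp$p_bound,
             n_perm = pp$n_perm, stringsAsFactors = FALSE)
}
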