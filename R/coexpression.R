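# Tissue-to-tissue co-expression profiles, PCA embedding, hierarchical
# clustering into tissue-specific (cluster 1) versus universally bimodal
# (clusters 2A/2B) genes, and intra-tissue gene-gene co-expression.

#' Shared-subject counts for all tissue pairs
#'
#' Counts the subjects sampled in both tissues of every unordered pair and
#' flags pairs with at least `min_shared` shared subjects as retained (the
#' co-expression profile is computed over retained pairs only).  Pair order
#' is canonical: lexicographic by tissue id.
#'
#' @param metadata sample metadata.
#' @param tissues tissue ids to consider (>= 2).
#' @param min_shared retention cutoff; pairs sharing fewer subjects are
#'   dropped (default 40, i.e. "fewer than 40" excluded).
#' @return data.frame `tissue_i, tissue_j, n_shared, retained`.
#' @export
shared_sample_counts <- function(metadata, tissues, min_shared = 40L) {
  tissues <- sort(unique(tissues))
  if (length(tissues) < 2L) stopf("need at least 2 tissues")
  subj <- lapply(tissues, function(ti)
    unique(metadata$subject_id[metadata$tissue_id == ti]))
  names(subj) <- tissues
  pairs <- utils::combn(tissues, 2L)
  n_shared <- apply(pairs, 2L, function(p)
    length(intersect(subj[[p[1L]]], subj[[p[2L]]])))
  data.frame(tissue_i = pairs[1L, ], tissue_j = pairs[2L, ],
             n_shared = as.integer(n_shared),
             retained = n_shared >= min_shared,
             stringsAsFactors = FALSE)
}

#' Co-expression of one gene between two tissues
#'
#' Pearson correlation of `log1p(TPM)` across the subjects shared by the
#' two panels.  Undefined (NA) when fewer than 2 shared subjects or when
#' either side has zero variance (which includes the all-zero case).
#'
#' @param gene gene id.
#' @param panel_i,panel_j [expression_panel()] objects.
#' @param shared_subjects optional explicit subject ids; defaults to the
#'   intersection of the two panels' subjects.
#' @return correlation in \[-1, 1\], or NA when undefined.
#' @export
tissue_pair_correlation <- function(gene, panel_i, panel_j,
                                    shared_subjects = NULL) {
  s <- shared_subjects %||% intersect(subject_ids(panel_i),
                                      subject_ids(panel_j))
  if (length(s) < 2L) return(NA_real_)
  a <- log1p(panel_i$values[gene, s])
  b <- log1p(panel_j$values[gene, s])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Tissue-to-tissue co-expression profiles
#'
#' For every gene, the vector of tissue-pair correlations over the retained
#' pairs, in canonical (lexicographic) pair order.  Genes with any
#' undefined correlation on a retained pair are dropped and reported.
#'
#' @param panels named list of [expression_panel()] objects.
#' @param genes character vector of gene ids to profile.
#' @param pair_table output of [shared_sample_counts()].
#' @return list: `profiles` (matrix, genes x retained pairs), `dropped`
#'   (character vector of removed genes).
#' @export
coexpression_profiles <- function(panels, genes, pair_table) {
  pt <- pair_table[pair_table$retained, , drop = FALSE]
  if (nrow(pt) == 0L) stopf("no retained tissue pairs")
  prof <- matrix(NA_real_, length(genes), nrow(pt),
                 dimnames = list(genes,
                                 paste(pt$tissue_i, pt$tissue_j, sep = "|")))
  for (k in seq_len(nrow(pt))) {
    pi <- panels[[pt$tissue_i[k]]]
    pj <- panels[[pt$tissue_j[k]]]
    s <- intersect(subject_ids(pi), subject_ids(pj))
    a <- log1p(pi$values[genes, s, drop = FALSE])
    b <- log1p(pj$values[genes, s, drop = FALSE])
    ac <- a - rowMeans(a); bc <- b - rowMeans(b)
    num <- rowSums(ac * bc)
    den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    prof[, k] <- r
  }
  bad <- rownames(prof)[rowSums(is.na(prof)) > 0L]
  list(profiles = prof[setdiff(genes, bad), , drop = FALSE], dropped = bad)
}

#' PCA embedding of co-expression profiles
#'
#' Centered (not variance-scaled) principal components of the profile
#' matrix.  Component signs are fixed so that the score of largest
#' magnitude on each component is positive, making embeddings reproducible
#' across platforms.
#'
#' @param profiles genes x pairs matrix.
#' @param n_comp number of components to return (default 2).
#' @return list: `scores` (genes x `n_comp`), `variance_fraction`.
#' @export
pca_embed <- function(profiles, n_comp = 2L) {
  if (nrow(profiles) < 2L) stopf("need at least 2 profiles for PCA")
  n_comp <- min(n_comp, ncol(profiles), nrow(profiles) - 1L)
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(n_comp), drop = FALSE]
  for (j in seq_len(ncol(sc))) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sc, variance_fraction = vf[seq_len(n_comp)])
}

#' Complete-linkage clustering in PC space
#'
#' @param coords points x dims matrix (typically the first two PCs).
#' @param k number of clusters.
#' @return integer cluster labels named by rownames of `coords`.
#' @export
hcluster_cut <- function(coords, k) {
  if (k < 1L || k > nrow(coords)) stopf("k must be in [1, n points]")
  hc <- hclust(dist(coords, method = "euclidean"), method = "complete")
  cutree(hc, k = k)
}

#' Semantic cluster labels for switch-like genes
#'
#' Clusters the switch-like genes' 2-D embedding by complete linkage and
#' cuts the same tree at k = 2 (coarse: cluster 1 versus cluster 2) and
#' k = 3 (fine: 1 / 2A / 2B), so the fine labels refine the coarse ones.
#' Semantics are assigned operationally:
#' cluster 2 is the coarse group whose genes are bimodal in the larger
#' fraction of tissues; within it, subcluster 2B is the one with the higher
#' mean sex separability (mean |Cohen's d| of log1p expression between the
#' sexes across tissues common to both), 2A the other.  If the k = 3 cut
#' splits cluster 1 instead of cluster 2 the configuration is degenerate: a
#' warning is emitted and cluster 2 is labelled 2A as a whole.
#'
#' @param scores_2d genes x 2 PCA score matrix of switch-like genes.
#' @param dip_results `results` data.frame from [call_bimodal()].
#' @param panels named list of panels (for the sex-separability rule).
#' @param metadata sample metadata (for subject sex and tissue sex
#'   specificity).
#' @return data.frame `gene_id, coarse, fine, PC1, PC2`.
#' @export
label_clusters <- function(scores_2d, dip_results, panels, metadata) {
  genes <- rownames(scores_2d)
  if (length(genes) < 3L) stopf("need >= 3 genes to label clusters")
  hc <- hclust(dist(scores_2d, method = "euclidean"), method = "complete")
  k2 <- cutree(hc, 2L); k3 <- cutree(hc, 3L)

  frac_bimodal <- vapply(genes, function(g) {
    r <- dip_results[dip_results$gene_id == g, ]
    if (nrow(r) == 0L) return(0)
    mean(r$bimodal)
  }, numeric(1))

  mean_frac <- tapply(frac_bimodal, k2, mean)
  c2 <- as.integer(names(which.max(mean_frac)))
  coarse <- ifelse(k2 == c2, "cluster2", "cluster1")
  if (length(unique(k2)) == 1L)
    warnf("degenerate coarse clustering: all genes in one cluster")

  # which k=3 groups sit inside coarse cluster 2?
  sub2 <- unique(k3[k2 == c2])
  fine <- rep("cluster1", length(genes))
  names(fine) <- genes
  if (length(sub2) == 2L) {
    sep <- sex_separability(genes, panels, metadata)
    m <- tapply(sep[genes], k3, mean)[as.character(sub2)]
    b <- sub2[which.max(m)]
    fine[k3 == b & k2 == c2] <- "cluster2B"
    fine[k3 != b & k2 == c2] <- "cluster2A"
  } else {
    warnf("k = 3 cut does not split cluster 2; labelling it 2A as a whole")
    fine[k2 == c2] <- "cluster2A"
  }
  data.frame(gene_id = genes, coarse = coarse, fine = unname(fine),
             PC1 = scores_2d[, 1L], PC2 = scores_2d[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

# mean |Cohen's d| of log1p expression between sexes, over tissues common
# to both sexes; the sex-separability score used to tell 2B from 2A.
sex_separability <- function(genes, panels, metadata) {
  sex_of <- tapply(metadata$sex, metadata$subject_id, function(s) s[1L])
  shared_tissues <- names(Filter(function(ti) {
    s <- unique(metadata$subject_id[metadata$tissue_id == ti])
    length(unique(sex_of[s])) == 2L
  }, setNames(as.list(names(panels)), names(panels))))
  acc <- matrix(0, length(genes), 0)
  out <- setNames(numeric(length(genes)), genes)
  cnt <- 0L
  for (ti in shared_tissues) {
    p <- panels[[ti]]
    sx <- sex_of[subject_ids(p)]
    have <- intersect(genes, gene_ids(p))
    lv <- log1p(p$values[have, , drop = FALSE])
    d <- vapply(have, function(g)
      abs(cohens_d(lv[g, sx == "female"], lv[g, sx == "male"])), numeric(1))
    d[!is.finite(d)] <- 0
    out[have] <- out[have] + d
    cnt <- cnt + 1L
  }
  if (cnt > 0L) out <- out / cnt
  out
}

#' Gene-gene co-expression within one tissue
#'
#' Pearson correlation matrix of `log1p(TPM)` across the tissue's subjects
#' for the given gene set.  Zero-variance genes yield NA rows/columns and a
#' warning; the diagonal is 1 by construction.
#'
#' @param panel [expression_panel()].
#' @param geneset [gene_set()] or character vector (>= 2 genes).
#' @return symmetric correlation matrix.
#' @export
intra_tissue_gene_correlation <- function(panel, geneset) {
  genes <- if (inherits(geneset, "GeneSet")) geneset$members else geneset
  genes <- intersect(genes, gene_ids(panel))
  if (length(genes) < 2L) stopf("need >= 2 genes present in the panel")
  if (ncol(panel$values) < 3L) stopf("need >= 3 subjects")
  lv <- t(log1p(panel$values[genes, , drop = FALSE]))
  zero_var <- apply(lv, 2L, stats::sd) == 0
  if (any(zero_var))
    warnf("zero-variance gene(s): %s",
          paste(genes[zero_var], collapse = ", "))
  r <- suppressWarnings(cor(lv))
  diag(r) <- 1
  r
}
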