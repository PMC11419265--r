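# Confounder screening with cluster-2 internal controls, and sex-bias
# testing of switch-like genes.

#' Correlation of a gene's expression with a technical covariate
#'
#' Pearson correlation between `log1p(TPM)` and the covariate across the
#' panel's subjects.  When either side has zero variance the correlation is
#' undefined and coerced to 0 with a warning (an undefined correlation can
#' never justify eliminating a gene).
#'
#' @param panel [expression_panel()].
#' @param gene gene id.
#' @param covariate_values numeric vector named by subject id (e.g. the
#'   tissue's ischemic times).
#' @return correlation coefficient.
#' @export
confounder_correlation <- function(panel, gene, covariate_values) {
  s <- intersect(subject_ids(panel), names(covariate_values))
  if (length(s) < 3L) stopf("need >= 3 subjects with covariate values")
  a <- log1p(panel$values[gene, s])
  b <- covariate_values[s]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("zero variance for gene '%s': correlation undefined, using 0", gene)
    return(0)
  }
  cor(a, b)
}

#' Confounder screen for switch-like genes
#'
#' For every gene-tissue pair in which a gene is bimodal, computes the
#' correlation of `log1p` expression with each technical covariate
#' (`ischemic_time`, `fixative_time`), for both cluster-1 genes (the
#' candidates) and cluster-2 genes (the internal controls, whose
#' genetically driven bimodality is robust to such confounders).
#'
#' @param panels named list of panels.
#' @param assignments cluster assignment data.frame from [label_clusters()].
#' @param metadata sample metadata.
#' @param dip_results `results` data.frame from [call_bimodal()]; cluster-1
#'   genes are screened in the tissues where they are bimodal, cluster-2
#'   controls contribute in every tissue.
#' @param covariates covariate column names in `metadata`.
#' @return data.frame `gene_id, tissue_id, covariate, r, r2, cluster`.
#' @export
confounder_screen <- function(panels, assignments, metadata, dip_results,
                              covariates = c("ischemic_time",
                                             "fixative_time")) {
  rows <- list()
  for (ti in names(panels)) {
    p <- panels[[ti]]
    md <- metadata[metadata$tissue_id == ti, ]
    for (cv in covariates) {
      cov_vals <- setNames(md[[cv]], md$subject_id)
      for (ci in c("cluster1", "cluster2")) {
        gsel <- assignments$gene_id[assignments$coarse == ci]
        if (ci == "cluster1") {
          bim <- dip_results$gene_id[dip_results$tissue_id == ti &
                                     dip_results$bimodal]
          gsel <- intersect(gsel, bim)
        }
        gsel <- intersect(gsel, gene_ids(p))
        if (length(gsel) == 0L) next
        r <- vapply(gsel, function(g)
          suppressWarnings(confounder_correlation(p, g, cov_vals)),
          numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gsel, tissue_id = ti, covariate = cv,
          r = unname(r), r2 = unname(r)^2, cluster = ci,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stopf("nothing to screen")
  do.call(rbind, rows)
}

#' Internal-control confounder filter
#'
#' A cluster-1 gene is eliminated in tissue i if, for any covariate c, its
#' squared correlation with c exceeds the maximum squared correlation among
#' the cluster-2 internal controls for that covariate.  Controls are
#' matched per tissue by default; `scope = "global"` uses the maximum over
#' all tissues instead.
#'
#' @param cluster1_results,cluster2_results rows of [confounder_screen()]
#'   output for candidate and control genes.
#' @param scope `"per_tissue"` (default) or `"global"` cluster-2 maxima.
#' @return list: `eliminated` (data.frame `gene_id, tissue_id` of dropped
#'   gene-tissue pairs), `genuine` (named list, per tissue, of surviving
#'   cluster-1 gene ids -- the sets C_i).
#' @export
internal_control_filter <- function(cluster1_results, cluster2_results,
                                    scope = c("per_tissue", "global")) {
  scope <- match.arg(scope)
  c1 <- cluster1_results
  if (nrow(cluster2_results) == 0L) {
    warnf("no cluster-2 internal controls: filter passes all genes")
    genuine <- lapply(split(c1$gene_id, c1$tissue_id), unique)
    return(list(eliminated = c1[0, c("gene_id", "tissue_id")],
                genuine = genuine))
  }
  max_r2 <- function(ti, cv) {
    sel <- cluster2_results$covariate == cv
    if (scope == "per_tissue") sel <- sel & cluster2_results$tissue_id == ti
    if (!any(sel)) return(Inf)  # no control measured: cannot eliminate
    max(cluster2_results$r2[sel])
  }
  kill <- mapply(function(g, ti, cv, r2) r2 > max_r2(ti, cv),
                 c1$gene_id, c1$tissue_id, c1$covariate, c1$r2)
  elim <- unique(c1[kill, c("gene_id", "tissue_id")])
  keyed <- paste(c1$gene_id, c1$tissue_id)
  dropped <- paste(elim$gene_id, elim$tissue_id)
  keep <- c1[!(keyed %in% dropped), ]
  genuine <- lapply(split(keep$gene_id, keep$tissue_id), unique)
  list(eliminated = elim, genuine = genuine)
}

#' Wilcoxon rank-sum test between sexes
#'
#' Two-sided rank-sum p-value (R's `wilcox.test`: exact for small tie-free
#' samples, midrank normal approximation with continuity correction
#' otherwise).
#'
#' @param x_female,x_male numeric vectors (>= 2 values each to be testable).
#' @return p-value, or NA with attribute `untestable` when a group is too
#'   small.
#' @export
wilcoxon_rank_sum <- function(x_female, x_male) {
  if (length(x_female) < 2L || length(x_male) < 2L)
    return(structure(NA_real_, untestable = TRUE))
  suppressWarnings(wilcox.test(x_female, x_male)$p.value)
}

#' Cohen's d effect size (female minus male)
#'
#' `(mean(x_female) - mean(x_male)) / s_pooled`, pooled SD with the
#' `n1 + n2 - 2` denominator.  Positive d means female-biased.  A zero
#' pooled SD yields 0 for equal means and a signed infinity otherwise.
#'
#' @inheritParams wilcoxon_rank_sum
#' @return effect size d.
#' @export
cohens_d <- function(x_female, x_male) {
  n1 <- length(x_female); n2 <- length(x_male)
  if (n1 < 2L || n2 < 2L) stopf("both groups need >= 2 values")
  num <- mean(x_female) - mean(x_male)
  sp <- sqrt(((n1 - 1) * stats::var(x_female) +
              (n2 - 1) * stats::var(x_male)) / (n1 + n2 - 2))
  if (sp == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sp
}

#' Sex-bias screen for switch-like genes
#'
#' For every switch-like gene in every tissue common to both sexes, tests
#' whether the `log1p` expression distribution differs between the sexes
#' (Wilcoxon rank-sum), adjusts jointly across all tested gene-tissue
#' pairs by Benjamini-Hochberg (per-tissue scoping available), and calls a
#' pair sex-biased iff `q <= fdr` and `|Cohen's d| > d_min`.
#'
#' @param panels named list of panels.
#' @param switch_genes [gene_set()] or character vector of genes to test.
#' @param metadata sample metadata.
#' @param fdr BH false discovery rate (default 0.05).
#' @param d_min minimum absolute Cohen's d (default 0.2).
#' @param scope `"joint"` BH across all pairs (default) or `"per_tissue"`.
#' @return data.frame `gene_id, tissue_id, p_value, q_value, cohens_d,
#'   biased, direction`.
#' @export
sex_bias_screen <- function(panels, switch_genes, metadata, fdr = 0.05,
                            d_min = 0.2, scope = c("joint", "per_tissue")) {
  scope <- match.arg(scope)
  genes <- if (inherits(switch_genes, "GeneSet")) switch_genes$members
           else switch_genes
  sex_of <- tapply(metadata$sex, metadata$subject_id, function(s) s[1L])
  rows <- list()
  for (ti in names(panels)) {
    p <- panels[[ti]]
    sx <- sex_of[subject_ids(p)]
    if (length(unique(sx)) < 2L) next  # sex-specific tissue: skipped
    have <- intersect(genes, gene_ids(p))
    if (length(have) == 0L) next
    lv <- log1p(p$values[have, , drop = FALSE])
    f <- sx == "female"
    stats_ <- vapply(have, function(g) {
      c(wilcoxon_rank_sum(lv[g, f], lv[g, !f]),
        cohens_d(lv[g, f], lv[g, !f]))
    }, numeric(2))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = have, tissue_id = ti,
      p_value = stats_[1L, ], cohens_d = stats_[2L, ],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0L) stopf("no testable tissue (both sexes required)")
  res <- do.call(rbind, rows)
  if (scope == "joint") {
    res$q_value <- bh_adjust(res$p_value, fdr)$q_values
  } else {
    res$q_value <- NA_real_
    for (ti in unique(res$tissue_id)) {
      i <- res$tissue_id == ti
      res$q_value[i] <- bh_adjust(res$p_value[i], fdr)$q_values
    }
  }
  res$biased <- res$q_value <= fdr & abs(res$cohens_d) > d_min
  res$direction <- ifelse(res$cohens_d > 0, "female", "male")
  res[c("gene_id", "tissue_id", "p_value", "q_value", "cohens_d",
        "biased", "direction")]
}
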