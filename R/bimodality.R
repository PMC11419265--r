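# Tissue/gene filtering, log transform, genome-wide dip scan with BH
# correction and the effect-size gate, yielding switch-like gene calls.

#' Select focal tissues: size filter plus one tissue per organ
#'
#' Tissues with fewer than `min_subjects` distinct subjects are excluded;
#' among the survivors, exactly one tissue per organ is kept, chosen
#' uniformly at random under `seed` (reported tissues are sorted).
#'
#' @param metadata sample metadata ([read_sample_metadata()] layout).
#' @param min_subjects minimum number of subjects per tissue (default 50).
#' @param seed seed for the random one-per-organ choice.
#' @return character vector of retained tissue ids.
#' @export
filter_tissues <- function(metadata, min_subjects = 50L, seed = 1L) {
  counts <- tapply(metadata$subject_id, metadata$tissue_id,
                   function(s) length(unique(s)))
  eligible <- names(counts)[counts >= min_subjects]
  if (length(eligible) == 0L)
    stopf("no tissue has >= %d subjects", min_subjects)
  organ_of <- vapply(eligible, function(ti) {
    unique(metadata$organ[metadata$tissue_id == ti])[1L]
  }, character(1))
  picked <- with_seed(seed, {
    vapply(split(eligible, organ_of), function(tis) {
      if (length(tis) == 1L) tis else sample(tis, 1L)
    }, character(1))
  })
  sort(unname(picked))
}

#' Expression universe: genes highly expressed somewhere
#'
#' A gene enters the testing universe G iff its mean TPM across subjects is
#' strictly greater than `tpm_threshold` in at least one panel.
#'
#' @param panels list of [expression_panel()] objects (the focal tissues).
#' @param tpm_threshold strict mean-TPM cutoff (default 10).
#' @return [gene_set()] named "universe".
#' @export
filter_genes_by_expression <- function(panels, tpm_threshold = 10) {
  stopifnot(length(panels) >= 1L)
  keep <- NULL
  for (p in panels) {
    m <- rowMeans(p$values)
    pass <- rownames(p$values)[m > tpm_threshold]
    keep <- union(keep, pass)
  }
  if (length(keep) == 0L) stopf("no gene exceeds mean TPM %g", tpm_threshold)
  gene_set("universe", keep)
}

#' Natural log1p transform of TPM
#'
#' `log(x + 1)` maps a TPM of 0 to 0 and damps the very large values bulk
#' RNA-seq produces for a few samples.
#'
#' @param values non-negative numeric vector or matrix.
#' @return transformed object of the same shape.
#' @export
log1p_transform <- function(values) {
  if (anyNA(values) || any(values < 0)) stopf("TPM values must be >= 0")
  log1p(values)
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param fdr target false discovery rate (default 0.05).
#' @return list with `q_values` (BH-adjusted) and `reject` (logical).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  assert_scalar_number(fdr, "fdr", 0, 1)
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= fdr)
}

#' Effect-size gate for dip calls
#'
#' A statistically significant dip is only accepted when
#' `D > max(0.05, 0.05 / log(mean_tpm))` -- gene-tissue pairs with low mean
#' expression must clear a higher bar, since weak expression inflates
#' false-positive bimodality.  The logarithm is natural by default (the
#' convention of the R analyses this reproduces); `log_base = 10` is
#' available.  For `mean_tpm <= 1` the threshold is undefined or negative
#' and the gate returns `FALSE` with a warning.
#'
#' @param dip_stat dip statistic(s).
#' @param mean_tpm mean raw-scale TPM of the gene in the tissue.
#' @param log_base base of the logarithm in the gate formula.
#' @return logical vector: does each pair pass the gate?
#' @export
effect_size_gate <- function(dip_stat, mean_tpm, log_base = exp(1)) {
  stopifnot(length(dip_stat) == length(mean_tpm))
  thr <- pmax(0.05, 0.05 / log(mean_tpm, base = log_base))
  low <- mean_tpm <= 1
  if (any(low)) {
    warnf("%d gene-tissue pair(s) with mean TPM <= 1: gate threshold %s",
          sum(low), "undefined, gated FALSE")
    thr[low] <- Inf
  }
  dip_stat > thr
}

#' Genome-wide dip scan over gene-tissue pairs
#'
#' Runs the dip test on `log1p(TPM)` for every (gene in `universe`) x
#' (tissue panel) pair, adjusts p-values jointly by Benjamini-Hochberg, and
#' applies the effect-size gate.  A pair is called bimodal iff it is both a
#' BH rejection at `fdr` and passes the gate; a gene is switch-like iff it
#' is bimodal in at least one tissue.
#'
#' One bootstrap null table per distinct panel width is computed and shared
#' across genes, which makes the scan linear in the number of pairs.
#'
#' @param panels named list of [expression_panel()] objects.
#' @param universe [gene_set()] of genes to test (see
#'   [filter_genes_by_expression()]).
#' @param fdr false discovery rate for BH (default 0.05).
#' @param n_boot bootstrap samples per null table (default 5000).
#' @param seed seed for the bootstrap null.
#' @param gate apply the effect-size gate (default TRUE).
#' @param log_base logarithm base for the gate.
#' @return list of class `dip_scan`: `results` (data.frame with one row per
#'   gene-tissue pair: `gene_id, tissue_id, n_samples, mean_tpm, dip_stat,
#'   p_value, q_value, bimodal`) and `switch_genes` ([gene_set()] or NULL
#'   when nothing is called).
#' @export
call_bimodal <- function(panels, universe, fdr = 0.05, n_boot = 5000L,
                         seed = 1L, gate = TRUE, log_base = exp(1)) {
  stopifnot(length(panels) >= 1L, inherits(universe, "GeneSet"))
  tissues <- vapply(panels, function(p) p$tissue_id, character(1))
  per_tissue <- vector("list", length(panels))
  null_tables <- list()
  for (k in seq_along(panels)) {
    p <- panels[[k]]
    genes <- intersect(universe$members, gene_ids(p))
    v <- p$values[genes, , drop = FALSE]
    n <- ncol(v)
    if (n < 4L) stopf("panel '%s' has fewer than 4 subjects", p$tissue_id)
    key <- as.character(n)
    if (is.null(null_tables[[key]]))
      null_tables[[key]] <- dip_null_table(n, n_boot,
                                           seed = hash_seed(seed, key))
    lv <- log1p(v)
    dips <- vapply(seq_len(nrow(lv)), function(i) dip_statistic(lv[i, ]),
                   numeric(1))
    per_tissue[[k]] <- data.frame(
      gene_id = genes,
      tissue_id = p$tissue_id,
      n_samples = n,
      mean_tpm = rowMeans(v),
      dip_stat = dips,
      p_value = dip_pvalue(dips, null_tables[[key]]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, per_tissue)
  adj <- bh_adjust(res$p_value, fdr)
  res$q_value <- adj$q_values
  passes <- if (gate) {
    suppressWarnings(effect_size_gate(res$dip_stat, res$mean_tpm, log_base))
  } else TRUE
  res$bimodal <- adj$reject & passes
  sw <- unique(res$gene_id[res$bimodal])
  structure(list(
    results = res,
    switch_genes = if (length(sw)) gene_set("switch_like", sw) else NULL
  ), class = "dip_scan")
}

#' @export
print.dip_scan <- function(x, ...) {
  cat(sprintf("dip_scan: %d gene-tissue pairs, %d bimodal, %d switch-like genes\n",
              nrow(x$results), sum(x$results$bimodal),
              length(x$switch_genes$members %||% character(0))))
  invisible(x)
}
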