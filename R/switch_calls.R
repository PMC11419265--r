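# On/off discretization at kernel-density minima, and the concordance
# statistic over gene sets.

#' Kernel density estimate of a log1p expression sample
#'
#' Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth on a
#' 512-point grid spanning the data range extended by three bandwidths --
#' the defaults of R's `density()`, which this wraps.
#'
#' @param sample numeric vector on the log1p scale (n >= 5, non-constant).
#' @param n_grid grid size (default 512).
#' @param bw_mult bandwidth multiplier (default 1).
#' @return list `grid`, `density`.
#' @export
kde_density <- function(sample, n_grid = 512L, bw_mult = 1) {
  if (length(sample) < 5L) stopf("need n >= 5 for density estimation")
  if (stats::sd(sample) == 0) stopf("zero-variance sample")
  d <- density(sample, bw = stats::bw.nrd0(sample) * bw_mult, n = n_grid,
               cut = 3)
  list(grid = d$x, density = d$y)
}

#' Switching threshold at the density minimum
#'
#' The threshold is the abscissa of the interior local minimum with the
#' smallest density value (the "global minimum excluding endpoints");
#' monotone tails are not minima.  Ties break toward the smaller abscissa.
#' A strictly unimodal density has no interior minimum: `NA` is returned
#' and the gene should be treated as always-on.
#'
#' @param grid,density output of [kde_density()].
#' @return threshold abscissa, or NA when the density is unimodal.
#' @export
switching_threshold <- function(grid, density) {
  stopifnot(length(grid) == length(density), length(grid) >= 3L)
  dd <- diff(density)
  s <- sign(dd)
  s_nz <- s[s != 0]
  if (length(s_nz) == 0L) return(NA_real_)
  # positions where a falling run turns into a rising run = local minima
  idx_nz <- which(s != 0)
  minima <- integer(0)
  for (k in seq_len(length(idx_nz) - 1L)) {
    if (s[idx_nz[k]] < 0 && s[idx_nz[k + 1L]] > 0) {
      # minimum sits at the start of the rising run
      minima <- c(minima, idx_nz[k + 1L])
    }
  }
  minima <- minima[minima > 1L & minima < length(grid)]
  if (length(minima) == 0L) return(NA_real_)
  best <- minima[order(density[minima], grid[minima])][1L]
  grid[best]
}

#' On/off calls for one gene
#'
#' A subject is "on" iff its `log1p(TPM)` is strictly above the threshold.
#'
#' @param panel [expression_panel()].
#' @param gene gene id.
#' @param threshold switching threshold on the log1p scale.
#' @return named logical vector over the panel's subjects.
#' @export
call_on_off <- function(panel, gene, threshold) {
  if (is.na(threshold)) stopf("threshold undefined for gene '%s'", gene)
  log1p(panel$values[gene, ]) > threshold
}

#' Switch-call matrix for a gene set in one tissue
#'
#' Estimates a per-gene KDE threshold from the panel and calls each gene
#' on/off in every subject.  Genes with unimodal densities receive no
#' threshold and all-on calls, flagged in `no_threshold`.
#'
#' @param panel [expression_panel()].
#' @param genes [gene_set()] or character vector.
#' @param bw_mult bandwidth multiplier passed to [kde_density()].
#' @return list of class `SwitchCallMatrix`: `tissue_id`, `calls` (genes x
#'   subjects logical), `thresholds` (named numeric, NA = none),
#'   `no_threshold` (character).
#' @export
switch_call_matrix <- function(panel, genes, bw_mult = 1) {
  gsel <- if (inherits(genes, "GeneSet")) genes$members else genes
  gsel <- intersect(gsel, gene_ids(panel))
  if (length(gsel) == 0L) stopf("no requested gene present in the panel")
  thr <- vapply(gsel, function(g) {
    x <- log1p(panel$values[g, ])
    if (stats::sd(x) == 0) return(NA_real_)
    kd <- kde_density(x, bw_mult = bw_mult)
    switching_threshold(kd$grid, kd$density)
  }, numeric(1))
  calls <- matrix(TRUE, length(gsel), ncol(panel$values),
                  dimnames = list(gsel, subject_ids(panel)))
  for (g in gsel[!is.na(thr)]) calls[g, ] <- call_on_off(panel, g, thr[g])
  structure(list(tissue_id = panel$tissue_id, calls = calls,
                 thresholds = thr, no_threshold = gsel[is.na(thr)]),
            class = "SwitchCallMatrix")
}

#' @export
print.SwitchCallMatrix <- function(x, ...) {
  cat(sprintf("SwitchCallMatrix '%s': %d genes x %d subjects (%d without threshold)\n",
              x$tissue_id, nrow(x$calls), ncol(x$calls),
              length(x$no_threshold)))
  invisible(x)
}

#' Concordance of on/off states across a gene set
#'
#' The fraction of subjects in whom the genes of the set are either all on
#' or all off:
#' `(1/S) * sum_s [ prod_g 1(on) + prod_g 1(off) ]`.
#'
#' @param calls logical matrix (genes x subjects) or a `SwitchCallMatrix`.
#' @return concordance fraction in \[0, 1\].
#' @examples
#' m <- rbind(g1 = c(TRUE, TRUE, FALSE), g2 = c(TRUE, FALSE, FALSE))
#' concordance(m)  # subjects 1 and 3 concordant: 2/3
#' @export
concordance <- function(calls) {
  if (inherits(calls, "SwitchCallMatrix")) calls <- calls$calls
  if (!is.matrix(calls) || !is.logical(calls))
    stopf("'calls' must be a logical genes x subjects matrix")
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stopf("need at least one gene and one subject")
  on_all <- colSums(calls) == nrow(calls)
  off_all <- colSums(!calls) == nrow(calls)
  mean(on_all | off_all)
}
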