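# Classify universally switch-like genes by candidate genetic basis:
# Y linkage, structural-variant overlap, sign-consistent eQTLs, or
# unexplained.

#' Overlap genes with structural variants
#'
#' A gene is hit by an SV iff their intervals share at least `min_overlap`
#' bases under 0-based half-open semantics (the default 1 bp is the
#' convention of standard interval-overlap tools).  Inputs must carry
#' matching assembly tags (attribute `assembly`); a declared mismatch is an
#' error.  Overlap is computed with `GenomicRanges::findOverlaps`.
#'
#' @param genes gene annotation data.frame ([read_gene_annotation()]).
#' @param svs interval data.frame ([read_bed()]).
#' @param min_overlap minimum overlapping bases (default 1).
#' @return named list: gene id -> character vector of overlapping SV names
#'   (genes without hits map to empty vectors).
#' @export
overlap_genes_svs <- function(genes, svs, min_overlap = 1L) {
  ga <- attr(genes, "assembly"); sa <- attr(svs, "assembly")
  if (!is.null(ga) && !is.null(sa) && !is.na(ga) && !is.na(sa) &&
      !identical(ga, sa))
    stopf("assembly mismatch: genes are %s, SVs are %s", ga, sa)
  # half-open [start, end) -> 1-based closed IRanges [start+1, end]
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_s <- GenomicRanges::GRanges(
    svs$chrom, IRanges::IRanges(svs$start + 1L, svs$end))
  ov <- GenomicRanges::findOverlaps(gr_g, gr_s,
                                    minoverlap = as.integer(min_overlap))
  hits <- setNames(vector("list", nrow(genes)), genes$gene_id)
  for (g in names(hits)) hits[[g]] <- character(0)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh))
      hits[[genes$gene_id[qh[k]]]] <-
        c(hits[[genes$gene_id[qh[k]]]], svs$name[sh[k]])
  }
  hits
}

#' Sign-consistent eQTL support for a gene
#'
#' TRUE iff some variant has an association record for the gene in every
#' required tissue, all with the same effect sign (consistently increased
#' or consistently decreased expression across tissues).
#'
#' @param records eQTL data.frame ([read_eqtl_table()]).
#' @param gene gene id.
#' @param required_tissues tissue ids that must all be covered.
#' @return logical; attribute `"variants"` lists the supporting variant ids.
#' @export
eqtl_consistency <- function(records, gene, required_tissues) {
  rec <- records[records$gene_id == gene, ]
  if (nrow(rec) == 0L) return(structure(FALSE, variants = character(0)))
  ok <- vapply(split(rec, rec$variant_id), function(rv) {
    all(required_tissues %in% rv$tissue_id) &&
      length(unique(rv$effect_sign)) == 1L
  }, logical(1))
  structure(any(ok), variants = names(ok)[ok])
}

#' Classify the genetic basis of universally switch-like genes
#'
#' Every cluster-2 (2A/2B) gene receives exactly one category, assigned in
#' priority order: `y_linked` (annotated in the male-specific region of
#' chromosome Y) > `x_inactivation_marker` (listed in `x_marker_genes`,
#' e.g. a female-specific escape marker) > `structural_variant` (overlaps
#' an SV in any supplied annotation/SV catalogue pair; hits are unioned
#' across pairs) > `snv_eqtl` (a sign-consistent eQTL across all required
#' tissues) > `unexplained`.
#'
#' @param assignments cluster assignment data.frame from [label_clusters()].
#' @param annotations gene annotation data.frame, or list of them (one per
#'   assembly).
#' @param svs interval data.frame, or list matching `annotations`.
#' @param eqtls eQTL data.frame (or NULL).
#' @param required_tissues tissues an eQTL must cover to count.
#' @param x_marker_genes gene ids reserved for the X-inactivation category.
#' @return data.frame `gene_id, fine, category, evidence`.
#' @export
classify_genetic_basis <- function(assignments, annotations, svs,
                                   eqtls = NULL,
                                   required_tissues = character(0),
                                   x_marker_genes = character(0)) {
  anns <- if (is.data.frame(annotations)) list(annotations) else annotations
  svss <- if (is.data.frame(svs)) list(svs) else svs
  stopifnot(length(anns) == length(svss))
  targets <- assignments[assignments$fine %in% c("cluster2A", "cluster2B"), ]
  if (nrow(targets) == 0L)
    return(data.frame(gene_id = character(0), fine = character(0),
                      category = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  sv_hits <- setNames(vector("list", nrow(targets)), targets$gene_id)
  msr <- character(0)
  for (k in seq_along(anns)) {
    an <- anns[[k]]
    msr <- union(msr, an$gene_id[an$chry_msr])
    sub <- an[an$gene_id %in% targets$gene_id, , drop = FALSE]
    if (nrow(sub) == 0L) next
    attr(sub, "assembly") <- attr(an, "assembly")
    h <- overlap_genes_svs(sub, svss[[k]])
    for (g in names(h)) sv_hits[[g]] <- union(sv_hits[[g]], h[[g]])
  }
  out <- lapply(seq_len(nrow(targets)), function(i) {
    g <- targets$gene_id[i]
    if (g %in% msr) {
      cat_ <- "y_linked"; ev <- "chrY_MSR"
    } else if (g %in% x_marker_genes) {
      cat_ <- "x_inactivation_marker"; ev <- "annotation"
    } else if (length(sv_hits[[g]] %||% character(0)) > 0L) {
      cat_ <- "structural_variant"; ev <- paste(sv_hits[[g]], collapse = ",")
    } else {
      eq <- if (is.null(eqtls)) structure(FALSE, variants = character(0))
            else eqtl_consistency(eqtls, g, required_tissues)
      if (isTRUE(as.logical(eq))) {
        cat_ <- "snv_eqtl"; ev <- paste(attr(eq, "variants"), collapse = ",")
      } else {
        cat_ <- "unexplained"; ev <- ""
      }
    }
    data.frame(gene_id = g, fine = targets$fine[i], category = cat_,
               evidence = ev, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
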