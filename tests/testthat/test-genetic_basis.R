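# SV overlap, eQTL sign consistency, and the genetic-basis classifier.

mk_genes <- function(df, assembly = "hg38") {
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    start = df$start, end = df$end, strand = "+",
                    chry_msr = df$chry_msr %||% FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "assembly") <- assembly
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("interval overlap honours half-open boundaries", {
  genes <- mk_genes(data.frame(gene_id = "g", chrom = "chr1",
                               start = 100, end = 200))
  sv1 <- data.frame(chrom = "chr1", start = 199, end = 300, name = "sv1",
                    stringsAsFactors = FALSE)
  attr(sv1, "assembly") <- "hg38"
  expect_identical(overlap_genes_svs(genes, sv1)$g, "sv1")  # 1-base overlap
  sv2 <- sv1; sv2$start <- 200; sv2$name <- "sv2"
  expect_length(overlap_genes_svs(genes, sv2)$g, 0L)        # abutting: none
  svx <- sv1; attr(svx, "assembly") <- "hg19"
  expect_error(overlap_genes_svs(genes, svx), "assembly mismatch")
})

test_that("overlap hits equal the all-pairs brute-force scan", {
  set.seed(18)
  genes <- mk_genes(data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, TRUE),
    start = s <- sample(1:5000, 20), end = s + sample(50:500, 20)))
  svs <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                    start = t <- sample(1:5000, 10),
                    end = t + sample(50:800, 10),
                    name = sprintf("sv%02d", 1:10), stringsAsFactors = FALSE)
  attr(svs, "assembly") <- "hg38"
  got <- overlap_genes_svs(genes, svs)
  want <- overlap_bruteforce(genes, svs)
  for (g in names(want)) expect_setequal(got[[g]], want[[g]])
  # shuffling input order changes nothing
  genes2 <- genes[sample(nrow(genes)), ]
  attr(genes2, "assembly") <- "hg38"
  got2 <- overlap_genes_svs(genes2, svs[sample(nrow(svs)), ])
  for (g in names(want)) expect_setequal(got2[[g]], want[[g]])
})

test_that("eQTL support requires full tissue coverage with one sign", {
  tiss <- sprintf("T%02d", 1:27)
  rec <- data.frame(variant_id = "v1", gene_id = "g", tissue_id = tiss,
                    effect_sign = 1L, stringsAsFactors = FALSE)
  expect_true(eqtl_consistency(rec, "g", tiss))
  flip <- rec; flip$effect_sign[27] <- -1L
  expect_false(eqtl_consistency(flip, "g", tiss))
  # v2 incomplete, v3 complete and consistent: TRUE via v3
  rec2 <- rbind(
    data.frame(variant_id = "v2", gene_id = "g", tissue_id = tiss[-5],
               effect_sign = -1L),
    data.frame(variant_id = "v3", gene_id = "g", tissue_id = tiss,
               effect_sign = -1L))
  r <- eqtl_consistency(rec2, "g", tiss)
  expect_true(r)
  expect_identical(attr(r, "variants"), "v3")
  expect_false(eqtl_consistency(rec, "other_gene", tiss))
})

test_that("classifier assigns one category per gene in priority order", {
  asg <- data.frame(gene_id = c("y1", "both", "eq", "none"),
                    coarse = "cluster2",
                    fine = c("cluster2B", "cluster2A", "cluster2A",
                             "cluster2A"),
                    stringsAsFactors = FALSE)
  ann <- mk_genes(data.frame(
    gene_id = c("y1", "both", "eq", "none"),
    chrom = c("chrY", "chr2", "chr3", "chr4"),
    start = c(100, 100, 100, 100), end = c(500, 500, 500, 500),
    chry_msr = c(TRUE, FALSE, FALSE, FALSE)))
  svs <- data.frame(chrom = "chr2", start = 50, end = 150, name = "del1",
                    variant_type = "deletion", stringsAsFactors = FALSE)
  attr(svs, "assembly") <- "hg38"
  eq <- data.frame(variant_id = "v9", gene_id = c("both", "eq"),
                   tissue_id = "T01", effect_sign = 1L,
                   stringsAsFactors = FALSE)
  eq <- rbind(eq, within(eq, tissue_id <- "T02"))
  gb <- classify_genetic_basis(asg, ann, svs, eq,
                               required_tissues = c("T01", "T02"))
  cat_ <- setNames(gb$category, gb$gene_id)
  expect_identical(cat_[["y1"]], "y_linked")
  expect_identical(cat_[["both"]], "structural_variant")  # SV beats eQTL
  expect_identical(cat_[["eq"]], "snv_eqtl")
  expect_identical(cat_[["none"]], "unexplained")
  # exactly one category per cluster-2 gene: a partition
  expect_identical(sort(gb$gene_id), sort(asg$gene_id))
  expect_true(all(gb$evidence[gb$category != "unexplained"] != ""))
})

test_that("planted genetic bases are recovered from the synthetic truth", {
  run <- default_run()
  gb <- classify_genetic_basis(run$assignments, run$sim$truth$annotation,
                               run$sim$truth$svs)
  tr <- run$sim$truth$genes
  cls <- setNames(tr$class, tr$gene_id)
  expect_true(all(gb$category[cls[gb$gene_id] == "universal_sv"] ==
                  "structural_variant"))
  expect_true(all(gb$category[cls[gb$gene_id] == "y_linked"] == "y_linked"))
})
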