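# Confounder screening with internal controls; sex-bias quantification.

test_that("confounder correlation matches hand arithmetic", {
  cov_vals <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  v <- matrix(expm1(cov_vals), 1, dimnames = list("g", names(cov_vals)))
  p <- expression_panel("t", v)
  expect_equal(confounder_correlation(p, "g", cov_vals), 1)  # exact linear
  # hand-computed 5-point fixture
  v2 <- matrix(c(0, 3, 1, 8, 2), 1, dimnames = list("g", names(cov_vals)))
  p2 <- expression_panel("t", v2)
  x <- log1p(v2[1, ]); y <- cov_vals
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(confounder_correlation(p2, "g", cov_vals), hand)
  # constant covariate: undefined, coerced to 0 with a warning
  expect_warning(r <- confounder_correlation(p2, "g", cov_vals * 0 + 2),
                 "undefined")
  expect_identical(r, 0)
})

test_that("internal-control filter applies the squared-correlation rule", {
  c1 <- data.frame(
    gene_id = c("h1", "h1", "h2", "h3"),
    tissue_id = "T01",
    covariate = c("ischemic_time", "fixative_time",
                  "ischemic_time", "ischemic_time"),
    r = c(0.9, 0.1, 0.05, 0), r2 = c(0.81, 0.01, 0.0025, 0),
    cluster = "cluster1", stringsAsFactors = FALSE)
  c2 <- data.frame(
    gene_id = c("u1", "u2"), tissue_id = "T01",
    covariate = "ischemic_time", r = c(0.2, -0.3), r2 = c(0.04, 0.09),
    cluster = "cluster2", stringsAsFactors = FALSE)
  flt <- internal_control_filter(c1, c2)
  expect_identical(flt$eliminated$gene_id, "h1")      # 0.81 > 0.09
  expect_setequal(flt$genuine$T01, c("h2", "h3"))     # r = 0 always kept
  # a saturated control (r2 = 1) blocks all eliminations for that covariate
  c2b <- rbind(c2, data.frame(gene_id = "u3", tissue_id = "T01",
                              covariate = "ischemic_time", r = 1, r2 = 1,
                              cluster = "cluster2"))
  expect_identical(nrow(internal_control_filter(c1, c2b)$eliminated), 0L)
  # monotone: enlarging cluster 2 never eliminates more
  base_n <- nrow(internal_control_filter(c1, c2)$eliminated)
  expect_lte(nrow(internal_control_filter(c1, c2b)$eliminated), base_n)
  # no controls at all: passes everything, with a warning
  expect_warning(flt0 <- internal_control_filter(c1, c2[0, ]), "controls")
  expect_identical(nrow(flt0$eliminated), 0L)
})

test_that("eliminations equal a brute-force re-evaluation of the rule", {
  run <- default_run()
  scr <- run$screen
  c1 <- scr[scr$cluster == "cluster1", ]
  c2 <- scr[scr$cluster == "cluster2", ]
  flt <- run$filter
  manual <- unique(do.call(rbind, lapply(seq_len(nrow(c1)), function(i) {
    bar <- max(c2$r2[c2$tissue_id == c1$tissue_id[i] &
                     c2$covariate == c1$covariate[i]])
    if (c1$r2[i] > bar) c1[i, c("gene_id", "tissue_id")]
  })))
  got <- flt$eliminated[order(flt$eliminated$gene_id,
                              flt$eliminated$tissue_id), ]
  want <- manual[order(manual$gene_id, manual$tissue_id), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
})

test_that("rank-sum test and Cohen's d match their exact oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(wilcoxon_rank_sum(x, x), 1)          # identical groups
  # complete separation of two groups of 5: exact p = 2 / choose(10, 5)
  expect_equal(wilcoxon_rank_sum(1:5, 11:15), 2 / choose(10, 5))
  expect_equal(wilcoxon_rank_sum(11:15, 1:5), 2 / choose(10, 5))  # symmetry
  expect_true(is.na(wilcoxon_rank_sum(1, 1:5)))     # untestable
  expect_identical(cohens_d(x, x), 0)
  # means 1 vs 0, both SD 1 (exactly), equal n: d = 1
  a <- 1 + c(-1, 1) / sqrt(2); b <- a - 1
  expect_equal(sd(a), 1)
  expect_equal(cohens_d(a, b), 1)
  expect_equal(cohens_d(b, a), -1)                  # antisymmetry
  expect_identical(cohens_d(c(1, 1), c(0, 0)), Inf) # zero pooled SD
})

test_that("sex-bias screen recovers planted biases and respects its knobs", {
  run <- default_run()
  sim <- run$sim
  sb <- sex_bias_screen(sim$panels, run$scan$switch_genes, sim$metadata)
  tr <- sim$truth$genes
  # y-linked genes: male-biased in every tested (shared) tissue
  yl <- sb[sb$gene_id %in% tr$gene_id[tr$class == "y_linked"], ]
  expect_gt(nrow(yl), 0)
  expect_true(all(yl$biased))
  expect_true(all(yl$direction == "male"))
  expect_false(sim$truth$female_tissue %in% sb$tissue_id)  # skipped
  # planted on-fraction-biased genes are detected in their own tissue
  sx <- tr[tr$class == "sex_biased", ]
  own <- sb[paste(sb$gene_id, sb$tissue_id) %in%
            paste(sx$gene_id, sx$tissue),  ]
  expect_gt(mean(own$biased), 0.9)
  expect_true(all(own$direction[own$biased] == "female"))
  # d_min = Inf or fdr -> 0 switch everything off
  expect_identical(
    sum(sex_bias_screen(sim$panels, run$scan$switch_genes, sim$metadata,
                        d_min = Inf)$biased), 0L)
  expect_identical(
    sum(sex_bias_screen(sim$panels, run$scan$switch_genes, sim$metadata,
                        fdr = 0)$biased), 0L)
})

test_that("permuted sex labels yield ~no biased calls", {
  run <- default_run()
  sim <- run$sim
  md <- sim$metadata
  # permute subject sexes once, consistently across tissues
  subs <- unique(md$subject_id)
  set.seed(99)
  new_sex <- setNames(sample(tapply(md$sex, md$subject_id,
                                    function(s) s[1L])), subs)
  md$sex <- unname(new_sex[md$subject_id])
  shared <- setdiff(names(sim$panels), sim$truth$female_tissue)
  sb <- sex_bias_screen(sim$panels[shared], run$scan$switch_genes, md)
  expect_lte(mean(sb$biased), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(sb)))
})
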