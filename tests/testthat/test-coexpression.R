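# Tissue-pair bookkeeping, co-expression profiles, PCA and clustering.

test_that("shared-sample counts and the retention boundary are exact", {
  mk <- function(tissue, subjects) {
    data.frame(subject_id = subjects, sex = "male", tissue_id = tissue,
               organ = tissue, ischemic_time = 1, fixative_time = 1,
               stringsAsFactors = FALSE)
  }
  md <- rbind(mk("a", sprintf("s%02d", 1:60)),
              mk("b", sprintf("s%02d", 21:60)),   # shares exactly 40 with a
              mk("c", sprintf("x%02d", 1:45)))    # shares 0 with a and b
  tab <- shared_sample_counts(md, c("a", "b", "c"), min_shared = 40)
  expect_identical(nrow(tab), 3L)
  ab <- tab[tab$tissue_i == "a" & tab$tissue_j == "b", ]
  expect_identical(ab$n_shared, 40L)
  expect_true(ab$retained)                        # "fewer than 40" excluded
  expect_identical(sum(tab$retained), 1L)
})

test_that("tissue-pair correlation matches hand arithmetic and drops
           undefined cases", {
  v1 <- matrix(c(1, 2, 3, 4, 5,
                 0, 0, 0, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("g", "z"), paste0("s", 1:5)))
  v2 <- matrix(c(2, 1, 4, 3, 6,
                 1, 2, 3, 4, 5), 2, byrow = TRUE,
               dimnames = list(c("g", "z"), paste0("s", 1:5)))
  pa <- expression_panel("a", v1); pb <- expression_panel("b", v2)
  # hand Pearson of the log1p vectors
  x <- log1p(v1["g", ]); y <- log1p(v2["g", ])
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tissue_pair_correlation("g", pa, pb), hand)
  expect_equal(tissue_pair_correlation("g", pa, pa), 1)
  expect_true(is.na(tissue_pair_correlation("z", pa, pb)))  # all-zero side
})

test_that("profile dropping equals the brute-force zero-variance recount", {
  coh <- small_cohort(seed = 21, exact_zero_off = TRUE)
  # with exact zeros, y-linked genes are all-zero among the females of the
  # female-specific tissue's pairs only if every shared subject is female;
  # the general rule is: dropped iff some retained pair has a zero-variance
  # side
  tab <- shared_sample_counts(coh$metadata, names(coh$panels),
                              min_shared = 10)
  genes <- gene_ids(coh$panels[[1]])
  prof <- coexpression_profiles(coh$panels, genes, tab)
  rt <- tab[tab$retained, ]
  expected_drop <- Filter(function(g) {
    any(vapply(seq_len(nrow(rt)), function(k) {
      is.na(tissue_pair_correlation(g, coh$panels[[rt$tissue_i[k]]],
                                    coh$panels[[rt$tissue_j[k]]]))
    }, logical(1)))
  }, genes)
  expect_setequal(prof$dropped, expected_drop)
  expect_identical(nrow(prof$profiles), length(genes) - length(prof$dropped))
  expect_false(anyNA(prof$profiles))
})

test_that("PCA embedding is centred, ordered and sign-stable", {
  # profiles on an exact line: PC1 explains everything
  line <- outer(seq(-2, 2, length.out = 9), c(1, 2, 0.5))
  rownames(line) <- paste0("g", 1:9)
  emb <- pca_embed(line)
  expect_equal(emb$variance_fraction[1], 1)
  expect_true(all(diff(emb$variance_fraction) <= 1e-12))
  expect_lte(sum(emb$variance_fraction), 1 + 1e-8)
  # sign convention: the largest-|score| coordinate is positive
  expect_gt(emb$scores[which.max(abs(emb$scores[, 1])), 1], 0)
  expect_error(pca_embed(line[1, , drop = FALSE]), "2 profiles")
})

test_that("complete-linkage cut matches a hand-worked dendrogram", {
  # 1-D points: 0, .1, .25 | 1.0, 1.15 | 3.0
  # complete linkage merges: {0,.1} d=.1; {1.0,1.15} d=.15; {0,.1,.25} d=.25;
  # then {1.0,1.15} with {0..25} at d=1.15, finally 3.0 at d=3.
  pts <- matrix(c(0, 0.1, 0.25, 1.0, 1.15, 3.0), ncol = 1,
                dimnames = list(paste0("p", 1:6), NULL))
  k3 <- hcluster_cut(pts, 3)
  expect_identical(unname(k3[1:3]), rep(k3[["p1"]], 3))
  expect_identical(k3[["p4"]], k3[["p5"]])
  expect_identical(length(unique(k3)), 3L)
  expect_identical(length(unique(hcluster_cut(pts, 1))), 1L)
  expect_error(hcluster_cut(pts, 7), "k must be")
  # two separated clouds, k = 2: perfect split
  set.seed(2)
  cloud <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                 matrix(rnorm(40, 10, 0.1), ncol = 2))
  rownames(cloud) <- paste0("c", 1:40)
  k2 <- hcluster_cut(cloud, 2)
  expect_identical(length(unique(k2[1:20])), 1L)
  expect_identical(length(unique(k2[21:40])), 1L)
})

test_that("semantic labels recover the planted taxonomy", {
  run <- default_run()
  asg <- run$assignments
  cls <- run$sim$truth$genes
  lab <- setNames(asg$fine, asg$gene_id)
  svg <- intersect(cls$gene_id[cls$class == "universal_sv"], names(lab))
  ylg <- intersect(cls$gene_id[cls$class == "y_linked"], names(lab))
  hrg <- intersect(cls$gene_id[cls$class == "tissue_specific_hormone"],
                   names(lab))
  expect_true(all(lab[svg] == "cluster2A"))
  expect_true(all(lab[ylg] == "cluster2B"))
  expect_true(mean(lab[hrg] == "cluster1") > 0.95)
  # labels are invariant to the order genes enter the embedding
  perm <- sample(nrow(run$emb$scores))
  asg2 <- label_clusters(run$emb$scores[perm, ], run$scan$results,
                         run$sim$panels, run$sim$metadata)
  lab2 <- setNames(asg2$fine, asg2$gene_id)
  expect_identical(lab2[names(lab)], lab)
})

test_that("intra-tissue gene-gene correlation behaves", {
  p <- tiny_panel()
  v <- p$values[c(1, 1, 2), ]
  rownames(v) <- c("a", "b", "c")
  dup <- expression_panel("t", v)
  r <- intra_tissue_gene_correlation(dup, c("a", "b", "c"))
  expect_equal(r["a", "b"], 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  # planted hormone genes co-express strongly in their tissue; background
  # genes do not
  run <- default_run()
  tr <- run$sim$truth
  hg <- tr$genes$gene_id[tr$genes$class == "tissue_specific_hormone" &
                         tr$genes$tissue == "T01"]
  rh <- intra_tissue_gene_correlation(run$sim$panels[["T01"]], hg)
  expect_gt(mean(rh[upper.tri(rh)]), 0.6)
  bg <- tr$genes$gene_id[tr$genes$class == "background"][1:20]
  rb <- suppressWarnings(
    intra_tissue_gene_correlation(run$sim$panels[["T01"]], bg))
  expect_lt(mean(abs(rb[upper.tri(rb)]), na.rm = TRUE), 0.25)
})
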