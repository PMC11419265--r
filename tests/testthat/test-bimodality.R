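# Filtering, transforms, multiple testing, the effect-size gate, and the
# genome-wide scan driver.

test_that("tissue filter keeps one tissue per organ, at the size cutoff", {
  md <- do.call(rbind, lapply(1:4, function(k) {
    n <- c(60, 70, 80, 49)[k]
    data.frame(subject_id = sprintf("s%03d", 1:n),
               sex = "female",
               tissue_id = c("colon_a", "colon_b", "lung", "spleen")[k],
               organ = c("colon", "colon", "lung", "spleen")[k],
               ischemic_time = 100, fixative_time = 5,
               stringsAsFactors = FALSE)
  }))
  kept <- filter_tissues(md, min_subjects = 50, seed = 1)
  expect_length(intersect(kept, c("colon_a", "colon_b")), 1L)  # one per organ
  expect_true("lung" %in% kept)
  expect_false("spleen" %in% kept)                              # 49 < 50
  # all-distinct organs, all eligible: identity
  md2 <- md[md$tissue_id != "colon_b" & md$tissue_id != "spleen", ]
  expect_setequal(filter_tissues(md2, 50, seed = 1), c("colon_a", "lung"))
  # the random choice is seed-controlled
  picks <- vapply(1:20, function(s)
    intersect(filter_tissues(md, 50, seed = s), c("colon_a", "colon_b")),
    character(1))
  expect_length(unique(picks), 2L)
  expect_identical(filter_tissues(md, 50, seed = 9),
                   filter_tissues(md, 50, seed = 9))
})

test_that("expression universe uses a strict mean-TPM inequality", {
  mk <- function(tissue, means) {
    v <- matrix(rep(means, 4), ncol = 4,
                dimnames = list(paste0("g", seq_along(means)),
                                paste0("s", 1:4)))
    expression_panel(tissue, v)
  }
  panels <- list(mk("a", c(10, 10.5, 2)), mk("b", c(10, 0, 0)))
  u <- filter_genes_by_expression(panels, 10)
  expect_setequal(u$members, "g2")  # mean exactly 10 everywhere: excluded
})

test_that("log1p transform maps 0 to 0 and preserves order", {
  expect_identical(log1p_transform(0), 0)
  expect_equal(log1p_transform(exp(1) - 1), 1)
  x <- sort(rlnorm(50))
  expect_false(is.unsorted(log1p_transform(x)))
  expect_error(log1p_transform(c(1, -2)), ">= 0")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_true(all(r$reject))        # p_(4) = 0.04 <= 4 * 0.05/4
  expect_equal(r$q_values, c(0.04, 0.04, 0.04, 0.04))
  expect_false(any(bh_adjust(rep(1, 5))$reject))
  expect_true(bh_adjust(0.04, 0.05)$reject)   # m = 1: raw threshold
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # rejections at FDR 0.10 are a superset of those at 0.05
  set.seed(8)
  p <- runif(200)^2
  expect_true(all(bh_adjust(p, 0.05)$reject <= bh_adjust(p, 0.10)$reject))
})

test_that("effect-size gate follows D > max(0.05, 0.05/log(mean TPM))", {
  expect_true(effect_size_gate(0.06, 100))       # threshold 0.05
  expect_false(effect_size_gate(0.06, 1.5))      # 0.05/log(1.5) ~ 0.1233
  expect_false(effect_size_gate(0.05, 100))      # strict inequality
  expect_warning(g <- effect_size_gate(0.2, 0.5), "TPM <= 1")
  expect_false(g)
  # threshold non-increasing in mean TPM above 1
  tpm <- seq(1.05, 50, length.out = 40)
  thr <- pmax(0.05, 0.05 / log(tpm))
  expect_true(all(diff(thr) <= 0))
  # log10 option raises the low-expression bar
  expect_false(effect_size_gate(0.06, 3, log_base = 10))
})

test_that("the scan driver has power at the planted effect size", {
  # p_on = 0.5, delta = 4 sigma-units, n = 300: the dip test should reject
  # at FDR 5% in the vast majority of replicates
  nt <- dip_null_table(300, n_boot = 1000, seed = 2)
  set.seed(31)
  rej <- replicate(40, {
    x <- simulate_bimodal_sample(300, p_on = 0.5, log_mean_off = -0.5,
                                 log_mean_on = 3.5, log_sd = 1)
    dip_test(log1p(x), null_dips = nt)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("scan results are deterministic and carry coherent flags", {
  coh <- small_cohort()
  u <- filter_genes_by_expression(coh$panels)
  s1 <- suppressWarnings(call_bimodal(coh$panels, u, n_boot = 500, seed = 4))
  s2 <- suppressWarnings(call_bimodal(coh$panels, u, n_boot = 500, seed = 4))
  expect_identical(s1$results, s2$results)
  r <- s1$results
  expect_identical(nrow(r), length(u$members) * length(coh$panels))
  expect_true(all(r$p_value >= 1 / 501 & r$p_value <= 1))
  expect_true(all(r$dip_stat >= 1 / (2 * r$n_samples)))
  # bimodal implies BH rejection AND gate pass
  gate <- suppressWarnings(effect_size_gate(r$dip_stat, r$mean_tpm))
  expect_true(all(r$bimodal <= (r$q_value <= 0.05 & gate)))
  expect_setequal(s1$switch_genes$members, unique(r$gene_id[r$bimodal]))
})
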