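# Synthetic multi-tissue cohort generator with planted ground truth.
#
# Expression is lognormal on the TPM scale (Gaussian on log TPM), the
# standard bulk-RNA marginal; "on"/"off" states differ by `delta` log units
# with per-observation noise `sigma`, so the default delta = 4, sigma = 1
# plants a 4-sigma separation.  Off states are small-positive lognormals
# (optionally exact zeros, to exercise the all-zero gene-removal rule in
# co-expression profiling).
#
# Every gene draws its values from an RNG stream derived by stable hashing
# of (seed, gene id), so panels are reproducible independently of the order
# in which genes are generated.

#' Configuration of a synthetic cohort
#'
#' Planted gene classes:
#' \describe{
#'   \item{background}{unimodal lognormal expression, per-gene baselines
#'     spanning the high/low expression range (so the mean-TPM universe
#'     filter is exercised).}
#'   \item{universal_sv}{a biallelic gene deletion segregating at allele
#'     frequency `sv_allele_freq`; subjects homozygous for the deletion
#'     (probability q^2 under Hardy-Weinberg) have the gene off in every
#'     tissue.}
#'   \item{y_linked}{expressed (on) in males only, in all tissues shared by
#'     the sexes; in female-specific tissue everyone is off.}
#'   \item{tissue_specific_hormone}{on in the gene's designated tissue iff
#'     the subject's latent hormone level for that tissue exceeds
#'     `hormone_threshold`; all hormone genes of one tissue share the
#'     latent, so they toggle concordantly within a subject.}
#'   \item{confounded}{log-expression depends linearly (slope
#'     `confounder_beta` per SD) on the tissue's ischemic time, which is
#'     bimodal across donors (fast versus slow deaths), producing
#'     pseudo-bimodal expression in the designated tissue.}
#'   \item{sex_biased}{on with probability `sex_on_fraction_female` in
#'     females and `sex_on_fraction_male` in males in the designated shared
#'     tissue (on-fraction bias, not an absolute sex switch).}
#' }
#'
#' The default deletion allele frequency is 0.45: the effect-size gate
#' `D > 0.05` requires a minority-mode fraction of roughly 10% or more
#' (the population dip of a well-separated two-state mixture with minority
#' mass pi is about pi/2), so a detectable planted deletion needs
#' q^2 >= ~0.1.  See the methods vignette.
#'
#' @param n_tissues number of tissues; each is its own organ, and the last
#'   one is female-specific when `female_specific_tissue` is TRUE.
#' @param n_subjects cohort size.
#' @param sampling_fraction probability a subject was sampled for a given
#'   tissue (independent thinning; makes shared-sample counts vary).
#' @param n_background,n_universal_sv,n_y_linked,n_hormone,n_confounded,n_sex_biased
#'   genes per planted class.
#' @param sv_allele_freq deletion allele frequency q in \[0, 1\].
#' @param hormone_threshold latent-hormone cutoff (latents are N(0,1), so 0
#'   gives an on-fraction of one half).
#' @param delta on/off separation in log-TPM units (default 4 = 4 sigma).
#' @param sigma log-scale expression noise SD of the on state and of
#'   unimodal background expression (default 1).
#' @param sigma_off log-scale noise SD of the off state (default 0.15):
#'   a silenced or deleted gene sits at the quantification detection floor,
#'   where log-scale spread is strongly compressed relative to biological
#'   on-state variation.
#' @param log_mean_off log-TPM centre of the off state (default -0.5,
#'   i.e. TPM ~ 0.4).
#' @param exact_zero_off if TRUE, off states are exactly 0 TPM.
#' @param confounder_beta log-TPM shift per SD of ischemic time (default
#'   3.5, strong enough that confounded genes clear the dip gate and are
#'   discoverable -- elimination can only act on discovered genes).
#' @param sex_on_fraction_female,sex_on_fraction_male on-state probabilities
#'   of sex-biased genes by sex.
#' @param ischemic_effect,fixative_effect global log-TPM shift per
#'   within-tissue SD of ischemic time (default 0.4) and fixative time
#'   (default 0.3), applied multiplicatively to every gene: the
#'   post-mortem degradation gradient that affects all transcripts.  It is
#'   this shared technical gradient that gives the internal-control
#'   confounder filter a meaningful bar.
#' @param female_specific_tissue plant one female-only tissue?
#' @param seed integer master seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 8L,
                          n_subjects = 300L,
                          sampling_fraction = 0.8,
                          n_background = 300L,
                          n_universal_sv = 23L,
                          n_y_linked = 8L,
                          n_hormone = 32L,
                          n_confounded = 20L,
                          n_sex_biased = 18L,
                          sv_allele_freq = 0.45,
                          hormone_threshold = 0,
                          delta = 4,
                          sigma = 1,
                          sigma_off = 0.15,
                          log_mean_off = -0.5,
                          exact_zero_off = FALSE,
                          confounder_beta = 3.5,
                          sex_on_fraction_female = 0.9,
                          sex_on_fraction_male = 0.1,
                          ischemic_effect = 0.4,
                          fixative_effect = 0.3,
                          female_specific_tissue = TRUE,
                          seed = 1L) {
  cfg <- as.list(environment())
  assert_scalar_number(n_tissues, "n_tissues", 2)
  assert_scalar_number(n_subjects, "n_subjects", 2)
  assert_scalar_number(sampling_fraction, "sampling_fraction", 0, 1)
  for (nm in c("n_background", "n_universal_sv", "n_y_linked", "n_hormone",
               "n_confounded", "n_sex_biased"))
    assert_scalar_number(cfg[[nm]], nm, 0)
  assert_scalar_number(sv_allele_freq, "sv_allele_freq", 0, 1)
  if (delta <= 0) stopf("'delta' must be > 0")
  if (sigma <= 0) stopf("'sigma' must be > 0")
  if (sigma_off <= 0) stopf("'sigma_off' must be > 0")
  for (nm in c("sex_on_fraction_female", "sex_on_fraction_male"))
    assert_scalar_number(cfg[[nm]], nm, 0, 1)
  assert_scalar_number(seed, "seed")
  structure(cfg, class = "cohort_config")
}

#' Lognormal expression samplers
#'
#' `simulate_unimodal_sample()` draws `n` TPM values whose natural log is
#' N(`log_mean`, `log_sd`); `simulate_bimodal_sample()` mixes two such
#' components, each value "on" with probability `p_on`.
#'
#' @param n sample size (>= 1).
#' @param log_mean,log_sd lognormal parameters (natural-log scale).
#' @param p_on mixing probability of the on component.
#' @param log_mean_off,log_mean_on component centres.
#' @param log_sd_off optional separate spread for the off component
#'   (defaults to `log_sd`; a tight value emulates the detection floor).
#' @param seed optional seed (caller's RNG untouched when supplied).
#' @return numeric vector of non-negative TPM values; the bimodal sampler
#'   carries the on/off assignment in attribute `"on"`.
#' @export
simulate_unimodal_sample <- function(n, log_mean = 3, log_sd = 1,
                                     seed = NULL) {
  assert_scalar_number(n, "n", 1)
  if (log_sd <= 0) stopf("'log_sd' must be > 0")
  draw <- function() rlnorm(n, meanlog = log_mean, sdlog = log_sd)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @rdname simulate_unimodal_sample
#' @export
simulate_bimodal_sample <- function(n, p_on = 0.5, log_mean_off = -0.5,
                                    log_mean_on = 3.5, log_sd = 1,
                                    log_sd_off = log_sd, seed = NULL) {
  assert_scalar_number(n, "n", 1)
  assert_scalar_number(p_on, "p_on", 0, 1)
  if (log_sd <= 0) stopf("'log_sd' must be > 0")
  draw <- function() {
    on <- runif(n) < p_on
    mu <- ifelse(on, log_mean_on, log_mean_off)
    sdv <- ifelse(on, log_sd, log_sd_off)
    structure(rlnorm(n, meanlog = mu, sdlog = sdv), on = on)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a multi-tissue cohort with planted truth
#'
#' Generates one [expression_panel()] per tissue over a shared subject pool
#' (with Bernoulli subject-tissue thinning), a sample-metadata table with
#' bimodal ischemic times and lognormal fixative times, and a
#' `PlantedTruth` object: per-gene class labels and expected co-expression
#' cluster (`1`, `2A`, `2B`), per-subject latents (sex, deletion genotypes,
#' hormone levels), and expected on/off states for every genuinely
#' switch-like planted gene.  Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `panels` (named list), `metadata` (data.frame) and
#'   `truth` (class `PlantedTruth`: `genes`, `subjects`, `states`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  tissues <- sprintf("T%02d", seq_len(cf$n_tissues))
  organs <- sprintf("O%02d", seq_len(cf$n_tissues))
  female_tissue <- if (cf$female_specific_tissue) tissues[cf$n_tissues]
                   else NA_character_
  shared <- setdiff(tissues, female_tissue)
  subjects <- sprintf("S%04d", seq_len(cf$n_subjects))

  # subject-level latents
  sub <- with_seed(hash_seed(cf$seed, "subjects"), {
    sex <- ifelse(runif(cf$n_subjects) < 0.5, "female", "male")
    # donor-level ischemic time: mixture of fast and slow deaths (minutes)
    fast <- runif(cf$n_subjects) < 0.5
    isch <- ifelse(fast, rnorm(cf$n_subjects, 300, 50),
                   rnorm(cf$n_subjects, 900, 80))
    list(sex = sex, ischemic_base = pmax(0, isch))
  })

  # presence, covariates
  meta <- with_seed(hash_seed(cf$seed, "presence"), {
    rows <- list()
    for (k in seq_along(tissues)) {
      ti <- tissues[k]
      can <- if (identical(ti, female_tissue)) sub$sex == "female"
             else rep(TRUE, cf$n_subjects)
      pres <- can & (runif(cf$n_subjects) < cf$sampling_fraction)
      idx <- which(pres)
      rows[[k]] <- data.frame(
        subject_id = subjects[idx],
        sex = sub$sex[idx],
        tissue_id = ti,
        organ = organs[k],
        ischemic_time = pmax(0, sub$ischemic_base[idx] + rnorm(length(idx), 0, 60)),
        fixative_time = rlnorm(length(idx), log(6), 0.4),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  # per-tissue latent hormone levels (shared by that tissue's hormone genes)
  # every tissue hosts its own (small) hormone-driven gene group: losses
  # from an unlucky latent-covariate fluctuation stay local and small
  hormone_tissues <- tissues
  hormone <- with_seed(hash_seed(cf$seed, "hormone"), {
    h <- matrix(rnorm(cf$n_subjects * length(hormone_tissues)),
                nrow = cf$n_subjects,
                dimnames = list(subjects, hormone_tissues))
    h
  })

  # gene table
  gene_tab <- local({
    mk <- function(prefix, n, class) {
      if (n == 0L) return(NULL)
      data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n)),
                 class = class, stringsAsFactors = FALSE)
    }
    rbind(mk("BG", cf$n_background, "background"),
          mk("SV", cf$n_universal_sv, "universal_sv"),
          mk("YL", cf$n_y_linked, "y_linked"),
          mk("HR", cf$n_hormone, "tissue_specific_hormone"),
          mk("CF", cf$n_confounded, "confounded"),
          mk("SX", cf$n_sex_biased, "sex_biased"))
  })
  assign_tissue <- function(ids, pool) pool[(seq_along(ids) - 1L) %% length(pool) + 1L]
  gene_tab$tissue <- NA_character_
  gene_tab$tissue[gene_tab$class == "tissue_specific_hormone"] <-
    assign_tissue(which(gene_tab$class == "tissue_specific_hormone"),
                  hormone_tissues)
  gene_tab$tissue[gene_tab$class == "confounded"] <-
    assign_tissue(which(gene_tab$class == "confounded"), shared)
  gene_tab$tissue[gene_tab$class == "sex_biased"] <-
    assign_tissue(which(gene_tab$class == "sex_biased"), shared)
  gene_tab$expected_cluster <- c(
    background = NA_character_, universal_sv = "2A", y_linked = "2B",
    tissue_specific_hormone = "1", confounded = "1",
    sex_biased = "1")[gene_tab$class]

  # global degradation gradient: expressed transcripts respond (mildly) to
  # ischemic and fixative time; off states sit at the quantification floor
  # and do not scale with degradation
  degrade <- lapply(tissues, function(ti) {
    md <- meta[meta$tissue_id == ti, ]
    zk <- as.numeric(scale(md$ischemic_time))
    zf <- as.numeric(scale(md$fixative_time))
    exp(cf$ischemic_effect * zk + cf$fixative_effect * zf)
  })
  names(degrade) <- tissues

  mu_on <- cf$log_mean_off + cf$delta
  draw_vals <- function(n, mu) exp(rnorm(n, mu, cf$sigma))
  draw_off <- function(n) {
    if (cf$exact_zero_off) rep(0, n)
    else exp(rnorm(n, cf$log_mean_off, cf$sigma_off))
  }

  # per-gene subject-level hidden states (identical across tissues)
  states_by_gene <- list()  # gene -> logical per subject (TRUE = on) or NULL
  panel_vals <- lapply(tissues, function(ti) {
    matrix(NA_real_, nrow = nrow(gene_tab),
           ncol = sum(meta$tissue_id == ti),
           dimnames = list(gene_tab$gene_id,
                           meta$subject_id[meta$tissue_id == ti]))
  })
  names(panel_vals) <- tissues

  genotypes <- matrix(NA_integer_, nrow = cf$n_subjects, ncol = 0)
  sv_genes <- gene_tab$gene_id[gene_tab$class == "universal_sv"]
  if (length(sv_genes)) {
    genotypes <- matrix(NA_integer_, cf$n_subjects, length(sv_genes),
                        dimnames = list(subjects, sv_genes))
  }

  for (gi in seq_len(nrow(gene_tab))) {
    g <- gene_tab$gene_id[gi]
    cls <- gene_tab$class[gi]
    gseed <- hash_seed(cf$seed, g)
    with_seed(gseed, {
      if (cls == "background") {
        base <- runif(1, 0.5, 3.5)
        for (ti in tissues) {
          n <- ncol(panel_vals[[ti]])
          panel_vals[[ti]][g, ] <- draw_vals(n, base + rnorm(1, 0, 0.3)) *
            degrade[[ti]]
        }
      } else if (cls == "universal_sv") {
        hom <- runif(cf$n_subjects) < cf$sv_allele_freq^2
        genotypes[, g] <- ifelse(hom, 2L, 0L)  # 2 = homozygous deletion
        on <- !hom
        states_by_gene[[g]] <- setNames(on, subjects)
        for (ti in tissues) {
          sids <- colnames(panel_vals[[ti]])
          o <- on[match(sids, subjects)]
          v <- draw_vals(length(sids), mu_on) * degrade[[ti]]
          v[!o] <- draw_off(sum(!o))
          panel_vals[[ti]][g, ] <- v
        }
      } else if (cls == "y_linked") {
        on <- sub$sex == "male"
        states_by_gene[[g]] <- setNames(on, subjects)
        for (ti in tissues) {
          sids <- colnames(panel_vals[[ti]])
          o <- on[match(sids, subjects)]
          v <- draw_vals(length(sids), mu_on) * degrade[[ti]]
          v[!o] <- draw_off(sum(!o))
          panel_vals[[ti]][g, ] <- v
        }
      } else if (cls == "tissue_specific_hormone") {
        own <- gene_tab$tissue[gi]
        on <- hormone[, own] > cf$hormone_threshold
        states_by_gene[[g]] <- setNames(on, subjects)
        for (ti in tissues) {
          sids <- colnames(panel_vals[[ti]])
          if (identical(ti, own)) {
            o <- on[match(sids, subjects)]
            v <- draw_vals(length(sids), mu_on) * degrade[[ti]]
            v[!o] <- draw_off(sum(!o))
            panel_vals[[ti]][g, ] <- v
          } else {
            panel_vals[[ti]][g, ] <- draw_vals(length(sids), 2.5) *
              degrade[[ti]]
          }
        }
      } else if (cls == "confounded") {
        own <- gene_tab$tissue[gi]
        for (ti in tissues) {
          sids <- colnames(panel_vals[[ti]])
          if (identical(ti, own)) {
            k <- meta$ischemic_time[meta$tissue_id == ti]
            z <- (k - mean(k)) / stats::sd(k)
            panel_vals[[ti]][g, ] <- exp(2 + cf$confounder_beta * z +
                                          rnorm(length(sids), 0, cf$sigma)) *
              degrade[[ti]]
          } else {
            panel_vals[[ti]][g, ] <- draw_vals(length(sids), 2.5) *
              degrade[[ti]]
          }
        }
      } else if (cls == "sex_biased") {
        own <- gene_tab$tissue[gi]
        p <- ifelse(sub$sex == "female", cf$sex_on_fraction_female,
                    cf$sex_on_fraction_male)
        on <- runif(cf$n_subjects) < p
        states_by_gene[[g]] <- setNames(on, subjects)
        for (ti in tissues) {
          sids <- colnames(panel_vals[[ti]])
          if (identical(ti, own)) {
            o <- on[match(sids, subjects)]
            v <- draw_vals(length(sids), mu_on) * degrade[[ti]]
            v[!o] <- draw_off(sum(!o))
            panel_vals[[ti]][g, ] <- v
          } else {
            panel_vals[[ti]][g, ] <- draw_vals(length(sids), 2.5) *
              degrade[[ti]]
          }
        }
      }
    })
  }

  panels <- lapply(tissues, function(ti) expression_panel(ti, panel_vals[[ti]]))
  names(panels) <- tissues

  # expected on/off states per tissue for the genuinely switch-like classes
  switch_classes <- c("universal_sv", "y_linked", "tissue_specific_hormone",
                      "sex_biased")
  states <- lapply(tissues, function(ti) {
    sids <- colnames(panel_vals[[ti]])
    gsel <- gene_tab$gene_id[gene_tab$class %in% switch_classes &
                             (is.na(gene_tab$tissue) | gene_tab$tissue == ti |
                              gene_tab$class %in% c("universal_sv", "y_linked"))]
    gsel <- gsel[vapply(gsel, function(g) !is.null(states_by_gene[[g]]),
                        logical(1))]
    m <- do.call(rbind, lapply(gsel, function(g)
      states_by_gene[[g]][match(sids, subjects)]))
    if (is.null(m)) return(NULL)
    rownames(m) <- gsel
    colnames(m) <- sids
    m
  })
  names(states) <- tissues

  # truth-consistent synthetic genome annotation: universal_sv genes live on
  # "chrS" and are each overlapped by a planted deletion; y_linked genes sit
  # in the male-specific region of chrY; everything else on "chrB".
  annotation <- local({
    n <- nrow(gene_tab)
    chrom <- rep("chrB", n)
    chrom[gene_tab$class == "universal_sv"] <- "chrS"
    chrom[gene_tab$class == "y_linked"] <- "chrY"
    start <- 10000L * seq_len(n)
    df <- data.frame(gene_id = gene_tab$gene_id, chrom = chrom,
                     start = start, end = start + 5000L, strand = "+",
                     chry_msr = gene_tab$class == "y_linked",
                     stringsAsFactors = FALSE)
    attr(df, "assembly") <- "synth1"
    df
  })
  svs <- local({
    sel <- annotation[gene_tab$class == "universal_sv", , drop = FALSE]
    df <- data.frame(chrom = sel$chrom, start = sel$start + 1000L,
                     end = sel$end + 1000L,
                     name = paste0("del_", sel$gene_id),
                     variant_type = "deletion",
                     allele_frequency = cf$sv_allele_freq,
                     stringsAsFactors = FALSE)
    attr(df, "assembly") <- "synth1"
    df
  })

  truth <- structure(list(
    genes = gene_tab,
    annotation = annotation,
    svs = svs,
    subjects = data.frame(subject_id = subjects, sex = sub$sex,
                          ischemic_base = sub$ischemic_base,
                          stringsAsFactors = FALSE),
    genotypes = genotypes,
    hormone = hormone,
    hormone_threshold = cf$hormone_threshold,
    female_tissue = female_tissue,
    states = states
  ), class = "PlantedTruth")

  list(panels = panels, metadata = validate_sample_metadata(meta),
       truth = truth)
}

#' @export
print.PlantedTruth <- function(x, ...) {
  cat("PlantedTruth:", nrow(x$genes), "genes\n")
  print(table(x$genes$class))
  invisible(x)
}
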