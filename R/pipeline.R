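# End-to-end orchestration with a JSON config, per-stage outputs and a
# machine-readable run report.  Glue only: every computation lives in the
# stage modules.

.default_params <- list(
  fdr = 0.05, n_boot = 5000L, min_subjects = 50L, min_shared = 40L,
  tpm_threshold = 10, d_min = 0.2, n_perm = 10000L)

.default_stages <- list(
  filter = TRUE, dip = TRUE, coexpr = TRUE, cluster = TRUE,
  confound = TRUE, sexbias = TRUE, enrich = FALSE, switchcall = TRUE,
  genetic_basis = FALSE)

#' Validate a pipeline configuration file
#'
#' The config is JSON with top-level keys `seeds` (explicit integer seed
#' per stochastic stage: `tissue_choice`, `dip_boot`, `permutation`,
#' `simulation`), `params`, `stages`, and exactly one of `simulate` (cohort
#' generator settings, see [cohort_config()]) or `inputs` (paths to panels
#' and metadata).  Unknown keys anywhere are rejected, and every seed must
#' be explicit (fail-closed reproducibility).
#'
#' @param path JSON file path.
#' @return validated config list of class `RunConfig`.
#' @export
validate_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("seeds", "params", "stages", "simulate", "inputs",
                 "disease_lists", "genetic")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  need_seeds <- c("tissue_choice", "dip_boot", "permutation", "simulation")
  miss <- setdiff(need_seeds, names(raw$seeds))
  if (length(miss))
    stopf("missing explicit seed(s): %s", paste(miss, collapse = ", "))
  seeds <- lapply(raw$seeds[need_seeds], function(s) {
    if (!is.numeric(s) || length(s) != 1L) stopf("seeds must be integers")
    as.integer(s)
  })
  unknown <- setdiff(names(raw$params), names(.default_params))
  if (length(unknown))
    stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  params <- utils::modifyList(.default_params, as.list(raw$params))
  assert_scalar_number(params$fdr, "fdr", 0, 1)
  assert_scalar_number(params$d_min, "d_min", 0)
  assert_scalar_number(params$n_boot, "n_boot", 1)
  assert_scalar_number(params$n_perm, "n_perm", 1)
  assert_scalar_number(params$tpm_threshold, "tpm_threshold", 0)
  unknown <- setdiff(names(raw$stages), names(.default_stages))
  if (length(unknown))
    stopf("unknown stage flag(s): %s", paste(unknown, collapse = ", "))
  stages <- utils::modifyList(.default_stages, as.list(raw$stages))
  if (!is.null(raw$simulate) && !is.null(raw$inputs))
    stopf("give either 'simulate' or 'inputs', not both")
  if (is.null(raw$simulate) && is.null(raw$inputs))
    stopf("one of 'simulate' or 'inputs' is required")
  sim <- NULL
  if (!is.null(raw$simulate)) {
    args <- as.list(raw$simulate)
    args$seed <- seeds$simulation
    sim <- do.call(cohort_config, args)  # validates ranges, rejects unknowns
  }
  structure(list(seeds = seeds, params = params, stages = stages,
                 simulate = sim, inputs = raw$inputs,
                 disease_lists = raw$disease_lists, genetic = raw$genetic),
            class = "RunConfig")
}

#' Run the full switch-like expression pipeline
#'
#' Stage order: tissue/gene filtering, dip scan, co-expression profiling,
#' clustering, confounder screen, sex-bias screen, optional disease
#' enrichment, on/off switch calls with concordance, optional genetic-basis
#' classification.  Each stage writes its table under `out_dir` (when
#' given), and the returned report records per-stage counts, parameters and
#' seeds.  A stage failure aborts with the stage name; outputs of completed
#' stages are retained on disk.
#'
#' @param config `RunConfig` from [validate_config()], or a [cohort_config()]
#'   (run entirely on a simulated cohort with default parameters).
#' @param out_dir optional output directory for stage TSVs and the report.
#' @return report list (invisibly written as JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "cohort_config")) {
    config <- structure(list(
      seeds = list(tissue_choice = config$seed + 1L,
                   dip_boot = config$seed + 2L,
                   permutation = config$seed + 3L,
                   simulation = config$seed),
      params = .default_params, stages = .default_stages,
      simulate = config, inputs = NULL, disease_lists = NULL,
      genetic = NULL), class = "RunConfig")
  }
  stopifnot(inherits(config, "RunConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(params = config$params, seeds = config$seeds,
                 stages = list())
  emit <- function(name, df) {
    if (!is.null(out_dir) && is.data.frame(df))
      write_results_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    panels <- sim$panels; metadata <- sim$metadata; truth <- sim$truth
  } else {
    inp <- config$inputs
    metadata <- stage("inputs", read_sample_metadata(inp$metadata))
    files <- list.files(inp$panel_dir, pattern = "\\.gct$",
                        full.names = TRUE)
    if (length(files) == 0L) stopf("no panel files in %s", inp$panel_dir)
    panels <- stage("inputs", {
      ps <- lapply(files, function(f)
        read_expression_gct(f, sub("\\.gct$", "", basename(f))))
      names(ps) <- vapply(ps, function(p) p$tissue_id, character(1))
      ps
    })
  }
  report$stages$input <- list(n_tissues = length(panels),
                              n_subjects = length(unique(metadata$subject_id)))

  # filter
  tissues <- names(panels)
  if (isTRUE(config$stages$filter)) {
    tissues <- stage("filter",
      filter_tissues(metadata, config$params$min_subjects,
                     seed = config$seeds$tissue_choice))
    panels <- panels[tissues]
  }
  universe <- stage("filter",
    filter_genes_by_expression(panels, config$params$tpm_threshold))
  report$stages$filter <- list(tissues = tissues,
                               n_universe = length(universe$members))

  # dip scan
  scan <- stage("dip",
    call_bimodal(panels, universe, fdr = config$params$fdr,
                 n_boot = config$params$n_boot,
                 seed = config$seeds$dip_boot))
  emit("dip", scan$results)
  report$stages$dip <- list(
    n_pairs = nrow(scan$results),
    n_bimodal_pairs = sum(scan$results$bimodal),
    n_switch_genes = length(scan$switch_genes$members %||% character(0)))
  if (is.null(scan$switch_genes)) {
    report$note <- "no switch-like genes called; downstream stages skipped"
    if (!is.null(out_dir))
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(report)
  }

  # co-expression + clustering
  assignments <- NULL
  if (isTRUE(config$stages$coexpr)) {
    pair_tab <- stage("coexpr",
      shared_sample_counts(metadata, names(panels),
                           config$params$min_shared))
    emit("tissue_pairs", pair_tab)
    prof_all <- stage("coexpr",
      coexpression_profiles(panels, universe$members, pair_tab))
    prof_sw <- list(
      profiles = prof_all$profiles[
        intersect(rownames(prof_all$profiles), scan$switch_genes$members), ,
        drop = FALSE],
      dropped = intersect(prof_all$dropped, scan$switch_genes$members))
    report$stages$coexpr <- list(
      n_pairs_retained = sum(pair_tab$retained),
      n_profiled = nrow(prof_all$profiles),
      n_switch_profiled = nrow(prof_sw$profiles),
      dropped_switch_genes = prof_sw$dropped)
    if (isTRUE(config$stages$cluster)) {
      emb_all <- stage("cluster", pca_embed(prof_all$profiles))
      emb_sw <- stage("cluster", pca_embed(prof_sw$profiles))
      assignments <- stage("cluster",
        label_clusters(emb_sw$scores, scan$results, panels, metadata))
      emit("clusters", assignments)
      report$stages$cluster <- list(
        variance_fraction_all = emb_all$variance_fraction,
        variance_fraction_switch = emb_sw$variance_fraction,
        sizes = as.list(table(assignments$fine)))
    }
  }

  # confounder screen
  genuine <- NULL
  if (!is.null(assignments) && isTRUE(config$stages$confound)) {
    screen <- stage("confound",
      confounder_screen(panels, assignments, metadata, scan$results))
    flt <- stage("confound",
      internal_control_filter(screen[screen$cluster == "cluster1", ],
                              screen[screen$cluster == "cluster2", ]))
    emit("confounder_screen", screen)
    emit("eliminated", flt$eliminated)
    genuine <- flt$genuine
    report$stages$confound <- list(
      n_eliminated_pairs = nrow(flt$eliminated),
      n_genuine_per_tissue = lapply(genuine, length))
  } else if (!is.null(assignments)) {
    # pass-through: raw cluster-1 bimodal sets
    c1 <- assignments$gene_id[assignments$coarse == "cluster1"]
    bi <- scan$results[scan$results$bimodal &
                       scan$results$gene_id %in% c1, ]
    genuine <- lapply(split(bi$gene_id, bi$tissue_id), unique)
    report$stages$confound <- list(skipped = TRUE)
  }

  # sex bias
  if (isTRUE(config$stages$sexbias)) {
    sb <- stage("sexbias",
      sex_bias_screen(panels, scan$switch_genes, metadata,
                      fdr = config$params$fdr,
                      d_min = config$params$d_min))
    emit("sex_bias", sb)
    report$stages$sexbias <- list(
      n_tested = nrow(sb), n_biased = sum(sb$biased),
      n_female = sum(sb$biased & sb$direction == "female"),
      n_male = sum(sb$biased & sb$direction == "male"))
  }

  # enrichment (needs user-supplied disease lists)
  if (isTRUE(config$stages$enrich) && !is.null(config$disease_lists) &&
      length(genuine)) {
    enr <- stage("enrich", {
      rows <- list()
      for (dl in config$disease_lists) {
        Z <- read_gene_list(dl$path, dl$name %||% NULL)
        ti <- dl$tissue
        if (!is.null(genuine[[ti]]) && length(genuine[[ti]])) {
          C <- gene_set(paste0("C_", ti), genuine[[ti]])
          rows[[length(rows) + 1L]] <-
            enrichment_test(C, Z, universe, tissue_id = ti,
                            n_perm = config$params$n_perm,
                            seed = config$seeds$permutation)
        }
      }
      do.call(rbind, rows)
    })
    emit("enrichment", enr)
    report$stages$enrich <- if (is.null(enr)) list(n_tests = 0L) else
      list(n_tests = nrow(enr), folds = enr$fold, p_bounds = enr$p_bound)
  }

  # switch calls + per-tissue concordance of the genuine cluster-1 sets
  if (isTRUE(config$stages$switchcall) && length(genuine)) {
    conc <- stage("switchcall", {
      out <- list()
      for (ti in names(genuine)) {
        gs <- genuine[[ti]]
        if (length(gs) == 0L) next
        scm <- switch_call_matrix(panels[[ti]], gs)
        out[[ti]] <- data.frame(tissue_id = ti, n_genes = nrow(scm$calls),
                                n_subjects = ncol(scm$calls),
                                concordance = concordance(scm),
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    emit("concordance", conc)
    report$stages$switchcall <-
      if (is.null(conc)) list() else
        setNames(as.list(conc$concordance), conc$tissue_id)
  }

  # genetic basis of universally switch-like genes
  if (!is.null(assignments) &&
      (isTRUE(config$stages$genetic_basis) || !is.null(truth))) {
    gb <- stage("genetic_basis", {
      if (!is.null(config$genetic)) {
        ann <- read_gene_annotation(config$genetic$genes,
                                    config$genetic$assembly %||% NA)
        sv <- read_bed(config$genetic$svs,
                       config$genetic$assembly %||% NA)
        eq <- if (!is.null(config$genetic$eqtl))
          read_eqtl_table(config$genetic$eqtl) else NULL
        classify_genetic_basis(assignments, ann, sv, eq,
                               required_tissues = names(panels))
      } else if (!is.null(truth)) {
        classify_genetic_basis(assignments, truth$annotation, truth$svs)
      }
    })
    emit("genetic_basis", gb)
    if (!is.null(gb))
      report$stages$genetic_basis <- as.list(table(gb$category))
  }

  # planted-truth recovery (synthetic cohorts only)
  if (!is.null(truth) && !is.null(assignments))
    report$truth_recovery <- score_recovery(truth, scan, assignments,
                                            genuine)

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' Score pipeline output against planted truth
#'
#' @param truth `PlantedTruth` from [simulate_cohort()].
#' @param scan `dip_scan` from [call_bimodal()].
#' @param assignments cluster assignments from [label_clusters()].
#' @param genuine per-tissue genuine cluster-1 sets (may be NULL).
#' @return list with `sensitivity` (fraction of genuinely switch-like
#'   planted genes called switch-like), `cluster_ari` (adjusted Rand index
#'   of fine labels vs planted cluster truth), `confounded_eliminated` and
#'   `collateral_loss` (when `genuine` is given).
#' @export
score_recovery <- function(truth, scan, assignments, genuine = NULL) {
  g <- truth$genes
  switch_classes <- c("universal_sv", "y_linked", "tissue_specific_hormone",
                      "sex_biased")
  planted <- g$gene_id[g$class %in% switch_classes]
  called <- scan$switch_genes$members %||% character(0)
  sens <- if (length(planted)) mean(planted %in% called) else NA_real_

  lab <- setNames(assignments$fine, assignments$gene_id)
  tru <- setNames(paste0("cluster", g$expected_cluster), g$gene_id)
  common <- intersect(names(lab), g$gene_id[!is.na(g$expected_cluster)])
  ari <- if (length(common) >= 2L)
    adjusted_rand_index(lab[common], tru[common]) else NA_real_

  out <- list(sensitivity = sens, cluster_ari = ari)
  if (!is.null(genuine)) {
    conf <- g$gene_id[g$class == "confounded"]
    conf_called <- intersect(conf, called)
    surv <- unique(unlist(genuine))
    out$confounded_eliminated <- if (length(conf_called))
      mean(!(conf_called %in% surv)) else NA_real_
    c1_true <- intersect(
      g$gene_id[g$class %in% c("tissue_specific_hormone", "sex_biased")],
      assignments$gene_id[assignments$coarse == "cluster1"])
    out$collateral_loss <- if (length(c1_true))
      mean(!(c1_true %in% surv)) else NA_real_
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
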