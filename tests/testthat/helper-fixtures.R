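# Shared fixtures, all built in code at test time.

# tiny 3-gene x 4-subject panel
tiny_panel <- function(tissue = "stomach") {
  v <- matrix(c(0, 1, 5, 10,
                2, 3, 4, 5,
                100, 200, 0, 50), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  expression_panel(tissue, v)
}

tiny_metadata <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    sex = c("male", "female", "male", "female"),
    tissue_id = "stomach",
    organ = "stomach",
    ischemic_time = c(100, 200, 300, 400),
    fixative_time = c(5, 6, 7, 8),
    stringsAsFactors = FALSE)
}

# small fast cohort for module tests (not the acceptance world)
small_cohort <- function(seed = 7L, ...) {
  simulate_cohort(cohort_config(
    n_tissues = 4L, n_subjects = 120L, n_background = 60L,
    n_universal_sv = 6L, n_y_linked = 3L, n_hormone = 8L,
    n_confounded = 4L, n_sex_biased = 4L, seed = seed, ...))
}

# The default planted cohort run end to end, computed once per test session
# (the acceptance world of record; several files assert against it).
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- cohort_config(seed = 20260917L)
    sim <- simulate_cohort(cfg)
    universe <- filter_genes_by_expression(sim$panels)
    scan <- suppressWarnings(
      call_bimodal(sim$panels, universe, seed = 101L))
    pair_tab <- shared_sample_counts(sim$metadata, names(sim$panels))
    prof <- coexpression_profiles(sim$panels, universe$members, pair_tab)
    sw <- intersect(rownames(prof$profiles), scan$switch_genes$members)
    emb <- pca_embed(prof$profiles[sw, , drop = FALSE])
    asg <- label_clusters(emb$scores, scan$results, sim$panels,
                          sim$metadata)
    scr <- suppressWarnings(
      confounder_screen(sim$panels, asg, sim$metadata, scan$results))
    flt <- internal_control_filter(scr[scr$cluster == "cluster1", ],
                                   scr[scr$cluster == "cluster2", ])
    .run_cache$run <- list(sim = sim, universe = universe, scan = scan,
                           pair_tab = pair_tab, prof = prof, emb = emb,
                           assignments = asg, screen = scr, filter = flt)
  }
  .run_cache$run
}
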