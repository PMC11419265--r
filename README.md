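# switchscan

Discovery and interpretation of **switch-like (bimodal) gene expression**
across the tissues of a population RNA-seq cohort.

Most human genes are expressed like dimmers: continuously, unimodally,
across individuals. A minority behave like switches — in some tissue the
population splits into an "off" and an "on" group. The off state of such a
gene can mark disease susceptibility (gastric-cancer- and
vaginal-atrophy-linked gene sets are the motivating examples), and the
mechanism behind the switch — a common gene deletion, Y linkage, a
hormone-dependent transcriptional program, or a mere technical artifact —
is itself the biological question. switchscan is for computational
biologists working with GTEx-style multi-tissue TPM panels who want the
full pipeline: detection, classification, confounder control,
sex-bias and disease-enrichment analysis, on/off discretization, and
genetic-basis annotation — plus a synthetic cohort generator with planted
ground truth so every stage is testable without protected data.

## The statistics at the core

For a gene g and tissue i with samples s, expression `x_{g,i,s}` (TPM) is
tested on the `log(x+1)` scale with **Hartigan's dip statistic** D — the
sup-norm distance between the empirical CDF and the closest unimodal CDF —
with a bootstrap p-value (5000 uniform null samples of matched size),
Benjamini–Hochberg correction at FDR 5% across all gene-tissue pairs, and
the effect-size gate

    D > max(0.05, 0.05 / log(mean TPM))

Genes bimodal in ≥ 1 tissue are *switch-like*. Their tissue-to-tissue
co-expression vectors (Pearson r of log1p expression over all tissue pairs
sharing ≥ 40 subjects) are embedded by PCA and clustered
(complete linkage) into tissue-specific (cluster 1) versus universally
bimodal genes (2A: all tissues; 2B: the tissues shared by both sexes).
Cluster-2 genes act as internal controls for a confounder screen
(eliminate a cluster-1 gene whose r² with ischemic or fixative time exceeds
the cluster-2 maximum), sex bias is quantified by Wilcoxon + Cohen's d
(|d| > 0.2), disease enrichment by
`fold = (|C∩Z|/|C|)/(|G∩Z|/|G|)` with a 10,000-sample resampling null, and
on/off states are called at the interior minimum of a kernel density
estimate, yielding the **concordance** of a gene set: the fraction of
individuals in whom all its genes are simultaneously on or off.

## A worked example

```r
library(switchscan)

# one switch-like gene: half the cohort off at the detection floor,
# half on ~4 log-units higher
x <- simulate_bimodal_sample(300, p_on = 0.5, log_sd_off = 0.15, seed = 7)
r <- dip_test(log1p(x), n_boot = 5000, seed = 1)
sprintf("D = %.4f, p = %.2g, gate = %s", r$dip, r$p_value,
        effect_size_gate(r$dip, mean(x)))
#> "D = 0.0640, p = 0.0002, gate = TRUE"
```

D = 0.064 is far above anything unimodal data of this size produce
(the null 95th percentile at n = 300 is ≈ 0.03), the bootstrap p-value is
at its 1/(n_boot+1) floor, and the pair passes the low-expression gate
because its mean TPM (≈ 28) is high.

The full pipeline on the default synthetic cohort (8 tissues × 300
subjects, 401 genes: unimodal background plus planted deletion-driven,
Y-linked, hormone-driven, ischemic-confounded and sex-biased classes):

```r
report <- run_pipeline(cohort_config(seed = 1))
unlist(report$stages$dip)
#>         n_pairs n_bimodal_pairs  n_switch_genes
#>            2576             304              96
unlist(report$stages$cluster$sizes)
#>  cluster1 cluster2A cluster2B
#>        65        23         8
unlist(report$truth_recovery)
#>           sensitivity           cluster_ari confounded_eliminated
#>             0.9506173             1.0000000             1.0000000
#>       collateral_loss
#>             0.0000000
```

96 switch-like genes are found among 2,576 gene-tissue tests; the
co-expression clustering recovers the planted taxonomy exactly
(all 23 deletion-driven genes in 2A, all 8 Y-linked genes in 2B,
adjusted Rand index 1.0); the internal-control filter eliminates every
planted ischemic-time artifact without losing a single genuine
tissue-specific switch gene; overall 95% of planted switch genes are
recovered.

A thin command-line front end over the same functions ships in
`inst/cli/switchscan` (`simulate`, `dip`, `enrich`, `switchcall`, `run`
subcommands with a JSON config).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline on the default synthetic cohort from scratch
— generation, dip scan, clustering, screens, switch calls, genetic-basis
classification — using the given seed for every source of randomness, logs
the per-stage counts and planted-truth recovery, and writes the JSON
report to `--out` (stage tables land next to it under `pipeline/`).

## Scientific scope

The methods vignette (`vignettes/switchscan-methods.Rmd`) documents the
model and its assumptions, every default of the synthetic world and why it
was chosen (including why the effect-size gate implies a ~10% floor on the
detectable minority-mode mass, and why off states are modelled at the
quantification floor), the numerical choices (tie handling, bootstrap
conservativeness, KDE bandwidth behaviour), and what the planted-cohort
tests do and do not establish.
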