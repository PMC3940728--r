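# Shared study configuration for the analysis scripts.
# Each numbered script is a thin driver over the countgwas package and
# regenerates the synthetic cohort deterministically from this config,
# so the scripts can be run independently or in sequence.

library(countgwas)

study_cfg <- function() {
  sim_config(n_individuals = 2000, n_snps = 5000,
             chrom_length_bp = 5e7, block_size = 20,
             within_block_rho = 0.95, maf_per_block = TRUE,
             timepoints = c(8, 11, 14, 17),
             h2_by_timepoint = c(0.24, 0.16, 0.08, 0.45),
             n_causal = 500, clip_to_range = TRUE, seed = 20260930)
}

study_cohort <- function(cfg = study_cfg()) {
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  genes <- simulate_gene_annotation(cfg, n_genes = 400,
                                    candidate_fraction = 0.02,
                                    mean_len_bp = 50000)
  qc <- qc_filter(G)
  list(cfg = cfg, G = qc$genotypes, qc_report = qc$report,
       panel = panel, genes = genes)
}

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)
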