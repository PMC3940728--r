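#' Run configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] for synthetic input, or NULL to load
#'   from files.
#' @param genotype_prefix,phenotype_path,gene_bed_path Input paths
#'   (PLINK prefix or dosage TSV, phenotype TSV, gene BED); used only
#'   when `sim` is NULL. Exactly one of `sim` / file inputs per run.
#' @param qc A [qc_thresholds()].
#' @param n_scan_ages How many ages (those with the largest estimated
#'   heritability) to carry into the genome-wide scans (default 2).
#' @param clump_window_kb,clump_r2 LD clumping window and r^2 threshold.
#' @param n_perm Number of permutations.
#' @param perm_thresholds GC-corrected p-value thresholds for the
#'   permutation counts, or NULL to use the smallest observed
#'   GC-corrected p-values (the top `n_thresholds` signals at the most
#'   strongly associated age).
#' @param n_thresholds Number of observed top signals to turn into
#'   thresholds when `perm_thresholds` is NULL (default 2).
#' @param candidate_only Count co-location against flagged candidate
#'   genes only (default TRUE).
#' @param n_genes,candidate_fraction,mean_gene_len_bp Gene annotation
#'   parameters for simulated runs.
#' @param out_dir Output directory for artifacts (created); NULL for no
#'   artifact writing.
#' @param seed Master seed for the permutation stage.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       genotype_prefix = NULL, phenotype_path = NULL,
                       gene_bed_path = NULL,
                       qc = qc_thresholds(),
                       n_scan_ages = 2,
                       clump_window_kb = 500, clump_r2 = 0.3,
                       n_perm = 100,
                       perm_thresholds = NULL, n_thresholds = 2,
                       candidate_only = TRUE,
                       n_genes = 400, candidate_fraction = 0.02,
                       mean_gene_len_bp = 50000,
                       out_dir = NULL, seed = 1L) {
  from_files <- !is.null(genotype_prefix)
  if (from_files && !is.null(sim))
    stop("supply either a sim config or input paths, not both")
  if (!from_files && is.null(sim))
    stop("supply a sim config or input paths")
  structure(list(sim = sim, genotype_prefix = genotype_prefix,
                 phenotype_path = phenotype_path,
                 gene_bed_path = gene_bed_path, qc = qc,
                 n_scan_ages = n_scan_ages,
                 clump_window_kb = clump_window_kb, clump_r2 = clump_r2,
                 n_perm = as.integer(n_perm),
                 perm_thresholds = perm_thresholds,
                 n_thresholds = n_thresholds,
                 candidate_only = isTRUE(candidate_only),
                 n_genes = n_genes,
                 candidate_fraction = candidate_fraction,
                 mean_gene_len_bp = mean_gene_len_bp,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim` block
#' holds [sim_config()] arguments (matrices given row-wise).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(doc$sim)) {
    sa <- doc$sim
    for (nm in c("rg_matrix", "re_matrix"))
      if (!is.null(sa[[nm]]))
        sa[[nm]] <- do.call(rbind, lapply(sa[[nm]], as.numeric))
    if (!is.null(sa$covar_effects))
      sa$covar_effects <- unlist(sa$covar_effects)
    sim <- do.call(sim_config, sa)
  }
  qc <- if (is.null(doc$qc)) qc_thresholds()
        else do.call(qc_thresholds, doc$qc)
  args <- doc[setdiff(names(doc), c("sim", "qc"))]
  do.call(run_config, c(list(sim = sim, qc = qc), args))
}

# order-independent FNV-style hash of the serialized config, for
# artifact provenance
config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # hash the analysis, not where it lands
  b <- serialize(cfg, NULL, version = 2)
  h <- 2166136261
  for (x in as.integer(b))
    h <- (bitwAnd(bitwXor(as.integer(h %% 2^31), x), 2^31 - 1) *
            16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Execute the full analysis pipeline
#'
#' Stage order: input (simulate or load), SNP QC, GRM, per-age
#' rank-INT + univariate GREML, selection of the `n_scan_ages` ages
#' with the largest estimated h2, quasi-Poisson genome-wide scans with
#' genomic control at those ages, LD clumping to index variants on the
#' most strongly associated scan, the jointly-permuted genome-wide null
#' with candidate-gene co-location, and a machine-readable report. A
#' stage failure halts with an error naming the stage. With `out_dir`
#' set, every intermediate artifact is written (TSV/JSON), tagged with
#' the config hash and seed.
#'
#' @param cfg A [run_config()].
#' @param verbose Log one line per stage with row counts (default
#'   TRUE).
#' @return A `pipeline_report` list: per-age h2 table, scan ages,
#'   lambda_GC per scan, index-SNP count, lead SNPs, permutation
#'   empirical p-values with SEs, config hash, seed.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hash <- config_hash(cfg)
  od <- cfg$out_dir
  if (!is.null(od) && !dir.exists(od))
    dir.create(od, recursive = TRUE)
  art <- function(name) if (is.null(od)) NULL else file.path(od, name)

  # -- input -------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(cfg$sim)) {
      G <- simulate_genotypes(cfg$sim)
      panel <- simulate_phenotype_panel(G, cfg$sim)
      genes <- simulate_gene_annotation(cfg$sim, cfg$n_genes,
                                        cfg$candidate_fraction,
                                        cfg$mean_gene_len_bp)
      list(G = G, panel = panel, genes = genes)
    } else {
      G <- if (file.exists(paste0(cfg$genotype_prefix, ".bed")))
        read_plink(cfg$genotype_prefix)
      else read_dosage_tsv(cfg$genotype_prefix)
      list(G = G, panel = read_phenotype_tsv(cfg$phenotype_path),
           genes = read_gene_bed(cfg$gene_bed_path))
    }
  })
  G <- inp$G; panel <- inp$panel; genes <- inp$genes
  tps <- panel_timepoints(panel)
  say("input: %d individuals, %d SNPs, %d ages, %d genes",
      nrow(G$dosages), ncol(G$dosages), length(tps), nrow(genes))
  if (!is.null(od)) {
    write_phenotype_tsv(panel, art("phenotypes.tsv"))
    write_gene_bed(genes, art("genes.bed"))
  }

  # -- QC ----------------------------------------------------------
  qc <- stage("qc", qc_filter(G, cfg$qc))
  Gq <- qc$genotypes
  say("qc: %d of %d SNPs retained", ncol(Gq$dosages), ncol(G$dosages))
  if (!is.null(od))
    utils::write.table(qc$report, art("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # -- GRM + per-age GREML ----------------------------------------
  A <- stage("grm", compute_grm(Gq))
  reml <- stage("reml", {
    lapply(tps, function(tp) {
      sc <- panel[[paste0("score_", tp)]]
      X <- cbind(age = panel[[paste0("age_", tp)]], sex = panel$sex,
                 pc1 = panel$pc1, pc2 = panel$pc2)
      yt <- adjust_and_rank_transform(sc, X)
      names(yt) <- panel$id
      reml_univariate(A, yt)
    })
  })
  h2_tab <- data.frame(age = tps,
                       h2 = vapply(reml, `[[`, 0, "h2"),
                       se = vapply(reml, `[[`, 0, "se_h2"),
                       lrt = vapply(reml, `[[`, 0, "lrt_stat"),
                       df = vapply(reml, `[[`, 0L, "lrt_df"),
                       p = vapply(reml, `[[`, 0, "p_value"),
                       n = vapply(reml, `[[`, 0L, "n"))
  say("reml: h2 = %s", paste(sprintf("%.2f", h2_tab$h2), collapse = ", "))
  if (!is.null(od))
    utils::write.table(h2_tab, art("heritability.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # -- scan the ages with the highest h2 --------------------------
  scan_ages <- h2_tab$age[order(-h2_tab$h2)][seq_len(
    min(cfg$n_scan_ages, nrow(h2_tab)))]
  scan_ages <- sort(scan_ages)
  scans <- stage("scan", {
    lapply(scan_ages, function(a) genomic_control(gwas_scan(Gq, panel, a)))
  })
  names(scans) <- as.character(scan_ages)
  lambda <- vapply(scans, `[[`, 0, "lambda")
  say("scan: ages %s, lambda_GC = %s",
      paste(scan_ages, collapse = "/"),
      paste(sprintf("%.3f", lambda), collapse = ", "))
  if (!is.null(od))
    for (a in names(scans))
      write_assoc_tsv(scans[[a]]$table, art(sprintf("assoc_age%s.tsv", a)))

  # -- clump on the most strongly associated scan -----------------
  minp <- vapply(scans, function(s) min(s$table$p_gc, na.rm = TRUE), 0)
  best_age <- names(scans)[which.min(minp)]
  clump <- stage("clump", {
    iset <- select_index_snps(scans[[best_age]]$table, Gq,
                              window_kb = cfg$clump_window_kb,
                              r2_max = cfg$clump_r2)
    regions <- lapply(iset$index$snp_id, clump_region, G = Gq,
                      window_kb = cfg$clump_window_kb,
                      r2_min = cfg$clump_r2)
    names(regions) <- iset$index$snp_id
    list(iset = iset, regions = regions)
  })
  say("clump: %d index SNPs (pruned on age %s)",
      nrow(clump$iset$index), best_age)
  if (!is.null(od))
    write_index_tsv(clump$iset, clump$regions[clump$iset$index$snp_id],
                    art("index_snps.tsv"))

  # -- permutation null -------------------------------------------
  thr <- cfg$perm_thresholds
  if (is.null(thr)) {
    obs <- sort(scans[[best_age]]$table$p_gc)
    thr <- obs[seq_len(min(cfg$n_thresholds, length(obs)))]
  }
  G_index <- subset_snps(Gq, clump$iset$index$snp_id)
  pspec <- permutation_spec(S = cfg$n_perm, thresholds = thr,
                            timepoints = scan_ages, seed = cfg$seed,
                            candidate_only = cfg$candidate_only)
  perm <- stage("permute",
                run_permutation_null(G_index, panel, pspec,
                                     clump$regions, genes))
  say("permute: S = %d done, k_exceed = %s", perm$n_perms,
      paste(perm$k_exceed, collapse = ", "))
  if (!is.null(od))
    write_permutation_json(perm, art("permutation.json"),
                           art("perm_minima.tsv"))

  # -- report ------------------------------------------------------
  lead <- scans[[best_age]]$table
  lead <- lead[order(lead$p_gc), ][seq_len(min(5, nrow(lead))), ]
  obs_overlap <- vapply(lead$snp_id, function(s) {
    r <- clump$regions[[clump$iset$assignment[[s]]]]
    region_overlaps_genes(r, genes,
                          candidate_only = cfg$candidate_only)$overlap
  }, logical(1))
  report <- list(config_hash = hash, seed = cfg$seed,
                 n_individuals = nrow(G$dosages),
                 n_snps_input = ncol(G$dosages),
                 n_snps_qc = ncol(Gq$dosages),
                 heritability = h2_tab,
                 scan_ages = scan_ages,
                 lambda_gc = as.list(lambda),
                 n_index_snps = nrow(clump$iset$index),
                 pruned_on_age = as.numeric(best_age),
                 lead_snps = cbind(lead,
                                   candidate_overlap = obs_overlap),
                 thresholds = thr,
                 k_exceed = perm$k_exceed,
                 k_coloc = perm$k_coloc,
                 empirical_p = perm$empirical_p,
                 empirical_p_se = perm$se,
                 empirical_p_coloc = perm$empirical_p_coloc,
                 empirical_p_coloc_se = perm$se_coloc,
                 n_perm_failed = perm$n_failed)
  if (!is.null(od))
    jsonlite::write_json(report, art("report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  structure(report, class = "pipeline_report")
}
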