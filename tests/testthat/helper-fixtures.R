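# shared small fixtures, built once per test run

tiny_cfg <- function(n = 300, m = 400, seed = 7, ...) {
  sim_config(n_individuals = n, n_snps = m, chrom_length_bp = 5e6,
             block_size = 10, within_block_rho = 0.6,
             n_causal = max(2, min(50, m %/% 4)),
             seed = seed, ...)
}

# two-timepoint config for scan/permutation tests
two_age_cfg <- function(n = 300, m = 200, h2 = c(0, 0), seed = 11, ...) {
  sim_config(n_individuals = n, n_snps = m, chrom_length_bp = 5e6,
             block_size = 10, within_block_rho = 0.5,
             timepoints = c(8, 17), h2_by_timepoint = h2,
             rg_matrix = diag(2), re_matrix = diag(2),
             n_causal = max(2, min(20, m %/% 4)), seed = seed, ...)
}

# hand-built genotype matrix from a dosage matrix (bp = 1e4 * column)
toy_genotypes <- function(dos, chrom = "1", impute_r2 = 1,
                          bp = NULL) {
  m <- ncol(dos)
  if (is.null(bp)) bp <- 1e4 * seq_len(m)
  ids <- sprintf("s%03d", seq_len(nrow(dos)))
  rownames(dos) <- ids
  snp_id <- sprintf("t%03d", seq_len(m))
  colnames(dos) <- snp_id
  new_genotype_matrix(dos,
                      data.frame(snp_id = snp_id, chrom = chrom,
                                 bp = bp, ea = "A", oa = "B",
                                 impute_r2 = rep_len(impute_r2, m),
                                 stringsAsFactors = FALSE),
                      ids)
}

.fixture_env <- new.env(parent = emptyenv())

# moderately sized genotype panel + GRM shared across REML tests
reml_fixture <- function() {
  if (is.null(.fixture_env$reml)) {
    cfg <- sim_config(n_individuals = 800, n_snps = 1500,
                      chrom_length_bp = 2e7, block_size = 10,
                      within_block_rho = 0.5, seed = 42)
    G <- simulate_genotypes(cfg)
    .fixture_env$reml <- list(cfg = cfg, G = G, A = compute_grm(G))
  }
  .fixture_env$reml
}

# independent brute-force re-execution of the greedy index-selection
# definition, from a precomputed r2 matrix (no shared code with
# select_index_snps)
brute_force_index <- function(p, bp, R2, window_bp) {
  m <- length(p)
  ids <- names(p)
  assigned <- rep(NA_character_, m)
  indices <- character(0)
  repeat {
    un <- which(is.na(assigned) & is.finite(p))
    if (!length(un)) break
    ord <- un[order(p[un], bp[un], ids[un])]
    k <- ord[1]
    indices <- c(indices, ids[k])
    assigned[k] <- ids[k]
    for (q in which(is.na(assigned))) {
      if (abs(bp[q] - bp[k]) <= window_bp && R2[k, q] > 0.3)
        assigned[q] <- ids[k]
    }
  }
  list(indices = indices, assigned = stats::setNames(assigned, ids))
}
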