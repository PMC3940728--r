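test_that("gamma-frailty counts approach the Poisson limit as theta grows", {
  # moment oracle: with no latent variance and theta -> Inf the scores
  # are plain Poisson, so var/mean -> 1
  cfg <- sim_config(n_individuals = 1e5, n_snps = 10,
                    chrom_length_bp = 1e5, block_size = 5,
                    timepoints = 8, h2_by_timepoint = 0,
                    rg_matrix = matrix(1), re_matrix = matrix(1),
                    n_causal = 2, latent_sd = 0,
                    baseline_log_mean = log(2),
                    covar_effects = c(age = 0, sex = 0, pc1 = 0,
                                      pc2 = 0),
                    dispersion_theta = 1e8, seed = 3)
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  y <- panel$score_8
  expect_equal(var(y) / mean(y), 1, tolerance = 0.02)

  # and at theta = 2 the same config is clearly overdispersed
  cfg$dispersion_theta <- 2
  y2 <- simulate_phenotype_panel(G, cfg)$score_8
  expect_gt(var(y2) / mean(y2), 1.3)
})

test_that("default panel matches the target score distribution at n = 5000", {
  # bounded-instrument emulation: clipping on, as in the target
  # score description the defaults are tuned to
  cfg <- sim_config(n_individuals = 5000, n_snps = 2000,
                    chrom_length_bp = 2e7, n_causal = 300,
                    clip_to_range = TRUE, seed = 4)
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  tps <- panel_timepoints(panel)
  for (tp in tps) {
    y <- panel[[paste0("score_", tp)]]
    expect_gte(sd(y), 3.0)
    expect_lte(sd(y), 4.5)
    expect_true(median(y) %in% 1:2)
  }
  for (k in seq_len(length(tps) - 1)) {
    rho <- cor(panel[[paste0("score_", tps[k])]],
               panel[[paste0("score_", tps[k + 1])]],
               method = "spearman")
    expect_gte(rho, 0.3)
    expect_lte(rho, 0.7)
  }
})

test_that("clipping bounds scores at 24 and is off by default", {
  cfg <- tiny_cfg(n = 2000, m = 50, latent_sd = 1.5,
                  baseline_log_mean = log(4))
  G <- simulate_genotypes(cfg)
  p1 <- simulate_phenotype_panel(G, cfg)
  expect_gt(max(p1$score_8), 24)
  cfg$clip_to_range <- TRUE
  p2 <- simulate_phenotype_panel(G, cfg)
  expect_lte(max(p2$score_8), 24)
  expect_true(all(p2$score_8 >= 0))
})

test_that("panel generation is deterministic and records the truth", {
  cfg <- tiny_cfg(n = 100, m = 80)
  G <- simulate_genotypes(cfg)
  p1 <- simulate_phenotype_panel(G, cfg)
  p2 <- simulate_phenotype_panel(G, cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  tr <- attr(p1, "truth")
  expect_length(tr$causal_ids, cfg$n_causal)
  expect_equal(dim(tr$genetic_values), c(100, 4))
})

test_that("liability simulation realizes the variance components exactly", {
  cfg <- tiny_cfg(n = 500, m = 400)
  G <- simulate_genotypes(cfg)
  rg <- matrix(c(1, 0.6, 0.6, 1), 2)
  y <- simulate_liabilities(G, c(0.3, 0.5), rg_matrix = rg,
                            n_causal = 100, seed = 9)
  g <- attr(y, "genetic_values")
  expect_equal(apply(g, 2, sd), sqrt(c(0.3, 0.5)), tolerance = 1e-10)
  expect_equal(cor(g[, 1], g[, 2]), 0.6, tolerance = 0.15)
})

test_that("gene annotation flags, coverage and determinism behave", {
  cfg <- tiny_cfg()
  all_flagged <- simulate_gene_annotation(cfg, n_genes = 30,
                                          candidate_fraction = 1)
  expect_true(all(all_flagged$is_candidate))

  gs <- simulate_gene_annotation(cfg, n_genes = 400,
                                 candidate_fraction = 0.02)
  expect_identical(sum(gs$is_candidate), 8L)
  expect_true(all(gs$start < gs$end))

  # coverage oracle: union of generated intervals vs Poisson-coverage
  # closed form 1 - exp(-n * len / L)
  cfg2 <- sim_config(n_individuals = 10, n_snps = 10, n_causal = 5,
                     chrom_length_bp = 5e7, seed = 21)
  gs2 <- simulate_gene_annotation(cfg2, n_genes = 2000,
                                  candidate_fraction = 0.1,
                                  mean_len_bp = 50000)
  o <- gs2[order(gs2$start), ]
  cov_bp <- 0; cur_s <- o$start[1]; cur_e <- o$end[1]
  for (i in seq_len(nrow(o))[-1]) {
    if (o$start[i] <= cur_e) cur_e <- max(cur_e, o$end[i])
    else { cov_bp <- cov_bp + cur_e - cur_s
           cur_s <- o$start[i]; cur_e <- o$end[i] }
  }
  cov_bp <- cov_bp + cur_e - cur_s
  expected <- 1 - exp(-2000 * 50000 / 5e7)
  expect_equal(cov_bp / 5e7, expected, tolerance = 0.05)

  expect_identical(simulate_gene_annotation(cfg, 50, 0.1),
                   simulate_gene_annotation(cfg, 50, 0.1))
  expect_error(simulate_gene_annotation(
    sim_config(chrom_length_bp = 5000, n_snps = 100, n_causal = 10,
               seed = 1),
    n_genes = 50, candidate_fraction = 0.5, mean_len_bp = 1e6),
    "longer than chromosome")
})
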