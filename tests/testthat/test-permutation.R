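test_that("joint permutation preserves per-age multisets and cross-age structure", {
  cfg <- two_age_cfg(n = 200, m = 40, h2 = c(0.3, 0.3), seed = 40)
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  pp <- permute_panel(panel, seed = 99)
  for (a in c(8, 17)) {
    expect_identical(sort(pp[[paste0("score_", a)]]),
                     sort(panel[[paste0("score_", a)]]))
  }
  expect_equal(cor(pp$score_8, pp$score_17, method = "spearman"),
               cor(panel$score_8, panel$score_17, method = "spearman"),
               tolerance = 1e-12)
  # genotype-linked covariates stay in place
  expect_identical(pp$sex, panel$sex)
  expect_identical(pp$pc1, panel$pc1)
  # in joint mode ages travel with the scores
  expect_false(identical(pp$age_8, panel$age_8))
  pp2 <- permute_panel(panel, seed = 99, mode = "scores_only")
  expect_identical(pp2$age_8, panel$age_8)
})

test_that("permutation destroys a true genotype-phenotype association", {
  cfg <- two_age_cfg(n = 500, m = 10, seed = 41)
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  dos <- G$dosages[, 5]
  set.seed(42)
  panel$score_17 <- as.integer(rpois(500, exp(0.3 + 0.5 * dos)))
  Xc <- cbind(1, panel$age_17, panel$sex, panel$pc1, panel$pc2, dos)
  obs <- fit_quasi_poisson(panel$score_17, Xc)$beta[6]
  expect_gt(obs, 0.3)
  betas <- vapply(1:200, function(s) {
    pp <- permute_panel(panel, seed = s)
    X <- cbind(1, pp$age_17, pp$sex, pp$pc1, pp$pc2, dos)
    fit_quasi_poisson(pp$score_17, X)$beta[6]
  }, numeric(1))
  expect_lt(abs(mean(betas)), 2 * sd(betas) / sqrt(200))
})

test_that("binomial SE closed form reproduces known values", {
  expect_equal(signif(binomial_se(0.011, 1000), 2), 0.0033)
  expect_equal(signif(binomial_se(0.085, 1000), 2), 0.0088)
  expect_equal(binomial_se(0, 500), 0)
  expect_equal(binomial_se(1, 500), 0)
  expect_equal(binomial_se(0.5, 100), 0.05)
})

perm_fixture <- function() {
  if (is.null(.fixture_env$perm)) {
    cfg <- two_age_cfg(n = 250, m = 60, seed = 43)
    G <- simulate_genotypes(cfg)
    panel <- simulate_phenotype_panel(G, cfg)
    genes <- simulate_gene_annotation(cfg, n_genes = 40,
                                      candidate_fraction = 0.25,
                                      mean_len_bp = 80000)
    tab <- genomic_control(gwas_scan(G, panel, 17))$table
    iset <- select_index_snps(tab, G)
    Gi <- subset_snps(G, iset$index$snp_id)
    regions <- lapply(iset$index$snp_id, clump_region, G = G)
    names(regions) <- iset$index$snp_id
    .fixture_env$perm <- list(cfg = cfg, G = G, Gi = Gi, panel = panel,
                              genes = genes, regions = regions)
  }
  .fixture_env$perm
}

test_that("vacuous and certain thresholds give the expected counts", {
  fx <- perm_fixture()
  spec <- permutation_spec(S = 8, thresholds = c(0.999, 1e-12),
                           timepoints = c(8, 17), seed = 7)
  res <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                              fx$genes)
  # near-vacuous threshold: every permutation exceeds
  expect_identical(unname(res$k_exceed[1]), 8)
  expect_equal(res$empirical_p[1], 1)
  # absurd threshold: none do
  expect_identical(unname(res$k_exceed[2]), 0)
  expect_identical(unname(res$k_coloc[2]), 0)
  # subset event, both thresholds
  expect_true(all(res$k_coloc <= res$k_exceed))
  # empirical p monotone in threshold
  expect_true(all(diff(res$empirical_p[order(res$thresholds)]) >= 0))
})

test_that("wall-to-wall candidate genes make co-location certain", {
  fx <- perm_fixture()
  tiling <- data.frame(chrom = "1", start = 0,
                       end = fx$cfg$chrom_length_bp,
                       name = "everything", is_candidate = TRUE)
  class(tiling) <- c("gene_set", "data.frame")
  spec <- permutation_spec(S = 6, thresholds = 0.9,
                           timepoints = c(8, 17), seed = 8)
  res <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                              tiling)
  expect_identical(res$k_coloc, res$k_exceed)
})

test_that("chunked and single permutation runs agree exactly", {
  fx <- perm_fixture()
  spec <- permutation_spec(S = 12, thresholds = c(0.05, 0.5),
                           timepoints = c(8, 17), seed = 9)
  full <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                               fx$genes)
  c1 <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                             fx$genes, perm_range = c(1L, 5L))
  c2 <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                             fx$genes, perm_range = c(6L, 12L))
  comb <- combine_permutation_results(c1, c2)
  expect_identical(comb$k_exceed, full$k_exceed)
  expect_identical(comb$k_coloc, full$k_coloc)
  expect_equal(comb$minima, full$minima)
})

test_that("permutation result JSON serializes the counts it reports", {
  fx <- perm_fixture()
  spec <- permutation_spec(S = 4, thresholds = 0.5,
                           timepoints = c(17), seed = 10)
  res <- run_permutation_null(fx$Gi, fx$panel, spec, fx$regions,
                              fx$genes)
  jp <- file.path(tempdir(), "perm.json")
  mp <- file.path(tempdir(), "minima.tsv")
  write_permutation_json(res, jp, mp)
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$k_exceed, unname(res$k_exceed))
  expect_equal(back$S, 4)
  minima <- read.delim(mp)
  expect_equal(nrow(minima), 4)
  expect_equal(minima$min_p_gc, unname(res$minima))
})
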