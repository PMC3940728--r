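test_that("pairwise r2 matches hand calculation and its invariances", {
  dos <- cbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 2, 1, 2))
  G <- toy_genotypes(dos)
  expect_equal(pairwise_r2(G, 1, 1), 1)
  # allele flip invariance
  G2 <- toy_genotypes(cbind(dos[, 1], 2 - dos[, 1]))
  expect_equal(pairwise_r2(G2, 1, 2), 1)
  # hand oracle: squared Pearson correlation of the two vectors
  expect_equal(pairwise_r2(G, 1, 2), cor(dos[, 1], dos[, 2])^2,
               tolerance = 1e-12)
  Gm <- toy_genotypes(cbind(rep(1, 6), dos[, 1]))
  expect_error(pairwise_r2(Gm, 1, 2), "monomorphic")
})

test_that("greedy index selection follows the worked 3-SNP example", {
  # p = (0.01, 0.001, 0.5); r2(1,2) ~ 0.5, r2(2,3) ~ 0.1, all in window.
  # greedy: SNP2 first (assigns SNP1), then SNP3 -> indices {2, 3}
  set.seed(30)
  n <- 2000
  d2 <- rbinom(n, 2, 0.4)
  # SNP1: strong LD with SNP2 (keep most entries, resample the rest)
  d1 <- d2
  sw <- runif(n) < 0.3
  d1[sw] <- rbinom(sum(sw), 2, 0.4)
  # SNP3: weak LD with SNP2 (mostly independent)
  d3 <- rbinom(n, 2, 0.3)
  kp <- runif(n) < 0.2
  d3[kp] <- pmin(d2[kp], 2)
  G <- toy_genotypes(cbind(d1, d2, d3))
  stopifnot(pairwise_r2(G, 1, 2) > 0.3, pairwise_r2(G, 2, 3) < 0.3)
  tab <- data.frame(snp_id = G$snp_map$snp_id, chrom = "1",
                    bp = G$snp_map$bp, p = c(0.01, 0.001, 0.5))
  iset <- select_index_snps(tab, G, window_kb = 500, r2_max = 0.3)
  expect_identical(iset$index$snp_id, c("t002", "t003"))
  expect_identical(unname(iset$assignment[["t001"]]), "t002")
})

test_that("greedy selection equals brute-force re-execution on random instances", {
  set.seed(31)
  for (rep in 1:200) {
    m <- 20
    n <- 60
    # block-ish dosages so some pairs exceed the r2 threshold
    base <- matrix(rbinom(n * 5, 2, runif(5, 0.2, 0.5)), n, 5)
    dos <- base[, sample(5, m, replace = TRUE)]
    flip <- runif(m) < 0.3
    noise <- matrix(rbinom(n * m, 1, 0.15) * sample(c(-1, 1), n * m,
                                                    TRUE), n, m)
    dos <- pmin(pmax(dos + noise, 0), 2)
    dos[, flip] <- 2 - dos[, flip]
    keep <- apply(dos, 2, var) > 0
    dos <- dos[, keep, drop = FALSE]
    m <- ncol(dos)
    bp <- sort(sample.int(2e6, m))
    G <- toy_genotypes(dos, bp = bp)
    p <- setNames(round(runif(m), 3), G$snp_map$snp_id)  # ties likely
    tab <- data.frame(snp_id = G$snp_map$snp_id, chrom = "1",
                      bp = bp, p = unname(p))
    iset <- select_index_snps(tab, G, window_kb = 500, r2_max = 0.3)
    R2 <- suppressWarnings(cor(dos)^2)
    oracle <- brute_force_index(p, bp, R2, 5e5)
    expect_identical(sort(iset$index$snp_id), sort(oracle$indices))
    expect_identical(iset$assignment, oracle$assigned)
  }
})

test_that("index selection partitions the panel and is order invariant", {
  cfg <- tiny_cfg(n = 300, m = 80, seed = 33)
  G <- simulate_genotypes(cfg)
  set.seed(34)
  tab <- data.frame(snp_id = G$snp_map$snp_id, chrom = "1",
                    bp = G$snp_map$bp, p = runif(80))
  iset <- select_index_snps(tab, G)
  expect_true(all(!is.na(iset$assignment)))
  expect_true(all(iset$assignment %in% iset$index$snp_id))
  expect_true(all(iset$index$snp_id %in% tab$snp_id))
  # shuffled input rows give the same result
  perm <- sample(nrow(tab))
  iset2 <- select_index_snps(tab[perm, ], G)
  expect_identical(iset2$index, iset$index)
  expect_identical(iset2$assignment[names(iset$assignment)],
                   iset$assignment)
  # index count is non-increasing in the r2 threshold
  n_looser <- nrow(select_index_snps(tab, G, r2_max = 0.1)$index)
  expect_lte(n_looser, nrow(iset$index))
})

test_that("clumped regions match an exhaustive threshold check", {
  cfg <- tiny_cfg(n = 400, m = 60, seed = 35)
  G <- simulate_genotypes(cfg)
  idx <- G$snp_map$snp_id[25]
  r <- clump_region(idx, G, window_kb = 500, r2_min = 0.3)
  expect_true(idx %in% r$members)
  expect_lte(r$start_bp, G$snp_map$bp[25])
  expect_gte(r$end_bp, G$snp_map$bp[25])
  # oracle: apply the pairwise rule exhaustively
  in_win <- abs(G$snp_map$bp - G$snp_map$bp[25]) <= 5e5
  memb_oracle <- G$snp_map$snp_id[vapply(seq_len(60), function(j) {
    if (!in_win[j]) return(FALSE)
    if (j == 25) return(TRUE)
    pairwise_r2(G, 25, j) > 0.3
  }, logical(1))]
  expect_identical(sort(r$members), sort(memb_oracle))

  # isolated SNP degenerates to a single-point span
  dos <- cbind(rbinom(50, 2, 0.3), rbinom(50, 2, 0.4))
  Gi <- toy_genotypes(dos, bp = c(100, 2e6))
  ri <- clump_region("t001", Gi, window_kb = 500, r2_min = 0.3)
  expect_identical(ri$members, "t001")
  expect_equal(ri$start_bp, ri$end_bp)
})

test_that("region-gene overlap respects half-open boundaries", {
  genes <- data.frame(chrom = "1", start = 100, end = 200,
                      name = "gA", is_candidate = TRUE)
  class(genes) <- c("gene_set", "data.frame")
  reg <- function(s, e) structure(list(index = "x", members = "x",
                                       chrom = "1", start_bp = s,
                                       end_bp = e),
                                  class = "clumped_region")
  expect_true(region_overlaps_genes(reg(150, 160), genes)$overlap)
  # region starting exactly at the gene end (half-open) does not touch
  expect_false(region_overlaps_genes(reg(201, 300), genes)$overlap)
  # 1-based position 200 is the last base of [100, 200)
  expect_true(region_overlaps_genes(reg(200, 300), genes)$overlap)
  # chromosome mismatch
  g2 <- genes; g2$chrom <- "2"
  expect_false(region_overlaps_genes(reg(150, 160), g2)$overlap)
  # candidate_only filters non-flagged genes
  g3 <- genes; g3$is_candidate <- FALSE
  expect_false(region_overlaps_genes(reg(150, 160), g3,
                                     candidate_only = TRUE)$overlap)
})

test_that("random region-gene overlap rates match a direct oracle", {
  set.seed(36)
  genes <- data.frame(chrom = "1",
                      start = sort(sample.int(1e6, 50)))
  genes$end <- genes$start + sample(500:5000, 50, TRUE)
  genes$name <- paste0("g", 1:50)
  genes$is_candidate <- TRUE
  class(genes) <- c("gene_set", "data.frame")
  hits <- 0; oracle_hits <- 0
  for (i in 1:100) {
    s <- sample.int(1e6, 1); e <- s + sample(100:20000, 1)
    r <- structure(list(index = "x", members = "x", chrom = "1",
                        start_bp = s, end_bp = e),
                   class = "clumped_region")
    hits <- hits + region_overlaps_genes(r, genes)$overlap
    # direct interval intersection on half-open coordinates
    oracle_hits <- oracle_hits +
      any(pmax(genes$start, s - 1) < pmin(genes$end, e))
  }
  expect_identical(hits, oracle_hits)
})
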