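#' Simulate a longitudinal overdispersed count phenotype panel
#'
#' Builds per-age integer scores on top of a simulated genotype panel. A
#' set of `n_causal` SNPs (shared across ages) receives normal effects
#' whose cross-age correlation is `rg_matrix` (imposed through a matrix
#' square root); per-age genetic values are rescaled so that on the latent
#' log scale var(g_t) / (var(g_t) + var(e_t)) equals
#' `h2_by_timepoint[t]`, with total latent variance `latent_sd^2`.
#' Residual liabilities are multivariate normal with correlation
#' `re_matrix`. Scores are Poisson draws with mean
#' `exp(baseline_log_mean + covariates + g + e)` multiplied by a gamma
#' frailty with shape = rate = `dispersion_theta`, i.e. marginally
#' negative binomial with size `dispersion_theta`. With `clip_to_range`
#' scores are truncated at 24.
#'
#' @param G A `genotype_matrix` from [simulate_genotypes()].
#' @param cfg The same [sim_config()] used for `G`.
#' @param missing_rate Per individual-age probability of a missing score
#'   (default 0).
#' @return A `phenotype_panel`: data.frame with columns `id`, `sex`
#'   (0 = female, 1 = male), `pc1`, `pc2` and per age `t` the pair
#'   `age_<t>`, `score_<t>`; attribute `timepoints` gives the ages and
#'   attribute `truth` the causal SNP IDs, per-age effect vectors and
#'   realized genetic values (for simulation studies).
#' @export
simulate_phenotype_panel <- function(G, cfg, missing_rate = 0) {
  stopifnot(inherits(cfg, "sim_config"), inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages)
  Tk <- length(cfg$timepoints)
  set.seed(cfg$seed + 1L)

  # covariates: sex and two ancestry PCs travel with the genotype record
  sex <- stats::rbinom(n, 1, 0.5)
  pc1 <- stats::rnorm(n)
  pc2 <- stats::rnorm(n)

  # causal architecture with cross-age correlation rg
  causal <- sort(sample.int(ncol(G$dosages), cfg$n_causal))
  Xc <- G$dosages[, causal, drop = FALSE]
  p <- colMeans(Xc, na.rm = TRUE) / 2
  Xs <- scale(Xc, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
  Xs[is.na(Xs)] <- 0
  Rg <- corr_sqrt(cfg$rg_matrix)
  B <- (matrix(stats::rnorm(cfg$n_causal * Tk), cfg$n_causal, Tk) %*% Rg) /
    sqrt(cfg$n_causal)
  g <- Xs %*% B
  # rescale realized per-age genetic variance to h2 * latent_sd^2
  sd_g_target <- sqrt(cfg$h2_by_timepoint) * cfg$latent_sd
  sdg <- apply(g, 2, stats::sd)
  scl <- ifelse(sdg > 0, sd_g_target / sdg, 0)
  g <- sweep(g, 2, scl, `*`)
  B <- sweep(B, 2, scl, `*`)

  # residual liabilities with cross-age correlation re
  Re <- corr_sqrt(cfg$re_matrix)
  e <- matrix(stats::rnorm(n * Tk), n, Tk) %*% Re
  e <- sweep(e, 2, sqrt(1 - cfg$h2_by_timepoint) * cfg$latent_sd, `*`)

  panel <- data.frame(id = G$sample_ids, sex = sex, pc1 = pc1, pc2 = pc2,
                      stringsAsFactors = FALSE)
  ce <- cfg$covar_effects
  for (t in seq_len(Tk)) {
    tp <- cfg$timepoints[t]
    age <- tp + stats::rnorm(n, 0, 0.15)
    eta <- cfg$baseline_log_mean + ce["age"] * age + ce["sex"] * sex +
      ce["pc1"] * pc1 + ce["pc2"] * pc2 + g[, t] + e[, t]
    frailty <- stats::rgamma(n, shape = cfg$dispersion_theta,
                             rate = cfg$dispersion_theta)
    y <- stats::rpois(n, exp(eta) * frailty)
    if (cfg$clip_to_range) y <- pmin(y, 24L)
    if (missing_rate > 0)
      y[stats::runif(n) < missing_rate] <- NA_integer_
    panel[[paste0("age_", tp)]] <- age
    panel[[paste0("score_", tp)]] <- as.integer(y)
  }
  structure(panel,
            timepoints = cfg$timepoints,
            truth = list(causal_ids = G$snp_map$snp_id[causal],
                         effects = B, genetic_values = g),
            class = c("phenotype_panel", "data.frame"))
}

# symmetric PSD square root R with R %*% t(R) = M (eigen-based, tolerates
# singular correlation matrices)
corr_sqrt <- function(M) {
  es <- eigen(M, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  es$vectors %*% (sqrt(ev) * t(es$vectors))
}

#' Simulate Gaussian liabilities with an exact variance-component structure
#'
#' Generates one or more standard-scale Gaussian traits
#' `y_t = g_t + e_t` over a genotype panel, with `var(g_t) = h2[t]`,
#' `var(e_t) = 1 - h2[t]` (realized, not just expected), genetic
#' cross-trait correlation `rg_matrix` and residual correlation
#' `re_matrix`. This is the phenotype on the scale the GREML model
#' assumes and is the generative truth used to validate
#' variance-component recovery; the count panel of
#' [simulate_phenotype_panel()] puts the same structure on the latent
#' log scale, where Poisson and frailty noise attenuate the
#' observed-scale heritability.
#'
#' @param G A `genotype_matrix`.
#' @param h2 Numeric vector of per-trait heritabilities in \[0, 1).
#' @param rg_matrix,re_matrix Cross-trait correlation matrices (default
#'   identity).
#' @param n_causal Number of shared causal SNPs.
#' @param seed Integer seed.
#' @return An n x length(h2) matrix of traits (rownames = sample IDs);
#'   attribute `genetic_values` holds the realized g.
#' @export
simulate_liabilities <- function(G, h2, rg_matrix = NULL,
                                 re_matrix = NULL, n_causal = 500,
                                 seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"),
            all(h2 >= 0 & h2 < 1),
            n_causal >= 1, n_causal <= ncol(G$dosages))
  Tk <- length(h2)
  if (is.null(rg_matrix)) rg_matrix <- diag(Tk)
  if (is.null(re_matrix)) re_matrix <- diag(Tk)
  check_corr_matrix(rg_matrix, Tk, "rg_matrix")
  check_corr_matrix(re_matrix, Tk, "re_matrix")
  n <- nrow(G$dosages)
  set.seed(seed)
  causal <- sort(sample.int(ncol(G$dosages), n_causal))
  Xc <- G$dosages[, causal, drop = FALSE]
  p <- colMeans(Xc, na.rm = TRUE) / 2
  Xs <- scale(Xc, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
  Xs[is.na(Xs)] <- 0
  B <- (matrix(stats::rnorm(n_causal * Tk), n_causal, Tk) %*%
          corr_sqrt(rg_matrix)) / sqrt(n_causal)
  g <- Xs %*% B
  sdg <- apply(g, 2, stats::sd)
  g <- sweep(g, 2, ifelse(sdg > 0, sqrt(h2) / sdg, 0), `*`)
  e <- matrix(stats::rnorm(n * Tk), n, Tk) %*% corr_sqrt(re_matrix)
  sde <- apply(e, 2, stats::sd)
  e <- sweep(e, 2, ifelse(sde > 0, sqrt(1 - h2) / sde, 0), `*`)
  y <- g + e
  rownames(y) <- G$sample_ids
  attr(y, "genetic_values") <- g
  y
}

#' Ages at which a phenotype panel was measured
#' @param panel A `phenotype_panel`.
#' @return Numeric vector of ages.
#' @export
panel_timepoints <- function(panel) attr(panel, "timepoints")

#' Simulate a gene annotation with a flagged candidate subset
#'
#' Genes are placed uniformly on the simulated chromosome with
#' exponentially distributed lengths (mean `mean_len_bp`); a fixed-size
#' subset of `round(candidate_fraction * n_genes)` genes is flagged as
#' candidates, emulating a curated susceptibility-locus list covering a
#' small fraction of all genes.
#'
#' @param cfg A [sim_config()] (supplies chromosome length and seed).
#' @param n_genes Number of genes.
#' @param candidate_fraction Fraction in (0, 1\] of genes to flag.
#' @param mean_len_bp Mean gene length in bp.
#' @return A `gene_set` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `is_candidate`.
#' @export
simulate_gene_annotation <- function(cfg, n_genes = 400,
                                     candidate_fraction = 0.02,
                                     mean_len_bp = 50000) {
  stopifnot(inherits(cfg, "sim_config"),
            n_genes >= 1, candidate_fraction > 0, candidate_fraction <= 1)
  L <- cfg$chrom_length_bp
  set.seed(cfg$seed + 2L)
  len <- pmax(1, round(stats::rexp(n_genes, 1 / mean_len_bp)))
  if (any(len >= L)) stop("gene longer than chromosome")
  start <- floor(stats::runif(n_genes, 0, L - len))
  n_cand <- round(candidate_fraction * n_genes)
  cand <- logical(n_genes)
  cand[sample.int(n_genes, n_cand)] <- TRUE
  gs <- data.frame(chrom = "1", start = start, end = start + len,
                   name = sprintf("gene%04d", seq_len(n_genes)),
                   is_candidate = cand, stringsAsFactors = FALSE)
  gs <- gs[order(gs$start), ]
  rownames(gs) <- NULL
  class(gs) <- c("gene_set", "data.frame")
  gs
}
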