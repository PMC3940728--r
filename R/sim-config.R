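#' Simulation configuration for the synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' genotype panel dimensions and LD structure, the longitudinal count-trait
#' model (per-age SNP heritability, genetic and residual cross-age
#' correlation matrices, negative-binomial overdispersion) and covariate
#' effects.
#'
#' The default values emulate a population cohort screened for
#' social-communication difficulties at ages 8, 11, 14 and 17 years with a
#' bounded 0-24 integer instrument: median score 1-2, SD around 3.5-3.8,
#' per-age SNP heritabilities 0.24/0.16/0.08/0.45, strong adjacent-age
#' genetic correlations (0.82-0.97) decaying to about 0.5 across the full
#' age span, and weaker residual correlations (0.35-0.56).
#'
#' @param n_individuals Number of unrelated individuals.
#' @param n_snps Number of biallelic SNPs on the single simulated
#'   chromosome.
#' @param chrom_length_bp Chromosome length in base pairs; SNP positions
#'   are drawn uniformly without replacement, so it must exceed `n_snps`.
#' @param maf_range Length-2 numeric in (0, 0.5], lower/upper bound of the
#'   uniform distribution MAFs are drawn from.
#' @param block_size SNPs per LD block.
#' @param within_block_rho Latent exchangeable correlation within a block,
#'   in \[0, 1). 0 gives linkage equilibrium.
#' @param maf_per_block If `TRUE`, one MAF is drawn per LD block and
#'   shared by its SNPs (still uniform on `maf_range` marginally). SNPs
#'   in strong real LD necessarily have similar allele frequencies;
#'   with independent per-SNP MAFs (the default) frequency mismatch
#'   caps the attainable dosage r^2 well below `within_block_rho`, so
#'   block-level MAFs are the mode to use when downstream LD pruning
#'   is meant to collapse blocks.
#' @param timepoints Numeric vector of measurement ages (years).
#' @param h2_by_timepoint Per-age latent-scale SNP heritability, each in
#'   \[0, 1); same length as `timepoints`.
#' @param rg_matrix Genetic correlation matrix across ages (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param re_matrix Residual correlation matrix across ages (same
#'   requirements).
#' @param n_causal Number of causal SNPs (sampled without replacement),
#'   at most `n_snps`.
#' @param baseline_log_mean Intercept of the log count mean.
#' @param latent_sd Total SD of the latent genetic-plus-residual term on
#'   the log scale; together with `baseline_log_mean` and
#'   `dispersion_theta` this sets the marginal count mean and variance.
#' @param dispersion_theta Gamma-frailty shape/rate (> 0); the marginal
#'   score distribution is negative binomial with this size. Large values
#'   approach the Poisson limit.
#' @param covar_effects Named numeric vector of log-scale coefficients for
#'   `age` (per year of within-wave age jitter), `sex` (male = 1), `pc1`,
#'   `pc2`.
#' @param clip_to_range If `TRUE`, scores are truncated at 24, emulating a
#'   bounded instrument. Off by default because truncation distorts the
#'   count model the downstream tests assume.
#' @param seed Integer seed; all generator output is deterministic given
#'   the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 2000,
                       n_snps = 5000,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.05, 0.5),
                       block_size = 20,
                       within_block_rho = 0.7,
                       maf_per_block = FALSE,
                       timepoints = c(8, 11, 14, 17),
                       h2_by_timepoint = c(0.24, 0.16, 0.08, 0.45),
                       rg_matrix = default_rg_matrix(),
                       re_matrix = default_re_matrix(),
                       n_causal = 500,
                       baseline_log_mean = -0.45,
                       latent_sd = 1.5,
                       dispersion_theta = 30,
                       covar_effects = c(age = 0, sex = 0.25,
                                         pc1 = 0, pc2 = 0),
                       clip_to_range = FALSE,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1,
            chrom_length_bp >= n_snps,
            length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            block_size >= 1,
            length(timepoints) >= 1,
            length(h2_by_timepoint) == length(timepoints),
            n_causal >= 1, n_causal <= n_snps,
            latent_sd >= 0, dispersion_theta > 0)
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)")
  if (any(h2_by_timepoint < 0 | h2_by_timepoint >= 1))
    stop("h2_by_timepoint values must lie in [0, 1)")
  check_corr_matrix(rg_matrix, length(timepoints), "rg_matrix")
  check_corr_matrix(re_matrix, length(timepoints), "re_matrix")
  req <- c("age", "sex", "pc1", "pc2")
  if (!all(req %in% names(covar_effects)))
    stop("covar_effects must be named with: ", paste(req, collapse = ", "))
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps),
              chrom_length_bp = as.integer(chrom_length_bp),
              maf_range = as.numeric(maf_range),
              block_size = as.integer(block_size),
              within_block_rho = within_block_rho,
              maf_per_block = isTRUE(maf_per_block),
              timepoints = as.numeric(timepoints),
              h2_by_timepoint = as.numeric(h2_by_timepoint),
              rg_matrix = rg_matrix,
              re_matrix = re_matrix,
              n_causal = as.integer(n_causal),
              baseline_log_mean = baseline_log_mean,
              latent_sd = latent_sd,
              dispersion_theta = dispersion_theta,
              covar_effects = covar_effects[req],
              clip_to_range = isTRUE(clip_to_range),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

check_corr_matrix <- function(M, k, name) {
  if (!is.matrix(M) || nrow(M) != k || ncol(M) != k)
    stop(name, " must be a ", k, "x", k, " matrix")
  if (max(abs(M - t(M))) > 1e-10)
    stop(name, " must be symmetric")
  if (max(abs(diag(M) - 1)) > 1e-10)
    stop(name, " must have unit diagonal")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(name, " must be positive semi-definite")
  invisible(TRUE)
}

#' Default cross-age genetic correlation matrix
#'
#' Adjacent ages strongly correlated (0.82-0.97), decaying to ~0.5 across
#' the 8-17 year span.
#' @return 4x4 correlation matrix.
#' @export
default_rg_matrix <- function() {
  M <- rbind(c(1.00, 0.95, 0.75, 0.51),
             c(0.95, 1.00, 0.82, 0.70),
             c(0.75, 0.82, 1.00, 0.90),
             c(0.51, 0.70, 0.90, 1.00))
  dimnames(M) <- NULL
  M
}

#' Default cross-age residual correlation matrix
#'
#' Weaker than the genetic correlations (0.35-0.56), decaying with age
#' separation.
#' @return 4x4 correlation matrix.
#' @export
default_re_matrix <- function() {
  M <- rbind(c(1.00, 0.56, 0.45, 0.35),
             c(0.56, 1.00, 0.56, 0.45),
             c(0.45, 0.56, 1.00, 0.56),
             c(0.35, 0.45, 0.56, 1.00))
  dimnames(M) <- NULL
  M
}
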