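#' Genotype quality-control thresholds
#'
#' Defaults follow standard GWAS practice for chip data: remove SNPs with
#' minor allele frequency below 1%, call rate below 95%, Hardy-Weinberg
#' equilibrium P below 5.0e-7, or imputation quality (R^2) of 0.8 or
#' lower. Thresholds phrased as "<" are strict removals: a SNP exactly at
#' the MAF, call-rate or HWE boundary is retained; the imputation filter
#' requires R^2 strictly greater than the threshold.
#'
#' @param maf_min Minimum minor allele frequency (remove if MAF < this).
#' @param call_rate_min Minimum call rate (remove if below).
#' @param hwe_p_min HWE chi-square p-value floor (remove if below).
#' @param impute_r2_min Imputation R^2 floor (remove if not strictly
#'   above).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 5.0e-7, impute_r2_min = 0.8) {
  th <- list(maf_min = maf_min, call_rate_min = call_rate_min,
             hwe_p_min = hwe_p_min, impute_r2_min = impute_r2_min)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("all thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the expectation under the allele frequency estimated from the
#' same counts. A monomorphic SNP returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return The upper-tail chi-square(1) p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expc <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expc)^2 / expc)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Apply SNP-level quality-control filters
#'
#' Retains exactly the SNPs passing all four criteria (MAF, call rate,
#' HWE, imputation R^2); the filters are a conjunction, so their order
#' does not affect the retained set. For each removed SNP the report
#' gives the first failed criterion in the fixed precedence
#' maf, call_rate, hwe, impute_r2. MAF is computed from non-missing
#' dosages; for the HWE test fractional dosages are rounded to the
#' nearest hard call.
#'
#' @param G A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `genotypes` (filtered `genotype_matrix`) and
#'   `report` (data.frame: snp_id, maf, call_rate, hwe_p, impute_r2,
#'   status, reason).
#' @export
qc_filter <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  dos <- G$dosages
  n <- nrow(dos)
  call_rate <- colMeans(!is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(dos)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    x <- hard[, j]
    hwe_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  r2 <- G$snp_map$impute_r2

  reason <- rep(NA_character_, ncol(dos))
  reason[r2 <= thresholds$impute_r2_min] <- "impute_r2"
  reason[hwe_p < thresholds$hwe_p_min] <- "hwe"
  reason[call_rate < thresholds$call_rate_min] <- "call_rate"
  reason[maf < thresholds$maf_min] <- "maf"
  pass <- is.na(reason)

  report <- data.frame(snp_id = G$snp_map$snp_id, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       impute_r2 = r2,
                       status = ifelse(pass, "pass", "fail"),
                       reason = ifelse(pass, "", reason),
                       stringsAsFactors = FALSE)
  if (!any(pass))
    warning("no SNPs pass QC")
  out <- if (any(pass))
    new_genotype_matrix(dos[, pass, drop = FALSE],
                        G$snp_map[pass, , drop = FALSE], G$sample_ids)
  else NULL
  list(genotypes = out, report = report)
}
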