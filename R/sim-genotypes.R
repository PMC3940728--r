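#' Simulate a genotype dosage panel with block LD
#'
#' Genotypes are generated per LD block from a thresholded latent Gaussian:
#' each haplotype draws a latent vector with exchangeable correlation
#' `within_block_rho` inside the block, each latent coordinate is
#' thresholded at the normal quantile of that SNP's allele frequency to
#' give a 0/1 allele, and the two haplotypes are summed to a dosage in
#' \{0, 1, 2\}. Dosages count the effect allele, whose frequency is the
#' drawn MAF. MAFs are uniform on `maf_range`; positions are uniform
#' without replacement on the chromosome (strictly increasing).
#'
#' @param cfg A [sim_config()] object.
#' @param impute_r2 Per-SNP imputation quality to record in the map;
#'   either a single value (default 1, i.e. directly genotyped) or a
#'   length-`n_snps` vector.
#' @return A `genotype_matrix`: list with `dosages` (n x m integer
#'   matrix, SNP IDs as column names), `snp_map` (data.frame with
#'   `snp_id`, `chrom`, `bp`, `ea`, `oa`, `impute_r2`) and `sample_ids`.
#' @export
simulate_genotypes <- function(cfg, impute_r2 = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  m <- cfg$n_snps
  rho <- cfg$within_block_rho
  set.seed(cfg$seed)

  maf <- if (isTRUE(cfg$maf_per_block)) {
    nb <- ceiling(m / cfg$block_size)
    rep(stats::runif(nb, cfg$maf_range[1], cfg$maf_range[2]),
        each = cfg$block_size)[seq_len(m)]
  } else {
    stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  }
  bp <- sort(sample.int(cfg$chrom_length_bp, m))
  thr <- stats::qnorm(maf)

  dos <- matrix(0L, n, m)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / cfg$block_size))
  for (idx in blocks) {
    k <- length(idx)
    for (hap in 1:2) {
      # exchangeable latent: shared factor + independent noise
      f <- stats::rnorm(n)
      z <- sqrt(rho) * matrix(f, n, k) +
        sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
      al <- z < matrix(thr[idx], n, k, byrow = TRUE)
      dos[, idx] <- dos[, idx] + al
    }
  }
  storage.mode(dos) <- "integer"

  snp_id <- sprintf("snp%06d", seq_len(m))
  colnames(dos) <- snp_id
  sample_ids <- sprintf("ind%05d", seq_len(n))
  rownames(dos) <- sample_ids
  r2 <- rep_len(impute_r2, m)
  stopifnot(all(r2 >= 0 & r2 <= 1))
  map <- data.frame(snp_id = snp_id, chrom = "1", bp = bp,
                    ea = "A", oa = "B", impute_r2 = r2,
                    stringsAsFactors = FALSE)
  new_genotype_matrix(dos, map, sample_ids)
}

#' Construct a genotype_matrix object
#'
#' @param dosages n x m numeric matrix with entries in \[0, 2\] (NA
#'   allowed).
#' @param snp_map data.frame with columns `snp_id`, `chrom`, `bp`, `ea`,
#'   `oa`, `impute_r2`; positions must be strictly increasing within
#'   chromosome.
#' @param sample_ids Character vector of length n.
#' @return A `genotype_matrix`.
#' @export
new_genotype_matrix <- function(dosages, snp_map, sample_ids) {
  stopifnot(is.matrix(dosages),
            ncol(dosages) == nrow(snp_map),
            nrow(dosages) == length(sample_ids))
  need <- c("snp_id", "chrom", "bp", "ea", "oa", "impute_r2")
  stopifnot(all(need %in% names(snp_map)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]")
  for (ch in unique(snp_map$chrom)) {
    b <- snp_map$bp[snp_map$chrom == ch]
    if (any(diff(b) <= 0))
      stop("bp positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosages = dosages, snp_map = snp_map,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$snp_map$chrom), collapse = ",")))
  invisible(x)
}

#' Observed allele frequency of the effect allele per SNP
#'
#' @param G A `genotype_matrix`.
#' @return Numeric vector of length m (mean dosage / 2 over non-missing).
#' @export
allele_freq <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' Restrict a genotype panel to a subset of SNPs
#'
#' @param G A `genotype_matrix`.
#' @param snp_ids Character vector of SNP IDs to keep (order preserved as
#'   in `G`).
#' @return A `genotype_matrix` with the selected SNPs.
#' @export
subset_snps <- function(G, snp_ids) {
  keep <- G$snp_map$snp_id %in% snp_ids
  if (!any(keep)) stop("no matching SNPs")
  new_genotype_matrix(G$dosages[, keep, drop = FALSE],
                      G$snp_map[keep, , drop = FALSE],
                      G$sample_ids)
}
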