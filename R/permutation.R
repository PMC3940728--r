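#' Specification of the permutation null
#'
#' @param S Number of permutations.
#' @param thresholds GC-corrected p-value cut-offs to count exceedances
#'   at, each in (0, 1).
#' @param timepoints Ages scanned in each permutation.
#' @param seed Master seed; per-permutation sub-seeds are derived by a
#'   counter scheme, so results do not depend on chunking.
#' @param candidate_only Count co-location against candidate genes only
#'   (default TRUE).
#' @param gc_correct Re-estimate genomic control within every permuted
#'   scan (default TRUE), keeping the permuted statistics on the same
#'   scale as the GC-corrected thresholds.
#' @param mode `"joint"` permutes each individual's whole phenotype
#'   record (scores and ages at every time-point travel together,
#'   relabeled against the genotype/sex/PC record); `"scores_only"`
#'   permutes the score columns alone.
#' @return A `permutation_spec` list.
#' @export
permutation_spec <- function(S = 1000, thresholds, timepoints,
                             seed = 1L, candidate_only = TRUE,
                             gc_correct = TRUE,
                             mode = c("joint", "scores_only")) {
  stopifnot(S >= 1, all(thresholds > 0 & thresholds < 1),
            length(timepoints) >= 1)
  structure(list(S = as.integer(S), thresholds = as.numeric(thresholds),
                 timepoints = as.numeric(timepoints),
                 seed = as.integer(seed),
                 candidate_only = isTRUE(candidate_only),
                 gc_correct = isTRUE(gc_correct),
                 mode = match.arg(mode)),
            class = "permutation_spec")
}

# counter-mode sub-seed: independent of chunk layout, < 2^31
perm_subseed <- function(master, s) {
  as.integer((as.double(master) * 2654435.0 + s * 97561.0) %%
               2147483647)
}

#' Jointly permute a phenotype panel
#'
#' Applies one random permutation of individual labels simultaneously
#' to all phenotype records: the scores (and, in `"joint"` mode, the
#' ages at measurement) at every time-point travel together, while the
#' genotype-linked record (id, sex, ancestry covariates) stays in
#' place. Per-age score multisets and the within-individual cross-age
#' structure are preserved exactly; only the phenotype-genotype pairing
#' is broken.
#'
#' @param panel A `phenotype_panel`.
#' @param seed Integer seed for the permutation.
#' @param mode `"joint"` (default) or `"scores_only"`.
#' @return A permuted `phenotype_panel`.
#' @export
permute_panel <- function(panel, seed, mode = c("joint", "scores_only")) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(panel)
  idx <- sample.int(n)
  tps <- panel_timepoints(panel)
  cols <- paste0("score_", tps)
  if (mode == "joint") cols <- c(cols, paste0("age_", tps))
  out <- panel
  out[cols] <- panel[idx, cols]
  out
}

#' Binomial standard error of an empirical proportion
#'
#' `sqrt(p_hat * (1 - p_hat) / S)`.
#'
#' @param p_hat Proportion in \[0, 1\].
#' @param S Number of permutations (>= 1).
#' @return The standard error.
#' @export
binomial_se <- function(p_hat, S) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), all(S >= 1))
  sqrt(p_hat * (1 - p_hat) / S)
}

#' Run the jointly-permuted genome-wide null
#'
#' For each permutation: permute the panel, scan the index SNPs at
#' every configured age with quasi-Poisson regression, re-estimate
#' genomic control per scan, and record the minimum GC-corrected
#' p-value over all index SNPs and scans. Per threshold it counts
#' `k_exceed` (permutations where that minimum is at or below the
#' threshold) and `k_coloc` (where additionally the precomputed clumped
#' region of at least one passing SNP overlaps a candidate gene).
#' Empirical p-values are `k / S`; the `(k + 1) / (S + 1)` small-sample
#' versions are reported alongside, as is the co-location probability
#' conditional on exceedance. Execution over a sub-range of permutation
#' indices is supported for chunked runs; the counter-mode sub-seeds
#' make chunked and single runs identical after [combine_permutation_results()].
#'
#' @param G_index A `genotype_matrix` restricted to the observed-data
#'   index SNPs (fixed across permutations).
#' @param panel The observed `phenotype_panel`.
#' @param spec A [permutation_spec()].
#' @param regions Named list of `clumped_region` objects, one per index
#'   SNP (names = SNP IDs), precomputed on the observed data.
#' @param genes A `gene_set`.
#' @param perm_range Integer pair: first and last permutation index to
#'   execute (default the full `1..S`).
#' @return A `permutation_result` list: `spec`, per-threshold counts
#'   and empirical p-values with binomial SEs, `minima` (per-permutation
#'   minimum GC-corrected p), `lambda` (per permutation x age),
#'   `n_failed`, `failed_flag` (TRUE if failures exceed 1% of S).
#' @export
run_permutation_null <- function(G_index, panel, spec, regions, genes,
                                 perm_range = c(1L, spec$S)) {
  stopifnot(inherits(spec, "permutation_spec"))
  miss <- setdiff(G_index$snp_map$snp_id, names(regions))
  if (length(miss))
    stop("regions missing for index SNP(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  perms <- seq.int(perm_range[1], perm_range[2])
  nt <- length(spec$thresholds)
  ages <- spec$timepoints
  minima <- rep(NA_real_, length(perms))
  lambda <- matrix(NA_real_, length(perms), length(ages))
  exceed <- matrix(FALSE, length(perms), nt)
  coloc <- matrix(FALSE, length(perms), nt)
  n_failed <- 0L

  snp_ids <- G_index$snp_map$snp_id
  overlaps <- vapply(snp_ids, function(s)
    region_overlaps_genes(regions[[s]], genes,
                          candidate_only = spec$candidate_only)$overlap,
    logical(1))

  for (ii in seq_along(perms)) {
    s <- perms[ii]
    pp <- permute_panel(panel, perm_subseed(spec$seed, s),
                        mode = spec$mode)
    pmin_all <- rep(NA_real_, length(snp_ids))
    failed <- FALSE
    for (ai in seq_along(ages)) {
      tab <- try(gwas_scan(G_index, pp, ages[ai]), silent = TRUE)
      if (inherits(tab, "try-error")) { failed <- TRUE; break }
      if (spec$gc_correct) {
        gc <- try(genomic_control(tab), silent = TRUE)
        if (inherits(gc, "try-error")) { failed <- TRUE; break }
        lambda[ii, ai] <- gc$lambda
        pv <- gc$table$p_gc
      } else {
        pv <- tab$p
      }
      pmin_all <- pmin(pmin_all, pv, na.rm = TRUE)
    }
    if (failed) { n_failed <- n_failed + 1L; next }
    minima[ii] <- min(pmin_all, na.rm = TRUE)
    for (ti in seq_len(nt)) {
      pass <- !is.na(pmin_all) & pmin_all <= spec$thresholds[ti]
      exceed[ii, ti] <- any(pass)
      coloc[ii, ti] <- any(pass & overlaps)
    }
  }

  k_exceed <- colSums(exceed)
  k_coloc <- colSums(coloc)
  res <- structure(list(
    spec = spec,
    perm_range = perm_range,
    thresholds = spec$thresholds,
    k_exceed = k_exceed,
    k_coloc = k_coloc,
    n_perms = length(perms),
    minima = stats::setNames(minima, perms),
    lambda = lambda,
    n_failed = n_failed), class = "permutation_result")
  finalize_permutation_result(res)
}

finalize_permutation_result <- function(res) {
  S <- res$spec$S
  res$empirical_p <- res$k_exceed / S
  res$empirical_p_coloc <- res$k_coloc / S
  res$se <- binomial_se(res$empirical_p, S)
  res$se_coloc <- binomial_se(res$empirical_p_coloc, S)
  res$empirical_p_corrected <- (res$k_exceed + 1) / (S + 1)
  res$empirical_p_coloc_corrected <- (res$k_coloc + 1) / (S + 1)
  res$p_coloc_conditional <- ifelse(res$k_exceed > 0,
                                    res$k_coloc / res$k_exceed, NA_real_)
  res$failed_flag <- res$n_failed > 0.01 * S
  res
}

#' Combine chunked permutation results
#'
#' Sums the exceedance and co-location counts of results produced by
#' [run_permutation_null()] over disjoint `perm_range`s of the same
#' spec, giving counts identical to a single full run.
#'
#' @param ... `permutation_result` objects.
#' @return A combined `permutation_result`.
#' @export
combine_permutation_results <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  spec <- parts[[1]]$spec
  for (p in parts)
    if (!identical(p$spec$seed, spec$seed) ||
        !identical(p$thresholds, parts[[1]]$thresholds))
      stop("results come from different specs")
  minima <- unlist(lapply(parts, `[[`, "minima"))
  minima <- minima[order(as.integer(names(minima)))]
  res <- structure(list(
    spec = spec,
    perm_range = range(as.integer(names(minima))),
    thresholds = parts[[1]]$thresholds,
    k_exceed = Reduce(`+`, lapply(parts, `[[`, "k_exceed")),
    k_coloc = Reduce(`+`, lapply(parts, `[[`, "k_coloc")),
    n_perms = sum(vapply(parts, `[[`, 0L, "n_perms")),
    minima = minima,
    lambda = do.call(rbind, lapply(parts, `[[`, "lambda")),
    n_failed = sum(vapply(parts, `[[`, 0L, "n_failed"))),
    class = "permutation_result")
  finalize_permutation_result(res)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation null: S = %d (%d run), %d threshold(s)\n",
              x$spec$S, x$n_perms, length(x$thresholds)))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  thr %.3g: k_exceed = %d, p = %.4g (SE %.2g); k_coloc = %d, p = %.4g (SE %.2g)\n",
                x$thresholds[i], x$k_exceed[i], x$empirical_p[i],
                x$se[i], x$k_coloc[i], x$empirical_p_coloc[i],
                x$se_coloc[i]))
  invisible(x)
}

#' Write a permutation result as JSON plus per-permutation minima TSV
#'
#' @param res A `permutation_result`.
#' @param json_path Output JSON (spec echo, counts, empirical p, SEs,
#'   failure count, seed).
#' @param minima_path Optional TSV of per-permutation minimum
#'   GC-corrected p-values.
#' @return `json_path`, invisibly.
#' @export
write_permutation_json <- function(res, json_path, minima_path = NULL) {
  out <- list(S = res$spec$S, seed = res$spec$seed,
              timepoints = res$spec$timepoints,
              mode = res$spec$mode,
              candidate_only = res$spec$candidate_only,
              thresholds = res$thresholds,
              k_exceed = res$k_exceed, k_coloc = res$k_coloc,
              empirical_p = res$empirical_p, se = res$se,
              empirical_p_coloc = res$empirical_p_coloc,
              se_coloc = res$se_coloc,
              empirical_p_corrected = res$empirical_p_corrected,
              p_coloc_conditional = res$p_coloc_conditional,
              n_failed = res$n_failed)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(minima_path))
    utils::write.table(data.frame(perm = names(res$minima),
                                  min_p_gc = res$minima),
                       minima_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(json_path)
}
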