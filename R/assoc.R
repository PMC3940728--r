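#' Quasi-Poisson regression by IRLS
#'
#' Poisson log-link fit by iteratively reweighted least squares with the
#' dispersion estimated afterwards from Pearson residuals:
#' `phi = X^2_Pearson / (n - p)`. Quasi-Poisson standard errors are the
#' Poisson SEs times `sqrt(phi)`, so under overdispersion (phi > 1)
#' inference is widened while the point estimates are the Poisson ML
#' estimates. The Wald statistic `beta / SE` is referenced to the
#' standard normal.
#'
#' @param y Non-negative integer counts.
#' @param X Design matrix including an intercept column.
#' @param max_iter,tol IRLS cap (default 50) and convergence tolerance
#'   on the relative deviance change (default 1e-8).
#' @return A `glm_fit` list: `beta`, `se` (quasi-Poisson), `se_poisson`,
#'   `phi`, `wald`, `p_value` (per coefficient, two-sided normal),
#'   `deviance`, `n_used`, `converged`. With `phi = 0` (a perfect fit)
#'   the SEs are zero and the Wald columns are NA: flagged
#'   non-inferential.
#' @export
fit_quasi_poisson <- function(y, X, max_iter = 50, tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (any(y < 0) || any(y != floor(y)))
    stop("y must contain non-negative integer counts")
  if (all(y == 0)) stop("all counts are zero: no finite intercept")
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- log(mean(y) + 0.5)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    XtW <- crossprod(X, w * X)
    beta <- tryCatch(solve(XtW, crossprod(X, w * z)),
                     error = function(e) {
                       fit <- stats::lm.wfit(X, z, w)
                       bad <- names(fit$coefficients)[
                         is.na(fit$coefficients)]
                       stop("design matrix is collinear; offending ",
                            "column(s): ",
                            paste(if (length(bad)) bad else "<unnamed>",
                                  collapse = ", "), call. = FALSE)
                     })
    beta <- drop(beta)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  phi <- sum((y - mu)^2 / mu) / (n - p)
  if (phi < 1e-12) phi <- 0
  XtWX <- crossprod(X * sqrt(mu))
  vcov_pois <- chol2inv(chol(XtWX))
  se_pois <- sqrt(diag(vcov_pois))
  se <- se_pois * sqrt(phi)
  if (phi > 0) {
    wald <- beta / se
    pv <- 2 * stats::pnorm(-abs(wald))
  } else {
    wald <- rep(NA_real_, p)
    pv <- rep(NA_real_, p)
  }
  names(beta) <- colnames(X)
  structure(list(beta = beta, se = se, se_poisson = se_pois, phi = phi,
                 wald = wald, p_value = pv, deviance = dev,
                 n_used = n, converged = converged),
            class = "glm_fit")
}

#' Genome-wide quasi-Poisson association scan at one age
#'
#' For each SNP, regresses the untransformed integer scores at `age` on
#' age at measurement, sex, the two ancestry covariates and allele
#' dosage (quasi-Poisson, log link); the dosage coefficient is the
#' change in log counts per effect allele. Samples are restricted
#' listwise per age (and per SNP to non-missing dosages). Per-SNP
#' fitting failures are recorded and the scan continues.
#'
#' @param G A `genotype_matrix` (already QC-filtered).
#' @param panel A `phenotype_panel`.
#' @param age One of the panel's timepoints.
#' @return An `assoc_table` data.frame: `snp_id`, `chrom`, `bp`, `ea`,
#'   `oa`, `eaf`, `n`, `beta`, `se`, `phi`, `wald`, `p`; attribute
#'   `age`; rows with failed fits carry NA statistics.
#' @export
gwas_scan <- function(G, panel, age) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(panel, "phenotype_panel"))
  tps <- panel_timepoints(panel)
  if (!(age %in% tps)) stop("age ", age, " not measured in this panel")
  idx <- match(panel$id, G$sample_ids)
  if (anyNA(idx)) stop("panel ids missing from genotype panel")
  sc <- panel[[paste0("score_", age)]]
  av <- panel[[paste0("age_", age)]]
  keep <- !is.na(sc) & !is.na(av) & stats::complete.cases(
    panel[c("sex", "pc1", "pc2")])
  y <- as.numeric(sc[keep])
  Xbase <- cbind(intercept = 1, age = av[keep], sex = panel$sex[keep],
                 pc1 = panel$pc1[keep], pc2 = panel$pc2[keep],
                 dosage = 0)
  rows <- idx[keep]
  m <- ncol(G$dosages)
  eaf <- colMeans(G$dosages[rows, , drop = FALSE], na.rm = TRUE) / 2

  beta <- se <- phi <- wald <- pv <- rep(NA_real_, m)
  nn <- rep(NA_integer_, m)
  dcol <- ncol(Xbase)
  for (j in seq_len(m)) {
    dos <- G$dosages[rows, j]
    okj <- !is.na(dos)
    Xj <- Xbase[okj, , drop = FALSE]
    Xj[, dcol] <- dos[okj]
    fit <- try(fit_quasi_poisson(y[okj], Xj), silent = TRUE)
    if (inherits(fit, "glm_fit") && fit$converged) {
      beta[j] <- fit$beta[dcol]
      se[j] <- fit$se[dcol]
      phi[j] <- fit$phi
      wald[j] <- fit$wald[dcol]
      pv[j] <- fit$p_value[dcol]
      nn[j] <- fit$n_used
    }
  }
  out <- data.frame(snp_id = G$snp_map$snp_id, chrom = G$snp_map$chrom,
                    bp = G$snp_map$bp, ea = G$snp_map$ea,
                    oa = G$snp_map$oa, eaf = eaf, n = nn, beta = beta,
                    se = se, phi = phi, wald = wald, p = pv,
                    stringsAsFactors = FALSE)
  structure(out, age = age, class = c("assoc_table", "data.frame"))
}

#' Genomic-control correction of an association scan
#'
#' `lambda_GC` is the median of the squared Wald statistics divided by
#' the chi-square(1) median (0.4549364). Corrected statistics are
#' `wald^2 / max(lambda, 1)` (by default lambda is floored at 1, i.e.
#' significance is never inflated by a deflated scan) with upper-tail
#' chi-square(1) p-values. The correction divides every statistic by the
#' same constant, so the p-value ordering is unchanged.
#'
#' @param table An `assoc_table` from [gwas_scan()].
#' @param floor_lambda Floor lambda at 1 (default TRUE).
#' @return List with `lambda` (raw), `lambda_used`, and `table`: the
#'   input with a `p_gc` column appended.
#' @export
genomic_control <- function(table, floor_lambda = TRUE) {
  w2 <- table$wald^2
  w2 <- w2[is.finite(w2)]
  if (length(w2) == 0) stop("no valid Wald statistics")
  lambda <- stats::median(w2) / stats::qchisq(0.5, df = 1)
  lambda_used <- if (floor_lambda) max(lambda, 1) else lambda
  p_gc <- stats::pchisq(table$wald^2 / lambda_used, df = 1,
                        lower.tail = FALSE)
  table$p_gc <- p_gc
  list(lambda = lambda, lambda_used = lambda_used, table = table)
}

#' Write an association table as TSV
#'
#' Fixed column order compatible with the clumping input:
#' snp_id, chr, bp, ea, oa, eaf, n, beta, se, phi, wald, p, p_gc.
#'
#' @param table An `assoc_table` (with or without `p_gc`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(table, path) {
  if (is.null(table$p_gc)) table$p_gc <- NA_real_
  out <- table[c("snp_id", "chrom", "bp", "ea", "oa", "eaf", "n",
                 "beta", "se", "phi", "wald", "p", "p_gc")]
  names(out)[2] <- "chr"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
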