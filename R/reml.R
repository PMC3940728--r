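#' @title GREML variance-component estimation
#' @description Average-information REML on a genetic relationship
#'   matrix, exploiting that with a single GRM the covariance
#'   `V = vg * A + ve * I` is diagonal after one eigendecomposition of
#'   A; every iteration then costs O(n). The bivariate model uses the
#'   same rotation, under which V is similar to n independent 2x2
#'   blocks.
#' @name reml
NULL

# align a phenotype vector to the GRM sample order and drop missing pairs
align_pheno <- function(A, y) {
  if (!is.null(names(y))) {
    idx <- match(A$sample_ids, names(y))
    if (anyNA(idx)) stop("phenotype names do not cover GRM sample ids")
    y <- y[idx]
  } else if (length(y) != length(A$sample_ids)) {
    stop("phenotype length does not match GRM dimension")
  }
  y
}

#' Univariate GREML heritability
#'
#' Fits `y = mu + g + e` with `cov(g) = A * vg`, `cov(e) = I * ve` by
#' restricted maximum likelihood (average-information updates, an
#' expectation-maximization first step and EM fallback, step-halving to
#' keep the restricted log-likelihood non-decreasing). The heritability
#' is `h2 = vg / (vg + ve)` with a delta-method SE from the inverse
#' average-information matrix, and the test of `vg = 0` is a likelihood
#' ratio referenced by default to chi-square with 1 df (a
#' `0.5 chi2_0 + 0.5 chi2_1` mixture reference is available, which
#' halves the p-value).
#'
#' @param A A `grm` object.
#' @param y Phenotype vector (typically the output of
#'   [adjust_and_rank_transform()]); optionally named by sample ID; NA
#'   dropped.
#' @param constrain Keep variance components non-negative (default
#'   TRUE).
#' @param lrt_mixture Use the boundary mixture reference for the LRT
#'   p-value (default FALSE: plain chi-square 1 df).
#' @param max_iter,tol Iteration cap and convergence tolerance on both
#'   the log-likelihood change and the component change.
#' @return A `reml_fit` list: `h2`, `se_h2`, `var_g`, `var_e`,
#'   `se_var_g`, `se_var_e`, `loglik`, `loglik0`, `lrt_stat`, `lrt_df`,
#'   `p_value`, `n`, `converged`, `identifiable`, `iterations`,
#'   `trajectory`.
#' @export
reml_univariate <- function(A, y, constrain = TRUE, lrt_mixture = FALSE,
                            max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(A, "grm"))
  y <- align_pheno(A, y)
  ok <- !is.na(y)
  yy <- as.numeric(y[ok])
  Am <- A$values[ok, ok, drop = FALSE]
  n <- length(yy)
  if (n < 10) stop("too few observations for REML")

  es <- if (all(ok) && !is.null(A$eigen)) A$eigen
        else eigen(Am, symmetric = TRUE)
  lam <- es$values
  yt <- drop(crossprod(es$vectors, yy))
  xt <- drop(crossprod(es$vectors, rep(1, n)))

  vp <- stats::var(yy)
  floor_v <- 1e-8 * vp

  # null model (vg = 0) in closed form
  sxx <- sum(xt^2)
  rss <- sum(yt^2) - sum(xt * yt)^2 / sxx
  ve0 <- rss / (n - 1)
  ll0 <- -0.5 * ((n - 1) * log(ve0) + log(sxx) + (n - 1))

  parts <- function(vg, ve) {
    d <- vg * lam + ve
    if (any(d <= 0)) return(NULL)
    xvx <- sum(xt^2 / d)
    beta <- sum(xt * yt / d) / xvx
    Py <- (yt - xt * beta) / d
    yPy <- sum(yt * Py)
    ll <- -0.5 * (sum(log(d)) + log(xvx) + yPy)
    list(d = d, xvx = xvx, Py = Py, ll = ll)
  }
  grad_ai <- function(vg, ve, pp) {
    d <- pp$d; Py <- pp$Py; xvx <- pp$xvx
    trPA <- sum(lam / d) - sum(xt^2 * lam / d^2) / xvx
    trPI <- sum(1 / d) - sum(xt^2 / d^2) / xvx
    yPAPy <- sum(lam * Py^2)
    yPIPy <- sum(Py^2)
    Pw <- function(w) w / d - (xt / d) * (sum(xt * w / d) / xvx)
    wg <- lam * Py; we <- Py
    Pwg <- Pw(wg); Pwe <- Pw(we)
    AI <- 0.5 * rbind(c(sum(wg * Pwg), sum(wg * Pwe)),
                      c(sum(we * Pwg), sum(we * Pwe)))
    score <- -0.5 * c(trPA - yPAPy, trPI - yPIPy)
    list(AI = AI, score = score,
         em = c(vg + vg^2 / n * (yPAPy - trPA),
                ve + ve^2 / n * (yPIPy - trPI)))
  }

  # a GRM with (numerically) no eigenvalue spread cannot separate vg
  # from ve: pin vg at the constraint boundary and flag
  if (max(lam) - min(lam) < 1e-8) {
    return(structure(list(h2 = 0, se_h2 = NA_real_, var_g = 0,
                          var_e = ve0, se_var_g = NA_real_,
                          se_var_e = NA_real_, loglik = ll0,
                          loglik0 = ll0, lrt_stat = 0, lrt_df = 1L,
                          p_value = 1, n = n, converged = TRUE,
                          identifiable = FALSE, iterations = 0,
                          trajectory = NULL), class = "reml_fit"))
  }

  th <- c(vg = vp / 2, ve = vp / 2)
  pp <- parts(th[1], th[2])
  traj <- matrix(NA_real_, max_iter, 3,
                 dimnames = list(NULL, c("vg", "ve", "loglik")))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ga <- grad_ai(th[1], th[2], pp)
    step <- if (it == 1) ga$em - th else {
      s <- try(solve(ga$AI, ga$score), silent = TRUE)
      if (inherits(s, "try-error") || any(!is.finite(s)))
        ga$em - th else s
    }
    new_th <- th + step
    # step-halving: keep V positive definite, components in bounds, and
    # the restricted log-likelihood non-decreasing
    for (h in 1:30) {
      cand <- new_th
      if (constrain) cand <- pmax(cand, floor_v)
      ppc <- parts(cand[1], cand[2])
      if (!is.null(ppc) && is.finite(ppc$ll) && ppc$ll >= pp$ll - 1e-10)
        break
      step <- step / 2
      new_th <- th + step
      ppc <- NULL
    }
    if (is.null(ppc)) { ppc <- pp; cand <- th }
    d_ll <- abs(ppc$ll - pp$ll)
    d_th <- max(abs(cand - th))
    th <- cand; pp <- ppc
    traj[it, ] <- c(th, pp$ll)
    if (d_ll < tol && d_th < tol) { converged <- TRUE; break }
  }
  traj <- traj[!is.na(traj[, 3]), , drop = FALSE]
  if (!converged)
    stop(structure(class = c("reml_no_convergence", "error", "condition"),
                   list(message = paste0("REML did not converge in ",
                                         max_iter, " iterations"),
                        call = sys.call(), trajectory = traj)))

  ga <- grad_ai(th[1], th[2], pp)
  covm <- try(solve(ga$AI), silent = TRUE)
  if (inherits(covm, "try-error")) covm <- matrix(NA_real_, 2, 2)
  vg <- th[[1]]; ve <- th[[2]]
  h2 <- vg / (vg + ve)
  gr <- c(ve, -vg) / (vg + ve)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% covm %*% gr)))
  lrt <- max(0, 2 * (pp$ll - ll0))
  pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (lrt_mixture) pv <- pv / 2
  structure(list(h2 = h2, se_h2 = se_h2, var_g = vg, var_e = ve,
                 se_var_g = sqrt(max(0, covm[1, 1])),
                 se_var_e = sqrt(max(0, covm[2, 2])),
                 loglik = pp$ll, loglik0 = ll0, lrt_stat = lrt,
                 lrt_df = 1L, p_value = pv, n = n, converged = TRUE,
                 identifiable = TRUE, iterations = nrow(traj),
                 trajectory = traj), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("GREML: h2 = %.3f (SE %.3f), LRT = %.2f (df %d), P = %.3g, n = %d\n",
              x$h2, x$se_h2, x$lrt_stat, x$lrt_df, x$p_value, x$n))
  invisible(x)
}

#' Bivariate GREML genetic and residual correlations
#'
#' Fits the two-trait variance-component model on individuals observed
#' for both traits: genetic (co)variances `vg1, vg2, cg` and residual
#' (co)variances `ve1, ve2, ce`, with `rg = cg / sqrt(vg1 vg2)` and
#' `re = ce / sqrt(ve1 ve2)`. Estimation is average-information REML
#' with step-halving (initialized from the univariate fits); if the AI
#' iteration fails to make progress the restricted likelihood is
#' maximized directly by L-BFGS-B and SEs are still taken from the
#' average-information matrix at the optimum (delta method for the
#' correlations). If either trait shows essentially zero genetic
#' variance the genetic correlation is undefined and returned as NA
#' with a warning.
#'
#' @param A A `grm` object.
#' @param y1,y2 Phenotype vectors aligned to the GRM (optionally named);
#'   only individuals non-missing for both traits are used.
#' @param constrain Keep variance components non-negative and
#'   covariances inside the correlation bound (default TRUE).
#' @param max_iter,tol As in [reml_univariate()].
#' @return A `bivar_reml_fit` list: `rg`, `se_rg`, `re`, `se_re`,
#'   `components` (named vector), `se_components`, `loglik`, `n`,
#'   `converged`, `method`.
#' @export
reml_bivariate <- function(A, y1, y2, constrain = TRUE,
                           max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(A, "grm"))
  y1 <- align_pheno(A, y1); y2 <- align_pheno(A, y2)
  ok <- !is.na(y1) & !is.na(y2)
  z1 <- as.numeric(y1[ok]); z2 <- as.numeric(y2[ok])
  Am <- A$values[ok, ok, drop = FALSE]
  n <- length(z1)
  if (n < 10) stop("too few jointly observed individuals")

  es <- if (all(ok) && !is.null(A$eigen)) A$eigen
        else eigen(Am, symmetric = TRUE)
  lam <- es$values
  t1 <- drop(crossprod(es$vectors, z1))
  t2 <- drop(crossprod(es$vectors, z2))
  x <- drop(crossprod(es$vectors, rep(1, n)))

  vp1 <- stats::var(z1); vp2 <- stats::var(z2)
  floor1 <- 1e-8 * vp1; floor2 <- 1e-8 * vp2

  clampth <- function(th) {
    if (!constrain) return(th)
    th[1] <- max(th[1], floor1); th[2] <- max(th[2], floor2)
    th[4] <- max(th[4], floor1); th[5] <- max(th[5], floor2)
    bg <- 0.999 * sqrt(th[1] * th[2])
    be <- 0.999 * sqrt(th[4] * th[5])
    th[3] <- min(max(th[3], -bg), bg)
    th[6] <- min(max(th[6], -be), be)
    th
  }

  # th = (vg1, vg2, cg, ve1, ve2, ce)
  parts <- function(th) {
    a <- th[1] * lam + th[4]
    cc <- th[2] * lam + th[5]
    b <- th[3] * lam + th[6]
    det <- a * cc - b^2
    if (any(a <= 0) || any(cc <= 0) || any(det <= 0)) return(NULL)
    u1 <- (cc * t1 - b * t2) / det
    u2 <- (a * t2 - b * t1) / det
    XtVX <- rbind(c(sum(x^2 * cc / det), -sum(x^2 * b / det)),
                  c(-sum(x^2 * b / det), sum(x^2 * a / det)))
    XtVy <- c(sum(x * u1), sum(x * u2))
    beta <- solve(XtVX, XtVy)
    Py1 <- u1 - x * (cc * beta[1] - b * beta[2]) / det
    Py2 <- u2 - x * (a * beta[2] - b * beta[1]) / det
    yPy <- sum(t1 * Py1 + t2 * Py2)
    dXtVX <- XtVX[1, 1] * XtVX[2, 2] - XtVX[1, 2]^2
    ll <- -0.5 * (sum(log(det)) + log(dXtVX) + yPy)
    list(a = a, cc = cc, b = b, det = det, XtVX = XtVX,
         Py1 = Py1, Py2 = Py2, ll = ll)
  }

  # per-parameter dV blocks as (p11, p12, p22) x multiplier (lam or 1)
  dV <- list(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0),
             c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  mult <- list(lam, lam, lam, 1, 1, 1)

  grad_ai <- function(pp) {
    a <- pp$a; cc <- pp$cc; b <- pp$b; det <- pp$det
    i11 <- cc / det; i12 <- -b / det; i22 <- a / det
    Py1 <- pp$Py1; Py2 <- pp$Py2
    XtVXi <- solve(pp$XtVX)
    w1 <- vector("list", 6); w2 <- vector("list", 6)
    Pw1 <- vector("list", 6); Pw2 <- vector("list", 6)
    score <- numeric(6)
    for (j in 1:6) {
      p11 <- dV[[j]][1] * mult[[j]]
      p12 <- dV[[j]][2] * mult[[j]]
      p22 <- dV[[j]][3] * mult[[j]]
      w1[[j]] <- p11 * Py1 + p12 * Py2
      w2[[j]] <- p12 * Py1 + p22 * Py2
      vw1 <- i11 * w1[[j]] + i12 * w2[[j]]
      vw2 <- i12 * w1[[j]] + i22 * w2[[j]]
      tt <- XtVXi %*% c(sum(x * vw1), sum(x * vw2))
      Pw1[[j]] <- vw1 - x * (cc * tt[1] - b * tt[2]) / det
      Pw2[[j]] <- vw2 - x * (a * tt[2] - b * tt[1]) / det
      trV <- sum(p11 * i11 + 2 * p12 * i12 + p22 * i22)
      # correction tr((X'V-1X)^-1 X'V-1 dV V-1 X)
      q11 <- sum((p11 * i11^2 + 2 * p12 * i11 * i12 + p22 * i12^2) * x^2)
      q12 <- sum((p11 * i11 * i12 + p12 * (i11 * i22 + i12^2) +
                    p22 * i12 * i22) * x^2)
      q22 <- sum((p11 * i12^2 + 2 * p12 * i12 * i22 + p22 * i22^2) * x^2)
      corr <- XtVXi[1, 1] * q11 + 2 * XtVXi[1, 2] * q12 +
        XtVXi[2, 2] * q22
      trP <- trV - corr
      yPdP <- sum(w1[[j]] * Py1 + w2[[j]] * Py2)
      score[j] <- -0.5 * (trP - yPdP)
    }
    AI <- matrix(0, 6, 6)
    for (i in 1:6) for (j in i:6) {
      AI[i, j] <- 0.5 * sum(w1[[i]] * Pw1[[j]] + w2[[i]] * Pw2[[j]])
      AI[j, i] <- AI[i, j]
    }
    list(AI = AI, score = score)
  }

  # initial values from univariate fits and the phenotypic covariance
  Asub <- grm_subset(A, ok)
  if (all(ok)) Asub$eigen <- A$eigen
  f1 <- try(reml_univariate(Asub, z1, constrain = constrain),
            silent = TRUE)
  f2 <- try(reml_univariate(Asub, z2, constrain = constrain),
            silent = TRUE)
  vg1 <- if (inherits(f1, "reml_fit")) max(f1$var_g, floor1) else vp1 / 2
  ve1 <- if (inherits(f1, "reml_fit")) max(f1$var_e, floor1) else vp1 / 2
  vg2 <- if (inherits(f2, "reml_fit")) max(f2$var_g, floor2) else vp2 / 2
  ve2 <- if (inherits(f2, "reml_fit")) max(f2$var_e, floor2) else vp2 / 2
  rp <- stats::cor(z1, z2)
  th <- clampth(c(vg1, vg2, rp * sqrt(vg1 * vg2),
                  ve1, ve2, rp * sqrt(ve1 * ve2)))
  pp <- parts(th)
  if (is.null(pp)) { th <- clampth(c(vp1 / 2, vp2 / 2, 0, vp1 / 2,
                                     vp2 / 2, 0)); pp <- parts(th) }
  converged <- FALSE
  method <- "ai"
  stalls <- 0
  for (it in seq_len(max_iter)) {
    ga <- grad_ai(pp)
    step <- try(solve(ga$AI + diag(1e-10, 6), ga$score), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step)))
      step <- 0.01 * ga$score
    ok_step <- FALSE
    for (h in 1:30) {
      cand <- clampth(th + step)
      ppc <- parts(cand)
      if (!is.null(ppc) && is.finite(ppc$ll) &&
          ppc$ll >= pp$ll - 1e-10) { ok_step <- TRUE; break }
      step <- step / 2
    }
    if (!ok_step) { stalls <- stalls + 1
      if (stalls >= 3) break else next }
    d_ll <- abs(ppc$ll - pp$ll)
    d_th <- max(abs(cand - th))
    th <- cand; pp <- ppc
    if (d_ll < tol && d_th < tol) { converged <- TRUE; break }
  }

  if (!converged) {
    # direct maximization of the restricted likelihood
    method <- "lbfgsb"
    negll <- function(par) {
      p <- parts(clampth(par))
      if (is.null(p) || !is.finite(p$ll)) return(1e10)
      -p$ll
    }
    op <- stats::optim(th, negll, method = "L-BFGS-B",
                       control = list(maxit = 500))
    th <- clampth(op$par)
    pp <- parts(th)
    converged <- op$convergence == 0
  }

  ga <- grad_ai(pp)
  covm <- try(solve(ga$AI), silent = TRUE)
  if (inherits(covm, "try-error")) covm <- matrix(NA_real_, 6, 6)
  names(th) <- c("var_g1", "var_g2", "cov_g12", "var_e1", "var_e2",
                 "cov_e12")
  se_comp <- sqrt(pmax(0, diag(covm)))
  names(se_comp) <- names(th)

  corr_delta <- function(v1, v2, cv, idx) {
    r <- as.numeric(cv) / sqrt(v1 * v2)
    gr <- c(-cv / (2 * v1), -cv / (2 * v2), 1) / sqrt(v1 * v2)
    se <- sqrt(max(0, drop(t(gr) %*% covm[idx, idx] %*% gr)))
    as.numeric(c(r, se))
  }
  # a genetic variance below 1% of the phenotypic variance leaves the
  # genetic correlation essentially unidentified
  tiny_g <- th[1] < 1e-2 * vp1 || th[2] < 1e-2 * vp2
  if (tiny_g) {
    warning("genetic variance of at least one trait is at the boundary; ",
            "genetic correlation is undefined")
    rg <- c(NA_real_, NA_real_)
  } else {
    rg <- corr_delta(th[1], th[2], th[3], 1:3)
    rg[1] <- min(max(rg[1], -1), 1)
  }
  re <- corr_delta(th[4], th[5], th[6], 4:6)
  re[1] <- min(max(re[1], -1), 1)

  structure(list(rg = rg[1], se_rg = rg[2], re = re[1], se_re = re[2],
                 components = th, se_components = se_comp,
                 loglik = pp$ll, n = n, converged = converged,
                 method = method), class = "bivar_reml_fit")
}

#' @export
print.bivar_reml_fit <- function(x, ...) {
  cat(sprintf("bivariate GREML: rg = %.3f (SE %.3f), re = %.3f (SE %.3f), n = %d\n",
              x$rg, x$se_rg, x$re, x$se_re, x$n))
  invisible(x)
}

#' Cache the eigendecomposition of a GRM
#'
#' REML iterations work in the eigenbasis of the GRM; when many traits
#' are analysed against the same relationship matrix (and the same
#' complete set of individuals), decomposing once saves the dominant
#' O(n^3) cost per fit. The cache is used only when no individuals are
#' dropped for missingness.
#'
#' @param A A `grm` object.
#' @return The same `grm` with an `eigen` element attached.
#' @export
grm_precompute <- function(A) {
  stopifnot(inherits(A, "grm"))
  A$eigen <- eigen(A$values, symmetric = TRUE)
  A
}

# subset a grm to a logical/integer index of individuals
grm_subset <- function(A, idx) {
  structure(list(values = A$values[idx, idx, drop = FALSE],
                 n_markers = A$n_markers[idx, idx, drop = FALSE],
                 sample_ids = A$sample_ids[idx]),
            class = "grm")
}
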