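#' Covariate adjustment and rank-based inverse-normal transformation
#'
#' Regresses the phenotype on an intercept plus the supplied covariates
#' by least squares, ranks the residuals (ties get the average rank) and
#' maps them through the normal quantile of the Blom plotting position
#' `(rank - 3/8) / (n + 1/4)`. The result is approximately standard
#' normal whatever the score distribution, which is the form the
#' variance-component heritability model assumes.
#'
#' @param y Numeric phenotype; NA allowed (dropped together with the
#'   matching covariate rows).
#' @param X Covariate matrix or data.frame (no intercept column; one is
#'   added), or NULL for rank-INT of y alone. Must be full rank on the
#'   complete cases.
#' @return Numeric vector of the length of `y` with NA where input was
#'   incomplete; transformed values elsewhere.
#' @export
adjust_and_rank_transform <- function(y, X = NULL) {
  y <- as.numeric(y)
  n_all <- length(y)
  if (is.null(X)) {
    Xm <- matrix(1, n_all, 1)
  } else {
    Xm <- cbind(1, as.matrix(X))
  }
  ok <- stats::complete.cases(cbind(y, Xm))
  yy <- y[ok]; XX <- Xm[ok, , drop = FALSE]
  if (length(yy) < ncol(XX) + 1) stop("too few complete observations")
  if (stats::var(yy) == 0) stop("constant phenotype is untransformable")
  qr_x <- qr(XX)
  if (qr_x$rank < ncol(XX)) stop("covariate matrix is rank deficient")
  res <- qr.resid(qr_x, yy)
  n <- length(res)
  r <- rank(res, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, n_all)
  out[ok] <- z
  out
}
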