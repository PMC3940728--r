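#' Compute a genetic relationship matrix
#'
#' Standard allele-frequency-standardized GRM:
#' `A_jk = (1/m_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample allele frequency of SNP i and `m_jk` the number
#' of SNPs non-missing in both individuals. Monomorphic SNPs are excluded
#' with a warning.
#'
#' @param G A `genotype_matrix`.
#' @return A `grm` object: list with `values` (n x n symmetric),
#'   `n_markers` (n x n per-pair marker counts) and `sample_ids`.
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  p <- colMeans(dos, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | !is.finite(p)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from GRM")
    dos <- dos[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(dos) == 0) stop("no polymorphic SNPs for GRM")
  Z <- sweep(dos, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(Z)
  Z[!obs] <- 0
  A <- tcrossprod(Z)
  Nm <- if (all(obs)) {
    matrix(ncol(dos), nrow(dos), nrow(dos))
  } else {
    tcrossprod(obs * 1)
  }
  A <- A / Nm
  dimnames(A) <- NULL
  dimnames(Nm) <- NULL
  structure(list(values = A, n_markers = Nm, sample_ids = G$sample_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, mean diagonal %.4f\n",
              nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Write a GRM in GCTA binary-compatible layout
#'
#' Writes `prefix.grm.bin` (lower triangle incl. diagonal, row-wise,
#' float32), `prefix.grm.N.bin` (per-pair marker counts, float32) and
#' `prefix.grm.id` (FID/IID TSV).
#'
#' @param grm A `grm` object.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_bin <- function(grm, prefix) {
  n <- nrow(grm$values)
  lt <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$values[lt]), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(grm$n_markers[lt]), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary-compatible files
#'
#' @param prefix Path prefix of `.grm.bin/.grm.N.bin/.grm.id`.
#' @return A `grm` object.
#' @export
read_grm_bin <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  nn <- n * (n + 1) / 2
  v <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nn, size = 4)
  Nv <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nn, size = 4)
  if (length(v) != nn) stop("grm.bin size mismatch")
  A <- matrix(0, n, n); Nm <- matrix(0, n, n)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  A[lt] <- v; Nm[lt] <- Nv
  A <- A + t(A) - diag(diag(A))
  Nm <- Nm + t(Nm) - diag(diag(Nm))
  structure(list(values = A, n_markers = Nm, sample_ids = ids),
            class = "grm")
}
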