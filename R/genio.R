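#' @title Genotype and annotation file input/output
#' @description PLINK bed/bim/fam (v1.0, SNP-major), tab-separated dosage
#'   tables, phenotype tables and BED gene sets. Binary bed genotypes are
#'   hard calls; fractional dosages round-trip through the TSV dialect.
#' @name genio
NULL

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype panel as a PLINK bed/bim/fam triple
#'
#' Dosages are rounded to hard calls \{0, 1, 2\} for the 2-bit encoding;
#' NA becomes the missing code. The effect allele is written as allele 1
#' (A1) in the .bim, so dosage = count of A1.
#'
#' @param G A `genotype_matrix`.
#' @param prefix Path prefix; `prefix.bed/.bim/.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  dos <- round(G$dosages)
  n <- nrow(dos); m <- ncol(dos)
  # two-bit codes, SNP-major: 00 = 2 copies A1, 10 = het, 11 = 0 copies,
  # 01 = missing; 4 samples per byte, LSB first
  code <- matrix(3L, n, m)
  code[dos == 2] <- 0L
  code[dos == 1] <- 2L
  code[is.na(dos)] <- 1L
  bps <- ceiling(n / 4)
  pad <- matrix(0L, bps * 4, m)
  pad[seq_len(n), ] <- code
  b1 <- pad[seq(1, bps * 4, 4), , drop = FALSE]
  b2 <- pad[seq(2, bps * 4, 4), , drop = FALSE]
  b3 <- pad[seq(3, bps * 4, 4), , drop = FALSE]
  b4 <- pad[seq(4, bps * 4, 4), , drop = FALSE]
  bytes <- as.raw(b1 + 4L * b2 + 16L * b3 + 64L * b4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(bytes, con)

  map <- G$snp_map
  bim <- data.frame(chrom = map$chrom, snp_id = map$snp_id, cm = 0,
                    bp = map$bp, a1 = map$ea, a2 = map$oa)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$sample_ids, iid = G$sample_ids,
                    pat = 0, mat = 0, sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triple
#'
#' @param prefix Path prefix of the `.bed/.bim/.fam` triple.
#' @param impute_r2 Imputation quality to record per SNP (bed carries
#'   none); scalar or length-m vector, default 1.
#' @return A `genotype_matrix` with integer hard-call dosages counting
#'   allele 1.
#' @export
read_plink <- function(prefix, impute_r2 = 1) {
  bedf <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing file: ", f)
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bps <- ceiling(n / 4)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3 || !identical(raw[1:3], BED_MAGIC))
    stop("not a PLINK bed v1.0 SNP-major file (bad magic bytes): ", bedf)
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop("bed size mismatch: expected ", bps * m, " data bytes, got ",
         length(body))
  iv <- as.integer(body)
  codes <- rbind(iv %% 4L, (iv %/% 4L) %% 4L,
                 (iv %/% 16L) %% 4L, (iv %/% 64L) %% 4L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  ids <- fam[[2]]
  rownames(dos) <- ids
  colnames(dos) <- bim$snp_id
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, bp = bim$bp,
                    ea = bim$a1, oa = bim$a2,
                    impute_r2 = rep_len(impute_r2, m),
                    stringsAsFactors = FALSE)
  new_genotype_matrix(dos, map, ids)
}

#' Write a genotype panel as a dosage TSV
#'
#' Rows are SNPs (columns `snp_id`, `chrom`, `bp`, `ea`, `oa`,
#' `impute_r2`, then one column per sample); missing dosage is "NA".
#' Fractional dosages are kept to 6 significant digits.
#'
#' @param G A `genotype_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(G, path) {
  d <- t(G$dosages)
  d <- signif(d, 6)
  out <- cbind(G$snp_map[c("snp_id", "chrom", "bp", "ea", "oa",
                           "impute_r2")],
               as.data.frame(d))
  names(out)[-(1:6)] <- G$sample_ids
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#'
#' @param path Input file.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("snp_id", "chrom", "bp", "ea", "oa", "impute_r2")
  if (!all(meta %in% names(tab)))
    stop("dosage TSV must carry columns: ", paste(meta, collapse = ", "))
  ids <- setdiff(names(tab), meta)
  dos <- t(as.matrix(tab[ids]))
  colnames(dos) <- tab$snp_id
  map <- tab[meta]
  map$chrom <- as.character(map$chrom)
  new_genotype_matrix(dos, map, ids)
}

#' Write / read a phenotype panel as TSV
#'
#' Wide format: `id`, `sex`, `pc1`, `pc2`, then `age_<t>`, `score_<t>`
#' per measurement age.
#'
#' @param panel A `phenotype_panel`.
#' @param path File path.
#' @return `path` (write) or a `phenotype_panel` (read).
#' @export
write_phenotype_tsv <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tps <- as.numeric(sub("^score_", "", grep("^score_", names(tab),
                                            value = TRUE)))
  structure(tab, timepoints = tps,
            class = c("phenotype_panel", "data.frame"))
}

#' Write / read a gene set as BED (0-based half-open)
#'
#' Columns: chrom, start, end, name, score (0/1 candidate flag).
#'
#' @param genes A `gene_set` data.frame.
#' @param path File path.
#' @return `path` (write) or a `gene_set` (read).
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$end, name = genes$name,
                    score = as.integer(genes$is_candidate))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("gene BED needs at least 4 columns")
  gs <- data.frame(chrom = as.character(tab[[1]]), start = tab[[2]],
                   end = tab[[3]], name = as.character(tab[[4]]),
                   is_candidate = if (ncol(tab) >= 5) tab[[5]] != 0
                                  else TRUE,
                   stringsAsFactors = FALSE)
  if (any(gs$start >= gs$end)) stop("BED intervals need start < end")
  class(gs) <- c("gene_set", "data.frame")
  gs
}
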