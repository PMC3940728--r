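#' Pairwise LD between two SNPs as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two dosage
#' vectors over their shared non-missing samples. Invariant to allele
#' relabeling (x -> 2 - x).
#'
#' @param G A `genotype_matrix`.
#' @param i,j SNP IDs or column indices.
#' @return r^2 in \[0, 1\].
#' @export
pairwise_r2 <- function(G, i, j) {
  xi <- snp_column(G, i)
  xj <- snp_column(G, j)
  ok <- !is.na(xi) & !is.na(xj)
  if (stats::var(xi[ok]) == 0 || stats::var(xj[ok]) == 0)
    stop("r2 undefined for a monomorphic SNP")
  stats::cor(xi[ok], xj[ok])^2
}

snp_column <- function(G, i) {
  if (is.character(i)) {
    k <- match(i, G$snp_map$snp_id)
    if (is.na(k)) stop("unknown SNP: ", i)
    i <- k
  }
  G$dosages[, i]
}

#' Greedy selection of independent index SNPs
#'
#' PLINK-clump-style pruning: repeatedly take the unassigned SNP with
#' the smallest p-value as the next index (ties broken by smaller
#' genomic coordinate, then SNP ID), and assign to it every unassigned
#' SNP on the same chromosome within `window_kb` whose dosage r^2 with
#' the index exceeds `r2_max`. SNPs without a valid p-value are skipped.
#' The result partitions the panel: every SNP is an index or is
#' assigned to exactly one index.
#'
#' @param table An `assoc_table` (needs `snp_id`, `chrom`, `bp` and a
#'   p-value column).
#' @param G The matching `genotype_matrix`.
#' @param window_kb Physical window half-width in kb (default 500).
#' @param r2_max LD threshold: r^2 strictly greater assigns a SNP to the
#'   index (default 0.3).
#' @param p_col Which p-value column drives the ordering (default
#'   `"p_gc"` if present, else `"p"`).
#' @return An `index_set` list: `index` (data.frame snp_id, chrom, bp,
#'   p, ordered by selection) and `assignment` (named character vector
#'   mapping every SNP to its index).
#' @export
select_index_snps <- function(table, G, window_kb = 500, r2_max = 0.3,
                              p_col = NULL) {
  if (is.null(p_col)) p_col <- if ("p_gc" %in% names(table)) "p_gc" else "p"
  stopifnot(p_col %in% names(table))
  tab <- data.frame(snp_id = table$snp_id, chrom = table$chrom,
                    bp = table$bp, p = table[[p_col]],
                    stringsAsFactors = FALSE)
  gi <- match(tab$snp_id, G$snp_map$snp_id)
  if (anyNA(gi)) stop("association table contains SNPs absent from G")
  valid <- is.finite(tab$p)
  ord <- order(!valid, tab$p, tab$bp, tab$snp_id)
  win <- window_kb * 1000
  m <- nrow(tab)
  assigned <- rep(NA_character_, m)
  names(assigned) <- tab$snp_id
  is_index <- logical(m)
  for (k in ord) {
    if (!is.na(assigned[k])) next
    is_index[k] <- TRUE
    assigned[k] <- tab$snp_id[k]
    near <- which(is.na(assigned) & tab$chrom == tab$chrom[k] &
                    abs(tab$bp - tab$bp[k]) <= win)
    if (length(near)) {
      xk <- G$dosages[, gi[k]]
      for (q in near) {
        r2 <- suppressWarnings(stats::cor(xk, G$dosages[, gi[q]],
                                          use = "complete.obs")^2)
        if (is.finite(r2) && r2 > r2_max) assigned[q] <- tab$snp_id[k]
      }
    }
  }
  idx <- which(is_index)
  idx <- idx[order(tab$p[idx], tab$bp[idx], tab$snp_id[idx])]
  structure(list(index = data.frame(snp_id = tab$snp_id[idx],
                                    chrom = tab$chrom[idx],
                                    bp = tab$bp[idx], p = tab$p[idx],
                                    stringsAsFactors = FALSE),
                 assignment = assigned),
            class = "index_set")
}

#' Clumped LD region around an index SNP
#'
#' Members are the SNPs on the index's chromosome within `window_kb`
#' whose r^2 with the index exceeds `r2_min`, plus the index itself; the
#' span is the 1-based inclusive interval from the smallest to the
#' largest member position.
#'
#' @param index SNP ID of the index variant.
#' @param G A `genotype_matrix`.
#' @param window_kb Window half-width in kb (default 500).
#' @param r2_min LD threshold (default 0.3, strict >).
#' @return A `clumped_region` list: `index`, `members` (SNP IDs),
#'   `chrom`, `start_bp`, `end_bp`.
#' @export
clump_region <- function(index, G, window_kb = 500, r2_min = 0.3) {
  k <- match(index, G$snp_map$snp_id)
  if (is.na(k)) stop("unknown index SNP: ", index)
  ch <- G$snp_map$chrom[k]
  bp <- G$snp_map$bp[k]
  win <- window_kb * 1000
  near <- which(G$snp_map$chrom == ch & abs(G$snp_map$bp - bp) <= win)
  xk <- G$dosages[, k]
  memb <- k
  for (q in setdiff(near, k)) {
    r2 <- suppressWarnings(stats::cor(xk, G$dosages[, q],
                                      use = "complete.obs")^2)
    if (is.finite(r2) && r2 > r2_min) memb <- c(memb, q)
  }
  memb <- sort(memb)
  structure(list(index = index, members = G$snp_map$snp_id[memb],
                 chrom = ch, start_bp = min(G$snp_map$bp[memb]),
                 end_bp = max(G$snp_map$bp[memb])),
            class = "clumped_region")
}

#' Does a clumped region overlap any gene interval?
#'
#' The region span (1-based inclusive) is converted to 0-based
#' half-open (`[start - 1, end)`); genes are 0-based half-open as in
#' BED. Overlap requires at least one shared base:
#' `max(starts) < min(ends)`. A chromosome mismatch yields no overlap.
#'
#' @param region A `clumped_region`.
#' @param genes A `gene_set`.
#' @param candidate_only Restrict to genes flagged `is_candidate`
#'   (default FALSE).
#' @return List with `overlap` (flag) and `genes` (overlapping gene
#'   names).
#' @export
region_overlaps_genes <- function(region, genes, candidate_only = FALSE) {
  gs <- genes
  if (candidate_only) gs <- gs[gs$is_candidate, , drop = FALSE]
  rs <- region$start_bp - 1
  re <- region$end_bp
  hit <- gs$chrom == region$chrom &
    pmax(gs$start, rs) < pmin(gs$end, re)
  list(overlap = any(hit), genes = gs$name[hit])
}

#' Write an index set and its regions as TSV
#'
#' @param index_set An `index_set`.
#' @param regions List of `clumped_region` objects matching the index
#'   order.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index_set, regions, path) {
  stopifnot(length(regions) == nrow(index_set$index))
  out <- data.frame(index_snp = index_set$index$snp_id,
                    chr = index_set$index$chrom,
                    start = vapply(regions, `[[`, 0, "start_bp"),
                    end = vapply(regions, `[[`, 0, "end_bp"),
                    n_members = vapply(regions,
                                       function(r) length(r$members), 0L),
                    min_p = index_set$index$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
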