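#!/usr/bin/env Rscript
# Stage 4: reduce the panel to independent index variants by greedy LD
# clumping (±500 kb, r2 > 0.3) on the most strongly associated scan,
# and build the clumped region around each index SNP. Writes
# results/index_snps.tsv and results/clump_membership.tsv.

source(file.path("analysis", "00_config.R"))

co <- study_cohort()
lam <- read.delim(file.path(res_dir, "lambda_gc.tsv"))
tabs <- lapply(lam$age, function(a)
  read.delim(file.path(res_dir, sprintf("assoc_age%s.tsv", a))))
best <- which.min(sapply(tabs, function(t) min(t$p_gc, na.rm = TRUE)))
tab <- tabs[[best]]
names(tab)[names(tab) == "chr"] <- "chrom"
message("pruning on the age ", lam$age[best], " scan")

iset <- select_index_snps(tab, co$G, window_kb = 500, r2_max = 0.3)
regions <- lapply(iset$index$snp_id, clump_region, G = co$G,
                  window_kb = 500, r2_min = 0.3)
names(regions) <- iset$index$snp_id
message(sprintf("%d SNPs reduced to %d index variants", nrow(tab),
                nrow(iset$index)))
write_index_tsv(iset, regions, file.path(res_dir, "index_snps.tsv"))
write.table(data.frame(snp_id = names(iset$assignment),
                       index_snp = unname(iset$assignment)),
            file.path(res_dir, "clump_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

spans <- sapply(regions, function(r) r$end_bp - r$start_bp + 1)
message(sprintf("clumped region spans: median %.0f kb, max %.0f kb",
                median(spans) / 1000, max(spans) / 1000))
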