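#!/usr/bin/env Rscript
# Stage 3: quasi-Poisson genome-wide scans at the two most heritable
# ages, with genomic-control correction. Writes per-age association
# TSVs and a lambda_GC summary under results/.

source(file.path("analysis", "00_config.R"))

co <- study_cohort()
h2 <- read.delim(file.path(res_dir, "heritability.tsv"))
scan_ages <- sort(h2$age[order(-h2$h2)][1:2])
message("scanning ages with the highest estimated h2: ",
        paste(scan_ages, collapse = ", "))

lam <- sapply(scan_ages, function(a) {
  gc <- genomic_control(gwas_scan(co$G, co$panel, a))
  write_assoc_tsv(gc$table,
                  file.path(res_dir, sprintf("assoc_age%s.tsv", a)))
  top <- gc$table[order(gc$table$p_gc)[1:3], ]
  message(sprintf("age %s: lambda_GC = %.3f; top signals:", a,
                  gc$lambda))
  print(top[c("snp_id", "bp", "beta", "se", "p", "p_gc")], digits = 3)
  gc$lambda
})
write.table(data.frame(age = scan_ages, lambda_gc = lam),
            file.path(res_dir, "lambda_gc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("note: lambda_GC here reflects true polygenic signal, not ",
        "stratification - at this scaled-down panel a tenth of SNPs ",
        "are causal, so the median test statistic is genuinely ",
        "shifted; the null-calibration checks in the test suite show ",
        "lambda within a few percent of 1 when h2 = 0")
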