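#!/usr/bin/env Rscript
# Per-population, per-locus Hardy-Weinberg exact tests with a joint
# Bonferroni family, plus pairwise linkage tests on the pooled sample;
# loci failing in many populations are dropped.
library(jaycline)

gt <- read_genotypes("results/data/genotypes.tsv")
rep <- qc_report(gt, n_permutations = 9999, seed = 20L)
fl <- flag_loci(rep, max_failing_populations = 5)

write.table(rep$hwe, "results/qc_hwe_pvalues.tsv", sep = "\t", quote = FALSE)
write.table(rep$ld, "results/qc_ld_pvalues.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(c(sprintf("bonferroni threshold: %.3g over %d tests",
                     rep$bonferroni_alpha, rep$m),
             sprintf("retained: %s", paste(fl$retained, collapse = ", ")),
             sprintf("dropped: %s", paste(fl$dropped, collapse = ", ")),
             sprintf("borderline: %s", paste(fl$borderline, collapse = ", "))),
           "results/qc_decisions.txt")
cat(sprintf("QC: %d loci retained, %d dropped (threshold %.3g)\n",
            length(fl$retained), length(fl$dropped), rep$bonferroni_alpha))
cat(sprintf("min within-population LD p-value (Fisher-combined): %.3g\n",
            min(rep$ld$p_value, na.rm = TRUE)))
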