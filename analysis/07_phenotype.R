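#!/usr/bin/env Rscript
# Phenotype-ancestry association: correlation-matrix PCA of the
# morphometrics and trait-on-Q regressions at three spatial extents.
library(jaycline)

ph <- read.delim("results/data/phenotypes.tsv")
morpho <- c("wing", "tail", "tarsus", "bill_length", "bill_depth", "bill_width")
pca <- pca_correlation(ph[, morpho])
cat("morphometric PCA, variance explained:",
    paste0(round(100 * pca$explained, 1), "%"), "\n")

tab <- phenotype_assoc_table(ph, traits = c(morpho, "collar", "vent", "eyestripe"))
write.table(tab, "results/phenotype_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
wide <- reshape(as.data.frame(tab[, c("trait", "extent", "r_squared", "stars")]),
                idvar = "trait", timevar = "extent", direction = "wide")
print(wide, digits = 2)
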