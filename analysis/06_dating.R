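#!/usr/bin/env Rscript
# Time since secondary contact under neutral diffusion, from the fitted
# cline widths and sex-specific dispersal: female sigma 1.5-5.0 km for
# mtDNA, male-female average 0.5-3.0 km for the nuclear markers.
library(jaycline)

summary_ln <- readLines("results/cline_summary.txt")
w_mt <- as.numeric(sub(".*width ([0-9.]+) .*", "\\1", summary_ln[1]))
w_nuc <- as.numeric(sub(".*width ([0-9.]+) .*", "\\1", summary_ln[2]))

for (variant in c("formula", "paper_match")) {
  mt <- contact_range(w_mt, dispersal_spec(1.5, 5.0, "female"), variant)
  nuc <- contact_range(w_nuc, dispersal_spec(0.5, 3.0, "average"), variant)
  cat(sprintf("[%s] mtDNA: %s - %s generations; nuclear: %s - %s; overlap: %s\n",
              variant, format(mt$rounded[1], big.mark = ","),
              format(mt$rounded[2], big.mark = ","),
              format(nuc$rounded[1], big.mark = ","),
              format(nuc$rounded[2], big.mark = ","),
              ranges_overlap(mt, nuc)))
}
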