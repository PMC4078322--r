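#!/usr/bin/env Rscript
# In-silico restriction typing: digest every cyt-b amplicon with the BsrDI
# motif and tabulate per-site interior-haplotype frequencies.
library(jaycline)

seqs <- read_fasta("results/data/sequences.fasta")
ind <- read.delim("results/data/individuals.tsv")
calls <- digest_all(seqs)
write.table(calls, "results/mt_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- site_haplotype_counts(calls$call, ind$site[match(calls$id, ind$id)])
sites <- read_sites("results/data/sites.tsv")
mt <- merge(sites[, c("site_id", "distance")], counts, by = "site_id")
mt <- mt[order(mt$distance), ]
write_sites(mt, "results/sites_mt.tsv")

cat(sprintf("%d sequences typed: %d coastal, %d interior, %d ambiguous\n",
            nrow(calls), sum(calls$call == "coastal"),
            sum(calls$call == "interior"), sum(calls$call == "ambiguous")))
print(mt)
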