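#!/usr/bin/env Rscript
# Run the filter cascade on the staged allele counts and compare the
# called SNP set against the simulated truth.

library(gutevolve)
sim_dir <- "results/simulation"
if (!file.exists(file.path(sim_dir, "allele_counts.tsv")))
  stop("run analysis/02_simulate.R first")
dir.create("results", showWarnings = FALSE)

genome <- read_reference(file.path(sim_dir, "reference.fa"),
                         file.path(sim_dir, "genes.tsv"))
acm <- read_allele_counts(file.path(sim_dir, "allele_counts.tsv"))
called <- filter_candidate_sites(acm, genome)

write_snp_table(called$snps, "results/called_snps.tsv", "tsv")
write_snp_table(called$snps, "results/called_snps.vcf", "vcf")
write_genotypes(called$genotypes, "results/genotypes.tsv")
write.table(called$audit, "results/snp_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(sim_dir, "truth_snps.tsv"))
key_called <- paste(called$snps$replicon, called$snps$pos)
key_true <- paste(truth$replicon, truth$pos)
cat(sprintf("Called %d SNPs from %d candidate sites across %d isolates.\n",
            nrow(called$snps), nrow(called$audit),
            nrow(called$genotypes$calls)))
cat(sprintf("Against simulated truth: recall %.3f, precision %.3f.\n",
            mean(key_true %in% key_called), mean(key_called %in% key_true)))
cat(sprintf("Coding effects: %d nonsynonymous, %d synonymous, %d intergenic.\n",
            sum(called$snps$coding_effect == "nonsynonymous"),
            sum(called$snps$coding_effect == "synonymous"),
            sum(called$snps$coding_effect == "intergenic")))
rej <- called$audit$note[!called$audit$retained]
cat("Rejection reasons at discarded sites:\n")
print(table(rej[rej != ""]))
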