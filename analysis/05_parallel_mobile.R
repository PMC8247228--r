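#!/usr/bin/env Rscript
# Gene-level parallel evolution on the called SNPs, cross-host mutation
# frequencies, and mobile-element identification + presence trajectories.

library(gutevolve)
if (!file.exists("results/genotypes.tsv"))
  stop("run analysis/03_call_snps.R first")

geno <- read_genotypes("results/genotypes.tsv")
snps <- read_snp_table("results/called_snps.tsv")
meta_raw <- read.delim("results/simulation/isolates.tsv")
meta <- isolate_metadata(meta_raw$isolate_id, meta_raw$host_species,
                         meta_raw$subject_id, meta_raw$day, meta_raw$group)

pg <- detect_parallel_genes(snps, geno, window = 2000L, metadata = meta)
write.table(pg, "results/parallel_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Parallel genes (>= 2 SNPs within 2 kb, not perfectly
co-occurring): %s.\n",
            paste(pg$gene_id[pg$status == "parallel"], collapse = ", ")))
cat(sprintf("%d single-mutation genes; %d excluded.\n",
            sum(pg$status == "single_mutation"),
            sum(pg$status == "excluded")))

cc <- cross_host_consistency(snps, geno, meta)
write.table(cc, "results/cross_host_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Per-subject carrier fractions of the parallel genes:\n")
print(cc[cc$gene_id %in% pg$gene_id[pg$status == "parallel"], ])

# mobile elements: regenerate the deterministic scenario for the contigs
scfg <- sim_config(seed = 1L)
truth <- simulate_evolution(scfg)
samp <- sample_isolates_and_reads(truth, scfg)
genome <- read_reference("results/simulation/reference.fa",
                         "results/simulation/genes.tsv")
els <- identify_accessory_contigs(samp$contigs, genome)
write.table(els[setdiff(names(els), "sequence")],
            "results/mobile_elements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nAccessory (mobile) elements after core removal and dedup: %d.\n",
            nrow(els)))
tr <- element_trajectory(samp$element_evidence, meta)
write.table(tr, "results/element_trajectories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Presence frequency of each element per host and day:\n")
print(tr[c("element_id", "host_species", "day", "frequency")])
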