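test_that("the generator is deterministic and degenerates correctly", {
  # no plan, no mutation: a single ancestral lineage at frequency 1
  scfg <- sim_config(lineage_plan = NULL, mutation_prob = 0,
                     hosts = c(human = 1L), isolates_per_host_day = 5L)
  truth <- simulate_evolution(scfg)
  expect_equal(nrow(truth$snp_catalog), 0L)
  expect_true(all(truth$freqs[, , "ancestor"] == 1))

  # bitwise-identical truth from the same seed
  t1 <- simulate_evolution(sim_config(seed = 5L))
  t2 <- simulate_evolution(sim_config(seed = 5L))
  expect_identical(t1$snp_catalog, t2$snp_catalog)
  expect_identical(t1$freqs, t2$freqs)
  expect_identical(t1$genome$replicons, t2$genome$replicons)
  s1 <- sample_isolates_and_reads(t1)
  s2 <- sample_isolates_and_reads(t2)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$isolate_lineage, s2$isolate_lineage)
})

test_that("the default scenario carries the designed mutation structure", {
  truth <- default_run()$truth
  cat_tab <- truth$snp_catalog
  expect_equal(nrow(cat_tab), 22L)
  gene_counts <- table(cat_tab$gene_id[!is.na(cat_tab$gene_id)])
  expect_equal(length(gene_counts), 12L)                   # 12 mutated genes
  expect_equal(sum(gene_counts >= 2L), 5L)                 # 5 multi-SNP genes
  expect_equal(sum(is.na(cat_tab$gene_id)), 3L)            # 3 intergenic
  expect_equal(nrow(truth$lineages), 6L)                   # ancestor + 5
  # child SNP sets nest their parents'
  for (lin in setdiff(truth$lineages$lineage_id, "ancestor")) {
    parent <- truth$lineages$parent[truth$lineages$lineage_id == lin]
    if (parent == "ancestor") next
    expect_true(all(gutevolve:::lineage_snps(truth, parent) %in%
                    gutevolve:::lineage_snps(truth, lin)))
  }
  # exclusive frequencies sum to 1 on every subject-day
  sums <- apply(truth$freqs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("neutral lineages drift around their birth frequency", {
  # s = 0: the mean final frequency over replicates equals the initial
  # frequency within Monte-Carlo error (martingale property of drift)
  plan <- data.frame(lineage_id = "L1", parent = "ancestor",
                     birth_day = 0L, init_freq = 0.1, s = 0, n_snps = 1L,
                     stringsAsFactors = FALSE)
  finals <- vapply(1:120, function(seed) {
    scfg <- sim_config(seed = seed, lineage_plan = plan,
                       hosts = c(human = 1L), days = c(3L, 7L, 10L),
                       ne = 500L, n_genes = 5L,
                       replicon_layout = c(chromosome = 9000L))
    truth <- simulate_evolution(scfg)
    truth$freqs[1, "10", "L1"]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.1), 3 * se + 0.005)
})

test_that("selected lineages outgrow neutral expectation", {
  plan <- data.frame(lineage_id = "L1", parent = "ancestor",
                     birth_day = 0L, init_freq = 0.05, s = 0.25,
                     n_snps = 1L, stringsAsFactors = FALSE)
  scfg <- sim_config(seed = 11L, lineage_plan = plan,
                     hosts = c(human = 1L), ne = 2000L, n_genes = 5L,
                     replicon_layout = c(chromosome = 9000L))
  truth <- simulate_evolution(scfg)
  expect_gt(truth$freqs[1, "28", "L1"], 0.5)
})

test_that("stochastic births add exactly one SNP per event", {
  scfg <- sim_config(seed = 13L, lineage_plan = NULL, mutation_prob = 0.15,
                     hosts = c(human = 1L), n_genes = 10L,
                     replicon_layout = c(chromosome = 15000L))
  truth <- simulate_evolution(scfg)
  born <- setdiff(truth$lineages$lineage_id, "ancestor")
  expect_gt(length(born), 0L)
  per_lineage <- table(truth$snp_catalog$lineage_id)
  expect_true(all(per_lineage == 1L))
  # every stochastic lineage's parent precedes it
  for (lin in born) {
    row <- truth$lineages[truth$lineages$lineage_id == lin, ]
    parent_row <- truth$lineages[truth$lineages$lineage_id == row$parent, ]
    expect_lte(parent_row$birth_day, row$birth_day)
  }
})

test_that("error-free deep sequencing reproduces true genotypes exactly", {
  scfg <- sim_config(seed = 17L, error_rate = 0, mean_depth = 100,
                     depth_dispersion = 1e6,
                     hosts = c(human = 1L), isolates_per_host_day = 6L,
                     n_background_sites = 5L)
  truth <- simulate_evolution(scfg)
  samp <- sample_isolates_and_reads(truth, scfg)
  called <- filter_candidate_sites(samp$counts, truth$genome,
                                   annotate = FALSE)
  pos_of <- function(ids, snps) snps$pos[match(ids, snps$snp_id)]
  for (iso in rownames(called$genotypes$calls)) {
    called_set <- colnames(called$genotypes$calls)[
      called$genotypes$calls[iso, ] == "derived"]
    true_set <- colnames(samp$true_genotypes$calls)[
      samp$true_genotypes$calls[iso, ] == "derived"]
    expect_setequal(pos_of(called_set, called$snps),
                    truth$snp_catalog$pos[match(true_set,
                                                truth$snp_catalog$snp_id)])
  }
})

test_that("strand and depth defaults satisfy the per-strand filter almost surely", {
  # binomial tail: depth ~ NB(mu 60), strands split at 1/2 -> P(either
  # strand < 7) is far below 1%; verified empirically on one sample
  samp <- default_run()$samp
  fwd <- apply(samp$counts$counts[, , c(1, 3, 5, 7)], c(1, 2), sum)
  rev <- apply(samp$counts$counts[, , c(2, 4, 6, 8)], c(1, 2), sum)
  expect_gt(mean(fwd >= 7 & rev >= 7), 0.99)
})

test_that("sampled isolate fractions track true lineage frequencies", {
  run <- default_run()
  truth <- run$truth
  lin_of <- unlist(run$samp$isolate_lineage)
  meta <- run$samp$metadata
  raw <- truth_raw_frequencies(truth)
  ok <- 0L; total <- 0L
  for (sid in truth$subjects$subject_id) for (d in run$scfg$days) {
    iso <- meta$isolate_id[meta$subject_id == sid & meta$day == d]
    n <- length(iso)
    if (!n) next
    for (lin in setdiff(truth$lineages$lineage_id, "ancestor")) {
      members <- vapply(iso, function(i) {
        lin %in% c(lin_of[[i]],
                   gutevolve:::lineage_ancestry(truth$lineages, lin_of[[i]]))
      }, logical(1))
      p <- raw$raw[raw$subject_id == sid & raw$day == d &
                   raw$lineage_id == lin]
      se <- sqrt(max(p * (1 - p), 1e-6) / n)
      total <- total + 1L
      if (abs(mean(members) - p) <= 3 * se + 0.02) ok <- ok + 1L
    }
    break   # one day per subject keeps the check light
  }
  expect_gte(ok / total, 0.9)
})

test_that("community simulation honors class means and composition", {
  comm <- simulate_community(sim_config(seed = 19L))
  expect_true(all(abs(rowSums(comm$abundance) - 1) < 1e-9))

  # competitor day-28 counts concentrate near the configured mean of 70
  scfg <- sim_config(seed = 23L, community_n_competitors = 10L,
                     community_probiotic_subjects = 5L)
  comm2 <- simulate_community(scfg)
  d28 <- comm2$profiles[comm2$profiles$day == 28 &
                        comm2$profiles$group == "probiotic", ]
  comp_counts <- d28$snp_count[d28$species_id %in% comm2$competitors]
  expect_gte(length(comp_counts), 50L)
  expect_lt(abs(mean(comp_counts) - 70) / 70, 0.1)

  # under placebo, competitor and non-competitor rates are indistinguishable
  plc <- comm2$profiles[comm2$profiles$group == "placebo" &
                        comm2$profiles$day == 28, ]
  p <- wilcox.test(plc$snp_count[plc$species_id %in% comm2$competitors],
                   plc$snp_count[!plc$species_id %in% comm2$competitors])$p.value
  expect_gt(p, 0.01)
})
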