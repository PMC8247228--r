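test_that("per-cell genotype calls apply the printed filters", {
  cfg <- pipeline_config()
  # clean call: 8 fwd + 8 rev reads of G at quality 30
  r <- call_site_genotype(c(0, 0, 0, 0, 8, 8, 0, 0), 30, cfg)
  expect_true(r$pass)
  expect_equal(r$allele, "G")

  # 6 forward reads < 7 fails the strand-depth rule even at high total
  r <- call_site_genotype(c(0, 0, 0, 0, 6, 20, 0, 0), 30, cfg)
  expect_false(r$pass)
  expect_equal(r$fail_reasons, "strand-depth")

  # 17 G / 3 A over 10+10 reads: major-allele frequency 0.85 < 0.90
  r <- call_site_genotype(c(2, 1, 0, 0, 8, 9, 0, 0), 30, cfg)
  expect_false(r$pass)
  expect_equal(r$fail_reasons, "major-allele-frequency")
  expect_equal(r$allele, "G")

  # quality at the threshold fails (pass requires strictly < 60)
  r <- call_site_genotype(c(0, 0, 0, 0, 8, 8, 0, 0), 60, cfg)
  expect_false(r$pass)
  expect_equal(r$fail_reasons, "quality")

  # missing cell
  r <- call_site_genotype(rep(0, 8), NA, cfg)
  expect_false(r$pass)
  expect_equal(r$fail_reasons, "missing")

  # exact 50/50 tie cannot be called
  r <- call_site_genotype(c(10, 10, 0, 0, 10, 10, 0, 0), 30, cfg)
  expect_true(is.na(r$allele))
  expect_false(r$pass)
})

test_that("filter cascade discards concordant, low-coverage and high-failure sites", {
  genome <- tiny_genome(paste(rep("A", 21), collapse = ""))
  iso <- sprintf("i%d", 1:10)

  # every isolate matches the ancestor everywhere -> no SNPs
  bases <- matrix("A", 2, 10, dimnames = list(NULL, iso))
  res <- filter_candidate_sites(clean_acm(bases), genome)
  expect_equal(nrow(res$snps), 0L)
  expect_true(all(grepl("no-discordant-pair", res$audit$note)))

  # discordant site, but 4 of 10 isolates fail quality (40% >= 1/3)
  bases[1, 1:3] <- "G"
  acm <- clean_acm(bases)
  acm$quality[1, 7:10] <- 99
  res <- filter_candidate_sites(acm, genome)
  expect_false(res$audit$retained[1])
  expect_match(res$audit$note[1], "isolate-failure-fraction")

  # exactly 3 of 10 failing (30% < 1/3) keeps the site
  acm$quality[1, 10] <- 20
  res <- filter_candidate_sites(acm, genome)
  expect_true(res$audit$retained[1])
  expect_equal(res$snps$alt[1], "G")
  expect_equal(unname(res$genotypes$calls[c("i1", "i4", "i7"), 1]),
               c("derived", "ancestral", "ambiguous"))

  # median coverage below 10 discards
  acm2 <- clean_acm(bases, depth_per_strand = 4L)  # coverage 8 < 10
  res <- filter_candidate_sites(acm2, genome)
  expect_match(res$audit$note[1], "median-coverage")

  expect_error(
    filter_candidate_sites(clean_acm(bases[, 1, drop = FALSE]), genome),
    ">= 2 isolates")
})

test_that("retained sites always hold a discordant passing pair and are order-independent", {
  set.seed(404)
  for (rep in 1:25) {
    rn <- random_acm()
    res <- filter_candidate_sites(rn$acm, rn$genome, annotate = FALSE)
    # every retained site has >= 2 passing isolates with different alleles
    for (k in which(res$audit$retained)) {
      col <- res$genotypes$calls[, paste0("SNP_chr_", res$audit$pos[k])]
      expect_true(any(col == "derived") && any(col == "ancestral"))
    }
    # shuffling site and isolate order leaves the retained set unchanged
    sp <- sample(nrow(rn$acm$sites)); ip <- sample(length(rn$acm$isolates))
    shuf <- allele_count_matrix(rn$acm$sites[sp, , drop = FALSE],
                                rn$acm$isolates[ip],
                                rn$acm$counts[sp, ip, , drop = FALSE],
                                rn$acm$quality[sp, ip, drop = FALSE])
    res2 <- filter_candidate_sites(shuf, rn$genome, annotate = FALSE)
    expect_setequal(paste(res$audit$replicon, res$audit$pos)[res$audit$retained],
                    paste(res2$audit$replicon, res2$audit$pos)[res2$audit$retained])
  }
})

test_that("mutation typing is a strand-symmetric six-class partition", {
  expect_equal(classify_mutation_type("C", "A"), "G:C>T:A")
  expect_equal(classify_mutation_type("T", "C"), "A:T>G:C")
  expect_equal(classify_mutation_type("A", "G"), "A:T>G:C")
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seen <- character()
  for (r in bases) for (a in setdiff(bases, r)) {
    cls <- classify_mutation_type(r, a)
    expect_true(cls %in% mutation_classes())
    expect_equal(classify_mutation_type(comp[[r]], comp[[a]]), cls)
    seen <- c(seen, cls)
  }
  expect_setequal(unique(seen), mutation_classes())
  expect_equal(unname(table(seen)[mutation_classes()]), rep(2L, 6L),
               ignore_attr = TRUE)
  expect_error(classify_mutation_type("A", "A"), "ref == alt")
})

test_that("coding effects are annotated per strand with bacterial code", {
  g <- tiny_genome("ATGGCTTAA")           # + strand: M A *
  s <- snp_table("s1", "chr", 6L, "T", "C")  # GCT -> GCC, Ala -> Ala
  out <- annotate_coding_effect(s, g)
  expect_equal(out$coding_effect, "synonymous")
  expect_equal(out$aa_change, "A2A")

  s <- snp_table("s2", "chr", 4L, "G", "A")  # GCT -> ACT, Ala -> Thr
  out <- annotate_coding_effect(s, g)
  expect_equal(out$coding_effect, "nonsynonymous")
  expect_equal(out$aa_change, "A2T")

  # same gene encoded on the minus strand: genome is the reverse complement
  gm <- tiny_genome("TTAAGCCAT", strand = "-")   # revcomp = ATGGCTTAA
  # plus-strand position 4 is gene offset 5 (third base of codon 2)
  s <- annotate_coding_effect(snp_table("s3", "chr", 4L, "A", "G"), gm)
  expect_equal(s$coding_effect, "synonymous")
  expect_equal(s$aa_change, "A2A")

  # intergenic SNP: no annotation covers the position
  g2 <- reference_genome(c(chr = "ATGGCTTAAACGT"),
    data.frame(gene_id = "geneA", replicon = "chr", start = 1L, end = 9L,
               strand = "+", product = "toy", stringsAsFactors = FALSE))
  out <- annotate_coding_effect(snp_table("s4", "chr", 12L, "G", "T"), g2)
  expect_equal(out$coding_effect, "intergenic")
  expect_true(is.na(out$gene_id))

  # gene length not a multiple of 3
  g3 <- tiny_genome("ATGGCTTA")
  expect_warning(
    out <- annotate_coding_effect(snp_table("s5", "chr", 2L, "T", "C"), g3),
    "multiple of 3")
  expect_equal(out$coding_effect, "ambiguous")
})

test_that("simulated truth is recovered by the cascade at depth 60x", {
  run <- default_run()
  key_called <- paste(run$called$snps$replicon, run$called$snps$pos)
  key_true <- paste(run$truth$snp_catalog$replicon, run$truth$snp_catalog$pos)
  recall <- mean(key_true %in% key_called)
  precision <- mean(key_called %in% key_true)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
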