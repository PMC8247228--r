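geno_from <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  genotype_matrix(m)
}

test_that("pairwise SNP distance counts discordant unambiguous positions", {
  m <- matrix("ancestral", 3, 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  m["A", c("s1", "s2")] <- "derived"
  m["B", c("s2", "s3")] <- "derived"
  m["C", c("s1", "s2")] <- "derived"
  d <- pairwise_snp_distance(genotype_matrix(m))
  expect_equal(d$d["A", "C"], 0)          # identical derived sets
  expect_equal(d$d["A", "B"], 2)          # symmetric difference {s1, s3}
  expect_true(isSymmetric(d$d))
  expect_equal(unname(diag(d$d)), rep(0, 3))

  m["B", "s1"] <- "ambiguous"             # excludes s1 from the A-B pair
  d2 <- pairwise_snp_distance(genotype_matrix(m))
  expect_equal(d2$d["A", "B"], 1)
  expect_equal(d2$comparable["A", "B"], 2)
})

test_that("NJ trees are rooted on the ancestor with non-negative branches", {
  m <- matrix("ancestral", 3, 6,
              dimnames = list(c("x", "y", "z"), paste0("s", 1:6)))
  m["x", 1:2] <- "derived"; m["y", 3:4] <- "derived"; m["z", 5:6] <- "derived"
  d <- pairwise_snp_distance(genotype_matrix(m))
  # equidistant triple (4,4,4): every terminal branch is 2
  nj <- build_nj_tree(d, root_on_ancestor = FALSE)
  expect_s3_class(nj$tree, "phylo")
  expect_equal(sort(nj$tree$edge.length), rep(2, 3), tolerance = 1e-9)

  # an isolate identical to the ancestor sits on a zero-length branch
  m <- rbind(m, anc_twin = rep("ancestral", 6))
  d <- pairwise_snp_distance(genotype_matrix(m), include_ancestor = TRUE)
  nj <- build_nj_tree(d)
  expect_true(all(nj$tree$edge.length >= 0))
  twin_edge <- nj$tree$edge.length[
    nj$tree$edge[, 2] == match("anc_twin", nj$tree$tip.label)]
  expect_equal(twin_edge, 0, tolerance = 1e-9)
  expect_true("ancestor" %in% nj$tree$tip.label)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(nj, nwk)
  expect_true(startsWith(readLines(nwk), "("))
})

test_that("NJ recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  for (rep in 1:10) {
    true_tree <- ape::rtree(8)
    true_tree$edge.length <- true_tree$edge.length + 0.1
    d <- ape::cophenetic.phylo(true_tree)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    nj <- build_nj_tree(list(d = d), root_on_ancestor = FALSE)
    expect_equal(phangorn::RF.dist(ape::unroot(nj$tree),
                                   ape::unroot(true_tree)), 0)
    # path distances reproduce the additive input matrix
    back <- ape::cophenetic.phylo(nj$tree)
    expect_equal(back[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
})

test_that("dMRCA averages derived counts over in-subset polymorphic sites", {
  m <- matrix("ancestral", 3, 6,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  m["a", 1] <- "derived"            # p1: a, c derived; b ancestral
  m["c", 1] <- "derived"
  m[c("b", "c"), 2] <- "derived"    # p2: b, c derived; a ancestral
  m[c("b", "c"), 3] <- "derived"    # p3: b, c derived; a ancestral
  # all three positions polymorphic in-subset; derived counts 1, 2, 3
  expect_equal(dmrca(genotype_matrix(m)), 2.0)

  # genotypically identical isolates: no polymorphism, dMRCA 0
  m2 <- matrix("derived", 3, 4, dimnames = list(c("a", "b", "c"),
                                                paste0("s", 1:4)))
  expect_equal(dmrca(genotype_matrix(m2)), 0)

  # fixed-derived positions are excluded from the count
  m3 <- matrix(c("derived", "derived",      # s1 fixed derived
                 "derived", "ancestral"),   # s2 polymorphic
               2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(dmrca(genotype_matrix(m3)), 0.5)

  # single isolate subsets have no within-subset polymorphism
  expect_equal(dmrca(genotype_matrix(m), "c"), 0)
  expect_error(dmrca(genotype_matrix(m), character()), "empty")

  # invariant to adding positions ancestral in every subset isolate
  m4 <- cbind(m, s7 = rep("ancestral", 3))
  expect_equal(dmrca(genotype_matrix(m4)), dmrca(genotype_matrix(m)))
})

test_that("mutation spectrum tallies per SNP or weighted per isolate", {
  empty <- snp_table(character(), character(), integer(), character(),
                     character())
  expect_equal(unname(mutation_spectrum(empty)$pooled), rep(0, 6))

  tab <- published_snp_table()
  spec <- mutation_spectrum(tab, "per_snp")
  expect_equal(unname(spec$pooled[c("A:T>G:C", "A:T>C:G", "G:C>T:A",
                                    "G:C>A:T", "A:T>T:A", "G:C>C:G")]),
               c(8, 7, 5, 2, 0, 0))

  # per-isolate weighting equals a brute-force per-isolate class tally
  run <- default_run()
  snps <- run$called$snps
  geno <- run$called$genotypes
  spec_iso <- mutation_spectrum(snps, "per_isolate", geno = geno)
  brute <- setNames(numeric(6), mutation_classes())
  for (iso in rownames(geno$calls)) for (id in colnames(geno$calls))
    if (geno$calls[iso, id] == "derived") {
      cls <- snps$mutation_class[snps$snp_id == id]
      brute[cls] <- brute[cls] + 1
    }
  expect_equal(spec_iso$pooled, brute)

  # per-host means and SDs are reported across host species
  spec_host <- mutation_spectrum(snps, "per_snp", geno = geno,
                                 metadata = run$samp$metadata)
  expect_equal(rownames(spec_host$per_host), c("human", "mouse"))
  expect_length(spec_host$mean, 6L)
  expect_length(spec_host$sd, 6L)
})
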