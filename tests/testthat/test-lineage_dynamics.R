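test_that("trajectory frequencies honor the 4-isolate rule and exclude ambiguity", {
  iso <- sprintf("i%02d", 1:10)
  calls <- matrix("ancestral", 10, 2, dimnames = list(iso, c("s1", "s2")))
  calls[1:3, "s1"] <- "derived"          # 3 carriers < 4 -> dropped
  calls[1:4, "s2"] <- "derived"
  meta <- isolate_metadata(iso, "human", "h1",
                           day = rep(c(3L, 7L), each = 5L))
  fr <- snp_frequencies(genotype_matrix(calls), meta)
  expect_false("s1" %in% fr$snp_id)
  expect_true("s2" %in% fr$snp_id)

  # day with 5 isolates: 2 derived, 1 ambiguous -> 2/4 = 0.5
  calls2 <- matrix("ancestral", 5, 1, dimnames = list(iso[1:5], "sA"))
  calls2[1:2, 1] <- "derived"
  calls2[3, 1] <- "ambiguous"
  calls2 <- rbind(calls2,
                  matrix("derived", 2, 1, dimnames = list(c("x1", "x2"), "sA")))
  meta2 <- isolate_metadata(rownames(calls2), "human", "h1",
                            day = c(rep(3L, 5), 7L, 7L))
  fr <- snp_frequencies(genotype_matrix(calls2), meta2, min_isolates = 4L)
  expect_equal(fr$frequency[fr$day == 3], 0.5)
  expect_equal(fr$n_called[fr$day == 3], 4L)
})

test_that("Bezier interpolation passes through observations, stays bounded and monotone", {
  # identically-zero observations interpolate to zero
  tr <- interpolate_trajectory(c(0, 28), c(0, 0), grid_step = 1)
  expect_true(all(tr$frequency == 0))

  tr <- interpolate_trajectory(c(3, 7), c(0.2, 0.8), grid_step = 0.1)
  expect_equal(tr$frequency[tr$day == 3], 0.2)
  expect_equal(tr$frequency[tr$day == 7], 0.8)
  expect_true(all(tr$frequency >= 0 & tr$frequency <= 1))

  # monotone observations yield a monotone interpolant
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    days <- sort(sample(0:28, n))
    freqs <- sort(runif(n))
    tr <- interpolate_trajectory(days, freqs, grid_step = 0.25)
    expect_true(all(diff(tr$frequency) >= -1e-12))
    expect_equal(tr$frequency[match(days, tr$day)], freqs)
    # decreasing series likewise
    tr2 <- interpolate_trajectory(days, rev(freqs), grid_step = 0.25)
    expect_true(all(diff(tr2$frequency) <= 1e-12))
  }

  expect_warning(tr <- interpolate_trajectory(14, 0.5), "single")
  expect_equal(tr$frequency, 0.5)
})

test_that("lineages nest by derived-set inclusion with E-notation names", {
  # chain: s41 in {a,b,c}, s10 in {b,c}, s23 in {c}
  iso <- c("a", "b", "c", "d")
  calls <- matrix("ancestral", 4, 3,
                  dimnames = list(iso, c("s41", "s10", "s23")))
  calls[c("a", "b", "c"), "s41"] <- "derived"
  calls[c("b", "c"), "s10"] <- "derived"
  calls["c", "s23"] <- "derived"
  lt <- nest_lineages(genotype_matrix(calls))
  expect_equal(nrow(lt$nodes), 3L)
  expect_equal(lt$nodes$lineage_id, c("E1", "E1-A", "E1-A-1"))
  expect_equal(lt$nodes$parent, c(NA, "E1", "E1-A"))

  # disjoint derived sets under a common parent become siblings
  calls2 <- matrix("ancestral", 5, 3,
                   dimnames = list(c(iso, "e"), c("p", "c1", "c2")))
  calls2[c("a", "b", "c", "d"), "p"] <- "derived"
  calls2[c("a", "b"), "c1"] <- "derived"
  calls2[c("c", "d"), "c2"] <- "derived"
  lt2 <- nest_lineages(genotype_matrix(calls2))
  expect_setequal(lt2$nodes$parent[lt2$nodes$lineage_id != "E1"],
                  c("E1", "E1"))

  # heavy nesting conflicts demand manual curation
  calls3 <- matrix("ancestral", 4, 2,
                   dimnames = list(iso, c("x", "y")))
  calls3[c("a", "b"), "x"] <- "derived"
  calls3[c("b", "c"), "y"] <- "derived"
  expect_error(nest_lineages(genotype_matrix(calls3), conflict_threshold = 0.1),
               "manual curation")
})

test_that("simulated nested sweeps are recovered as the true lineage tree", {
  scfg <- sim_config(seed = 2L)
  truth <- simulate_evolution(scfg)
  samp <- sample_isolates_and_reads(truth, scfg)
  called <- filter_candidate_sites(samp$counts, truth$genome)
  lt <- nest_lineages(called$genotypes)
  m <- match_lineage_tree(lt, called$snps, truth)
  expect_false(is.null(m))
  expect_setequal(m$truth, setdiff(truth$lineages$lineage_id, "ancestor"))
  root_rows <- is.na(m$recovered_parent)
  expect_equal(m$truth_parent[root_rows], "ancestor")
  expect_equal(m$recovered_parent_truth[!root_rows],
               m$truth_parent[!root_rows])
})

test_that("Muller decomposition subtracts children and clamps at zero", {
  nodes <- data.frame(lineage_id = c("P", "C1", "C2"),
                      parent = c(NA, "P", "P"), stringsAsFactors = FALSE)
  freq <- data.frame(lineage_id = c("P", "C1", "C2"), day = 14L,
                     raw = c(0.8, 0.3, 0.3), stringsAsFactors = FALSE)
  out <- muller_decompose(freq, nodes)
  expect_equal(out$exclusive[out$lineage_id == "P"], 0.2)
  expect_equal(out$exclusive[out$lineage_id == "C1"], 0.3)  # leaf = raw

  freq$raw <- c(0.8, 0.5, 0.4)
  out <- muller_decompose(freq, nodes)
  expect_equal(out$exclusive[out$lineage_id == "P"], 0)     # clamped

  # idempotent when the output is fed back as leaf frequencies
  leaf <- out[c("lineage_id", "day")]
  leaf$raw <- out$exclusive
  again <- muller_decompose(leaf)
  expect_equal(again$exclusive, leaf$raw)
})

test_that("per-day exclusive frequencies conserve total mass on simulation", {
  run <- default_run()
  lt <- nest_lineages(run$called$genotypes)
  for (h in c("human", "mouse")) {
    lf <- lineage_frequencies(lt, run$samp$metadata, host = h)
    mm <- muller_decompose(lf, lt$nodes)
    for (d in unique(mm$day)) {
      roots <- lt$nodes$lineage_id[is.na(lt$nodes$parent)]
      root_raw <- sum(mm$raw[mm$day == d & mm$lineage_id %in% roots])
      expect_lte(root_raw, 1 + 1e-9)
      expect_lte(sum(mm$exclusive[mm$day == d]), root_raw + 1e-9)
    }
  }
})

test_that("estimated SNP trajectories track true lineage frequencies", {
  run <- default_run()
  fr <- snp_frequencies(run$called$genotypes, run$samp$metadata,
                        scope = "pooled")
  truth <- run$truth
  raw <- truth_raw_frequencies(truth)
  ok <- 0L; total <- 0L
  for (k in seq_len(nrow(fr))) {
    pos <- run$called$snps$pos[run$called$snps$snp_id == fr$snp_id[k]]
    lin <- truth$snp_catalog$lineage_id[truth$snp_catalog$pos == pos]
    if (!length(lin)) next
    tr <- raw[raw$day == fr$day[k] & raw$lineage_id == lin, ]
    p <- mean(tr$raw)                   # pooled over subjects
    se <- sqrt(max(p * (1 - p), 1e-6) / max(fr$n_called[k], 1))
    total <- total + 1L
    if (abs(fr$frequency[k] - p) <= 3 * se + 0.05) ok <- ok + 1L
  }
  expect_gte(ok / total, 0.9)
})

test_that("cross-host Mantel comparison is calibrated and label-invariant", {
  run <- default_run()
  lt <- nest_lineages(run$called$genotypes)
  mh <- lapply(c("human", "mouse"), function(h)
    muller_decompose(lineage_frequencies(lt, run$samp$metadata, host = h),
                     lt$nodes))
  # identical trajectories give R = 1
  self <- compare_host_dynamics(mh[[1]], mh[[1]], seed = 3L)
  expect_equal(self$mantel_r, 1)

  res <- compare_host_dynamics(mh[[1]], mh[[2]], seed = 3L)
  expect_true(is.finite(res$mantel_r))

  # independently shuffled trajectories: small |R|, p above 0.05
  set.seed(8)
  shuffle_days <- function(m) {
    days <- unique(m$day)
    remap <- setNames(sample(days), days)
    m$day <- remap[as.character(m$day)]
    m
  }
  null_p <- replicate(5, {
    compare_host_dynamics(shuffle_days(mh[[1]]), shuffle_days(mh[[2]]),
                          n_permutations = 119, seed = 9L)$p_value
  })
  expect_gte(mean(null_p > 0.05, na.rm = TRUE), 0.6)

  # consistent relabeling of time points in both matrices leaves R unchanged
  remap <- setNames(c(28L, 3L, 14L, 7L, 21L), c(3L, 7L, 14L, 21L, 28L))
  relab <- lapply(mh, function(m) {
    m$day <- remap[as.character(m$day)]
    m
  })
  res2 <- compare_host_dynamics(relab[[1]], relab[[2]], seed = 3L)
  expect_equal(res2$mantel_r, res$mantel_r)

  # constant distance matrices are reported as degenerate
  const <- mh[[1]]
  const$raw <- 1
  deg <- compare_host_dynamics(const, const, seed = 3L)
  expect_true(is.na(deg$mantel_r))
})
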