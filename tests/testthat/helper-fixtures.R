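# Shared fixture builders and independent oracles.

# tiny single-gene genome: one replicon, one + strand gene spanning it
tiny_genome <- function(seq = "ATGGCTTAA", gene_id = "geneA",
                        strand = "+") {
  reference_genome(
    c(chr = seq),
    data.frame(gene_id = gene_id, replicon = "chr", start = 1L,
               end = nchar(seq), strand = strand, product = "toy",
               stringsAsFactors = FALSE))
}

# build an allele_count_matrix from a compact cell spec:
# cells[[i]] = list(site = k, isolate = "A", base = "G", fwd = 8, rev = 8,
#                   quality = 30, extra = named counts for other channels)
make_acm <- function(n_sites, isolates, cells,
                     replicon = "chr", positions = seq_len(n_sites)) {
  counts <- array(0L, c(n_sites, length(isolates), 8L))
  quality <- matrix(NA_real_, n_sites, length(isolates))
  ch <- function(base, strand) match(base, c("A", "C", "G", "T")) * 2L -
    (strand == "fwd")
  for (cell in cells) {
    i <- match(cell$isolate, isolates)
    s <- cell$site
    if (!is.null(cell$base)) {
      counts[s, i, ch(cell$base, "fwd")] <-
        counts[s, i, ch(cell$base, "fwd")] + as.integer(cell$fwd)
      counts[s, i, ch(cell$base, "rev")] <-
        counts[s, i, ch(cell$base, "rev")] + as.integer(cell$rev)
    }
    if (!is.null(cell$extra))
      for (nm in names(cell$extra)) {
        parts <- strsplit(nm, "_")[[1]]
        counts[s, i, ch(parts[1], parts[2])] <-
          counts[s, i, ch(parts[1], parts[2])] + as.integer(cell$extra[[nm]])
      }
    quality[s, i] <- if (is.null(cell$quality)) 20 else cell$quality
  }
  allele_count_matrix(
    data.frame(replicon = replicon, pos = positions,
               stringsAsFactors = FALSE),
    isolates, counts, quality)
}

# uniform-coverage matrix where every isolate cleanly carries one base per
# site: bases is a site x isolate character matrix (NA = missing cell)
clean_acm <- function(bases, depth_per_strand = 10L, quality = 20,
                      replicon = "chr") {
  n_s <- nrow(bases); isolates <- colnames(bases)
  cells <- list()
  for (s in seq_len(n_s)) for (iso in isolates) {
    b <- bases[s, iso]
    if (is.na(b)) next
    cells[[length(cells) + 1L]] <- list(site = s, isolate = iso, base = b,
                                        fwd = depth_per_strand,
                                        rev = depth_per_strand,
                                        quality = quality)
  }
  make_acm(n_s, isolates, cells, replicon = replicon)
}

# independent brute-force reimplementation of the printed filter rules,
# enumerating all isolate pairs literally; used as the oracle against
# filter_candidate_sites
brute_force_filter <- function(acm, genome, config = pipeline_config()) {
  n_i <- length(acm$isolates)
  retained <- logical(nrow(acm$sites))
  for (s in seq_len(nrow(acm$sites))) {
    allele <- rep(NA_character_, n_i)
    ok <- logical(n_i)
    cov <- numeric(n_i)
    for (i in seq_len(n_i)) {
      cnt <- acm$counts[s, i, ]
      q <- acm$quality[s, i]
      per_base <- cnt[c(1, 3, 5, 7)] + cnt[c(2, 4, 6, 8)]
      fwd <- sum(cnt[c(1, 3, 5, 7)]); rev <- sum(cnt[c(2, 4, 6, 8)])
      cov[i] <- if (is.na(q)) 0 else fwd + rev
      if (is.na(q)) next
      if (!(q < 60)) next
      if (!(fwd >= 7 && rev >= 7)) next
      tot <- fwd + rev
      if (tot == 0) next
      mx <- max(per_base)
      if (sum(per_base == mx) != 1L) next
      if (!(mx / tot >= 0.90)) next
      ok[i] <- TRUE
      allele[i] <- c("A", "C", "G", "T")[which.max(per_base)]
    }
    disc <- FALSE
    for (i in seq_len(n_i)) for (j in seq_len(n_i))
      if (i < j && ok[i] && ok[j] && allele[i] != allele[j]) disc <- TRUE
    n_fail <- sum(!ok)
    retained[s] <- disc && median(cov) >= 10 && (n_fail / n_i < 1 / 3)
  }
  paste(acm$sites$replicon, acm$sites$pos)[retained]
}

# random count matrix exercising every filter boundary
random_acm <- function(n_isolates = 8L, n_sites = 12L, genome_len = 40L) {
  genome <- reference_genome(
    c(chr = paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                  collapse = "")))
  isolates <- sprintf("i%02d", seq_len(n_isolates))
  positions <- sort(sample.int(genome_len, n_sites))
  counts <- array(0L, c(n_sites, n_isolates, 8L))
  quality <- matrix(NA_real_, n_sites, n_isolates)
  ch <- function(base, strand) match(base, c("A", "C", "G", "T")) * 2L -
    (strand == "fwd")
  for (s in seq_len(n_sites)) {
    anc <- substr(genome$replicons[["chr"]], positions[s], positions[s])
    alt <- sample(setdiff(c("A", "C", "G", "T"), anc), 1L)
    for (i in seq_len(n_isolates)) {
      if (runif(1) < 0.08) next  # missing cell
      b <- if (runif(1) < 0.4) alt else anc
      fwd <- sample(0:20, 1L)
      rev <- sample(0:20, 1L)
      counts[s, i, ch(b, "fwd")] <- fwd
      counts[s, i, ch(b, "rev")] <- rev
      if (runif(1) < 0.35) {   # contaminate with a second allele
        o <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        counts[s, i, ch(o, "fwd")] <- sample(0:4, 1L)
        counts[s, i, ch(o, "rev")] <- sample(0:4, 1L)
      }
      quality[s, i] <- sample(c(10, 30, 59, 60, 61, 80), 1L)
    }
  }
  list(acm = allele_count_matrix(
         data.frame(replicon = "chr", pos = positions,
                    stringsAsFactors = FALSE),
         isolates, counts, quality),
       genome = genome)
}

# one shared default-scenario run, computed lazily and cached for the
# whole test session (simulation, calling, nesting)
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    scfg <- sim_config()
    truth <- simulate_evolution(scfg)
    samp <- sample_isolates_and_reads(truth, scfg)
    called <- filter_candidate_sites(samp$counts, truth$genome)
    .run_cache$run <- list(scfg = scfg, truth = truth, samp = samp,
                           called = called)
  }
  .run_cache$run
}

# map recovered lineage nodes onto truth lineages via SNP positions;
# returns NULL if the SNP partition disagrees, else a data.frame of
# matched (recovered, truth, recovered_parent, truth_parent)
match_lineage_tree <- function(lt, called_snps, truth) {
  truth_lin_of_pos <- setNames(truth$snp_catalog$lineage_id,
                               truth$snp_catalog$pos)
  pos_of_called <- setNames(called_snps$pos, called_snps$snp_id)
  rows <- lapply(seq_len(nrow(lt$nodes)), function(k) {
    ids <- strsplit(lt$nodes$snp_ids[k], ",")[[1]]
    tl <- unique(truth_lin_of_pos[as.character(pos_of_called[ids])])
    data.frame(recovered = lt$nodes$lineage_id[k],
               truth = if (length(tl) == 1L) tl else NA_character_,
               recovered_parent = lt$nodes$parent[k],
               n_snps = length(ids), stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  if (any(is.na(m$truth)) || anyDuplicated(m$truth)) return(NULL)
  m$truth_parent <- truth$lineages$parent[match(m$truth,
                                                truth$lineages$lineage_id)]
  m$recovered_parent_truth <- m$truth[match(m$recovered_parent, m$recovered)]
  m
}
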