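# Forward-time generator of every input the pipeline consumes, with ground
# truth: clonal probiotic evolution with nested selected sublineages,
# isolate sampling with stranded read counts, mobile-element dynamics, and
# a resident community with competitor-biased SNP accumulation.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a reference genome of one
#' chromosome and four plasmids; a scripted lineage plan of five nested
#' selected sublineages (E1, E1-A, E1-B, E1-B-1, E1-B-2) jointly carrying
#' 22 SNPs across 12 genes — five genes with multiple SNPs, seven with a
#' single SNP, three intergenic sites; sampling on days 3, 7, 14, 21 and 28
#' after the end of probiotic intake in two host species; sequencing at a
#' mean depth of 60x with a 0.5\% per-base error rate and an even strand
#' split; and a resident community in which probiotic competitors
#' accumulate SNPs at a day-28 mean of 70 against 2 for non-competitors
#' and 2 under placebo.
#'
#' @param ... named overrides.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    replicon_layout = c(chromosome = 60000L, plasmid1 = 4000L,
                        plasmid2 = 4000L, plasmid3 = 4000L,
                        plasmid4 = 4000L),
    n_genes = 40L,
    gene_length = 900L,
    hosts = c(human = 2L, mouse = 2L),   # subjects per host species
    days = c(3L, 7L, 14L, 21L, 28L),
    isolates_per_host_day = 20L,
    ne = 2000L,                  # Wright-Fisher population size
    mutation_prob = 0,           # per-lineage per-day stochastic birth prob
    selection_default = 0.10,    # s for stochastic births
    lineage_plan = "default",    # "default", NULL (none), or a data.frame
    mean_depth = 60,
    depth_dispersion = 10,       # negative-binomial size
    error_rate = 0.005,
    strand_prob = 0.5,
    n_background_sites = 30L,    # invariant sites carried in count tables
    quality_range = c(5, 30),    # passing site qualities (lower = stronger)
    n_mobile_elements = 2L,
    mobile_element_lengths = c(1200L, 1500L),
    community_n_species = 37L,
    community_n_competitors = 8L,
    community_probiotic_subjects = 7L,
    community_placebo_subjects = 5L,
    community_probiotic_days = c(0L, 3L, 7L, 14L, 21L, 28L),
    community_placebo_days = c(0L, 14L, 28L),
    competitor_day28_mean = 70,
    noncompetitor_day28_mean = 2,
    placebo_day28_mean = 2,
    competitor_coupling = 1.0,   # strength of negative abundance coupling
    abundance_noise_sd = 0.3,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
            cfg$strand_prob >= 0, cfg$strand_prob <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            all(diff(cfg$days) > 0))
  structure(cfg, class = "sim_config")
}

# The scripted five-sublineage plan: birth day, starting frequency taken
# from the parent, selection coefficient, and the number of defining SNPs
# of each branch (3+4+5+5+5 = 22).
default_lineage_plan <- function() {
  data.frame(
    lineage_id = c("E1", "E1-A", "E1-B", "E1-B-1", "E1-B-2"),
    parent = c("ancestor", "E1", "E1", "E1-B", "E1-B"),
    birth_day = c(0L, 1L, 1L, 5L, 7L),
    init_freq = c(0.10, 0.06, 0.06, 0.05, 0.05),
    s = c(0.22, 0.16, 0.19, 0.12, 0.17),
    n_snps = c(3L, 4L, 5L, 5L, 5L),
    stringsAsFactors = FALSE)
}

random_genome <- function(cfg) {
  replicons <- vapply(cfg$replicon_layout, function(len)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
  chrom <- names(cfg$replicon_layout)[1L]
  chrom_len <- cfg$replicon_layout[[1L]]
  spacing <- (chrom_len - 2000L) %/% cfg$n_genes
  if (spacing <= cfg$gene_length)
    stop("chromosome too short for the requested gene layout")
  starts <- 1000L + spacing * (seq_len(cfg$n_genes) - 1L)
  ann <- data.frame(
    gene_id = sprintf("g%02d", seq_len(cfg$n_genes)),
    replicon = chrom,
    start = starts,
    end = starts + cfg$gene_length - 1L,
    strand = rep(c("+", "-"), length.out = cfg$n_genes),
    product = sprintf("synthetic protein %02d", seq_len(cfg$n_genes)),
    stringsAsFactors = FALSE)
  reference_genome(replicons, ann)
}

# Allocate the 22 plan SNPs: genes g01-g05 get (2,2,2,4,2) SNPs, g06-g12
# one each, plus three intergenic sites; blocks are assigned to branches so
# that every multi-SNP gene is hit from at least two distinct branches
# (independent events, the parallel-evolution signature).
plan_snp_allocation <- function() {
  list(
    "E1"     = c("g01", "g06", "intergenic"),
    "E1-A"   = c("g02", "g03", "g07", "g08"),
    "E1-B"   = c("g01", "g02", "g05", "g09", "intergenic"),
    "E1-B-1" = c("g03", "g04", "g04", "g10", "g11"),
    "E1-B-2" = c("g04", "g04", "g05", "g12", "intergenic"))
}

place_snp <- function(genome, gene_id, used_pos) {
  chrom <- names(genome$replicons)[1L]
  if (gene_id == "intergenic") {
    ann <- genome$annotations
    repeat {
      pos <- sample.int(nchar(genome$replicons[[chrom]]), 1L)
      inside <- any(ann$replicon == chrom & ann$start <= pos & ann$end >= pos)
      if (!inside && !pos %in% used_pos) return(pos)
    }
  }
  g <- genome$annotations[genome$annotations$gene_id == gene_id, ]
  repeat {
    pos <- sample(seq.int(g$start, g$end), 1L)
    if (!pos %in% used_pos) return(pos)
  }
}

#' Simulate clonal within-host evolution of the probiotic
#'
#' Discrete-generation Wright-Fisher resampling of sublineage frequencies
#' with multiplicative selection (expected frequency proportional to
#' current frequency times 1+s, renormalised; one generation per day),
#' run independently per host subject. New sublineages are born either on
#' the scripted lineage plan (same branch structure in every subject —
#' the convergent-evolution scenario) or stochastically at
#' \code{mutation_prob} per lineage per day, each birth adding one SNP to
#' its parent's set. Fully determined by \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{sim_truth}: list with \code{genome},
#'   \code{snp_catalog} (snp_id, replicon, pos, ref, alt, gene_id,
#'   lineage_id), \code{lineages} (lineage_id, parent, birth_day, s),
#'   \code{subjects} (subject_id, host_species), \code{freqs} (array
#'   subject x day 0..28 x lineage, exclusive frequencies summing to 1),
#'   \code{mobile_elements} (element_id, length, sequence, carrier_lineage)
#'   and \code{config}.
#' @export
simulate_evolution <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- random_genome(config)
  chrom <- names(genome$replicons)[1L]
  plan <- config$lineage_plan
  if (identical(plan, "default")) plan <- default_lineage_plan()
  # SNP catalogue for scripted branches
  catalog <- data.frame(snp_id = character(), replicon = character(),
                        pos = integer(), ref = character(),
                        alt = character(), gene_id = character(),
                        lineage_id = character(), stringsAsFactors = FALSE)
  if (!is.null(plan)) {
    alloc <- plan_snp_allocation()
    if (!identical(sort(plan$lineage_id), sort(names(alloc)))) {
      # custom plan: draw n_snps random gene targets per branch
      alloc <- lapply(seq_len(nrow(plan)), function(i)
        sample(genome$annotations$gene_id, plan$n_snps[i], replace = TRUE))
      names(alloc) <- plan$lineage_id
    }
    used <- integer()
    k <- 0L
    for (lid in plan$lineage_id) for (tgt in alloc[[lid]]) {
      k <- k + 1L
      pos <- place_snp(genome, tgt, used)
      used <- c(used, pos)
      ref <- substr(genome$replicons[[chrom]], pos, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      catalog <- rbind(catalog, data.frame(
        snp_id = sprintf("S%02d", k), replicon = chrom, pos = pos,
        ref = ref, alt = alt,
        gene_id = if (tgt == "intergenic") NA_character_ else tgt,
        lineage_id = lid, stringsAsFactors = FALSE))
    }
  }
  lineages <- data.frame(lineage_id = "ancestor", parent = NA_character_,
                         birth_day = 0L, s = 0, stringsAsFactors = FALSE)
  if (!is.null(plan))
    lineages <- rbind(lineages, data.frame(
      lineage_id = plan$lineage_id, parent = plan$parent,
      birth_day = plan$birth_day, s = plan$s, stringsAsFactors = FALSE))
  subjects <- data.frame(
    subject_id = unlist(lapply(names(config$hosts), function(h)
      sprintf("%s%d", toupper(substr(h, 1, 1)), seq_len(config$hosts[[h]])))),
    host_species = rep(names(config$hosts), config$hosts),
    stringsAsFactors = FALSE)
  max_day <- max(config$days)
  n_days <- max_day + 1L
  # grow lineage table first (stochastic births share one catalogue across
  # subjects would break independence, so stochastic births are per-subject
  # but recorded globally with subject-tagged ids)
  freq_list <- list()
  for (si in seq_len(nrow(subjects))) {
    x <- setNames(numeric(nrow(lineages)), lineages$lineage_id)
    x["ancestor"] <- 1
    traj <- matrix(0, n_days, length(x),
                   dimnames = list(0:max_day, names(x)))
    for (d in 0:max_day) {
      # scripted births at the start of the day
      if (!is.null(plan)) {
        born <- plan[plan$birth_day == d, , drop = FALSE]
        for (b in seq_len(nrow(born))) {
          par <- born$parent[b]
          take <- min(born$init_freq[b], x[par] / 2)
          x[par] <- x[par] - take
          x[born$lineage_id[b]] <- take
        }
      }
      # stochastic births
      if (config$mutation_prob > 0) {
        alive <- names(x)[x > 0]
        for (par in alive) {
          if (runif(1) < config$mutation_prob) {
            new_id <- sprintf("%s_m%s_d%d", subjects$subject_id[si],
                              par, d)
            gene <- sample(genome$annotations$gene_id, 1L)
            pos <- place_snp(genome, gene, catalog$pos)
            ref <- substr(genome$replicons[[chrom]], pos, pos)
            catalog <- rbind(catalog, data.frame(
              snp_id = sprintf("S%02d", nrow(catalog) + 1L),
              replicon = chrom, pos = pos, ref = ref,
              alt = sample(setdiff(BASES, ref), 1L),
              gene_id = gene, lineage_id = new_id,
              stringsAsFactors = FALSE))
            lineages <- rbind(lineages, data.frame(
              lineage_id = new_id, parent = par, birth_day = d,
              s = config$selection_default, stringsAsFactors = FALSE))
            take <- max(1 / config$ne, 0)
            take <- min(take, x[par] / 2)
            x[new_id] <- take
            x[par] <- x[par] - take
            traj <- cbind(traj, 0)
            colnames(traj)[ncol(traj)] <- new_id
          }
        }
      }
      traj[as.character(d), names(x)] <- x
      # Wright-Fisher step with selection into the next day
      if (d < max_day) {
        fit <- 1 + lineages$s[match(names(x), lineages$lineage_id)]
        w <- x * fit
        x[] <- stats::rmultinom(1L, config$ne, w / sum(w)) / config$ne
      }
    }
    freq_list[[subjects$subject_id[si]]] <- traj
  }
  all_lin <- lineages$lineage_id
  freqs <- array(0, c(nrow(subjects), n_days, length(all_lin)),
                 dimnames = list(subjects$subject_id, 0:max_day, all_lin))
  for (sid in names(freq_list))
    freqs[sid, , colnames(freq_list[[sid]])] <- freq_list[[sid]]
  # mobile elements ride on scripted branches
  me <- data.frame(element_id = character(), length = integer(),
                   sequence = character(), carrier_lineage = character(),
                   stringsAsFactors = FALSE)
  if (config$n_mobile_elements > 0L && !is.null(plan)) {
    carriers <- rep(c("E1-B", "E1-A"),
                    length.out = config$n_mobile_elements)
    carriers <- intersect(carriers, lineages$lineage_id)
    for (e in seq_len(min(config$n_mobile_elements, length(carriers)))) {
      len <- config$mobile_element_lengths[
        (e - 1L) %% length(config$mobile_element_lengths) + 1L]
      me <- rbind(me, data.frame(
        element_id = sprintf("ME%03d", e), length = len,
        sequence = paste(sample(BASES, len, replace = TRUE), collapse = ""),
        carrier_lineage = carriers[e], stringsAsFactors = FALSE))
    }
  }
  structure(list(genome = genome, snp_catalog = catalog,
                 lineages = lineages, subjects = subjects, freqs = freqs,
                 mobile_elements = me, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d subject(s), %d sublineage(s), %d true SNP(s), %d mobile element(s)\n",
    nrow(x$subjects), nrow(x$lineages) - 1L, nrow(x$snp_catalog),
    nrow(x$mobile_elements)))
  invisible(x)
}

# lineage ancestry: ids of lin and all its ancestors up to (not incl.) root
lineage_ancestry <- function(lineages, lin) {
  out <- character()
  while (!is.na(lin) && lin != "ancestor") {
    out <- c(out, lin)
    lin <- lineages$parent[match(lin, lineages$lineage_id)]
  }
  out
}

# SNP ids carried by a lineage (its defining block plus inherited blocks)
lineage_snps <- function(truth, lin) {
  truth$snp_catalog$snp_id[
    truth$snp_catalog$lineage_id %in% lineage_ancestry(truth$lineages, lin)]
}

#' Raw (cumulative) truth frequency of each sublineage per subject and day
#'
#' @param truth a \code{\link{simulate_evolution}} result.
#' @return data.frame \code{subject_id, day, lineage_id, raw}.
#' @export
truth_raw_frequencies <- function(truth) {
  lin_ids <- truth$lineages$lineage_id
  desc <- lapply(lin_ids, function(l) {
    keep <- vapply(lin_ids, function(m)
      l %in% c(m, lineage_ancestry(truth$lineages, m)), logical(1))
    lin_ids[keep]
  })
  names(desc) <- lin_ids
  rows <- list()
  for (sid in dimnames(truth$freqs)[[1]])
    for (d in dimnames(truth$freqs)[[2]])
      for (l in lin_ids)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, day = as.integer(d), lineage_id = l,
          raw = sum(truth$freqs[sid, d, desc[[l]]]),
          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Sample isolates and per-site stranded read counts from simulated truth
#'
#' Isolates are drawn multinomially from each subject's exclusive lineage
#' frequencies on each sampling day. Per isolate and site, total depth is
#' negative-binomial, reads split binomially between strands, and each
#' read's base is miscalled at the configured error rate; covered cells get
#' a passing site quality. Mobile-element carriage is translated into
#' accessory contigs and per-element coverage/depth evidence, and every
#' isolate also assembles one core-genome contig (to exercise core
#' removal).
#'
#' @param truth a \code{\link{simulate_evolution}} result.
#' @param config the same \code{\link{sim_config}} used for the truth.
#' @return list with \code{metadata} (an \code{isolate_metadata}),
#'   \code{counts} (an \code{\link{allele_count_matrix}} over the true SNP
#'   sites plus invariant background sites), \code{true_genotypes}
#'   (a \code{\link{genotype_matrix}} of the isolates' true states),
#'   \code{isolate_lineage} (named character), \code{contigs} (named list
#'   isolate -> contig vector) and \code{element_evidence} (data.frame).
#' @export
sample_isolates_and_reads <- function(truth, config = truth$config) {
  set.seed(config$seed + 77003L)
  genome <- truth$genome
  chrom <- names(genome$replicons)[1L]
  # isolate draw
  per_subject <- config$isolates_per_host_day %/%
    max(table(truth$subjects$host_species))
  if (per_subject < 1L) stop("isolates_per_host_day below subject count")
  meta_rows <- list(); lineage_of <- character()
  for (si in seq_len(nrow(truth$subjects))) {
    sid <- truth$subjects$subject_id[si]
    for (d in config$days) {
      x <- truth$freqs[sid, as.character(d), ]
      draw <- stats::rmultinom(1L, per_subject, x)[, 1L]
      lin_drawn <- rep(names(x), draw)
      for (k in seq_along(lin_drawn)) {
        iso <- sprintf("%s_d%02d_i%02d", sid, d, k)
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          isolate_id = iso,
          host_species = truth$subjects$host_species[si],
          subject_id = sid, day = d, group = "probiotic",
          stringsAsFactors = FALSE)
        lineage_of[iso] <- lin_drawn[k]
      }
    }
  }
  metadata <- do.call(rbind, meta_rows)
  metadata <- isolate_metadata(metadata$isolate_id, metadata$host_species,
                               metadata$subject_id, metadata$day,
                               metadata$group)
  isolates <- metadata$isolate_id
  # site table: true SNP sites + invariant background sites
  snp_sites <- truth$snp_catalog[c("replicon", "pos")]
  bg_pos <- sample(setdiff(seq_len(nchar(genome$replicons[[chrom]])),
                           truth$snp_catalog$pos),
                   config$n_background_sites)
  sites <- rbind(snp_sites,
                 data.frame(replicon = chrom, pos = bg_pos,
                            stringsAsFactors = FALSE))
  sites <- sites[order(sites$replicon, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  n_s <- nrow(sites); n_i <- length(isolates)
  counts <- array(0L, c(n_s, n_i, 8L))
  quality <- matrix(NA_real_, n_s, n_i)
  site_key <- paste(sites$replicon, sites$pos)
  snp_at_site <- truth$snp_catalog[
    match(site_key, paste(truth$snp_catalog$replicon,
                          truth$snp_catalog$pos)), ]
  true_calls <- matrix("ancestral", n_i, nrow(truth$snp_catalog),
                       dimnames = list(isolates, truth$snp_catalog$snp_id))
  channel_of <- function(base, strand)
    match(base, BASES) * 2L - (strand == "fwd")
  for (i in seq_len(n_i)) {
    carried <- lineage_snps(truth, lineage_of[[isolates[i]]])
    true_calls[i, carried] <- "derived"
    for (s in seq_len(n_s)) {
      ref_b <- substr(genome$replicons[[sites$replicon[s]]],
                      sites$pos[s], sites$pos[s])
      true_b <- ref_b
      if (!is.na(snp_at_site$snp_id[s]) &&
          snp_at_site$snp_id[s] %in% carried)
        true_b <- snp_at_site$alt[s]
      depth <- rnbinom(1L, mu = config$mean_depth,
                       size = config$depth_dispersion)
      n_err <- rbinom(1L, depth, config$error_rate)
      bases <- c(rep(true_b, depth - n_err),
                 if (n_err > 0L) sample(setdiff(BASES, true_b), n_err,
                                        replace = TRUE))
      if (depth > 0L) {
        fwd <- as.logical(rbinom(depth, 1L, config$strand_prob))
        for (b in BASES) {
          counts[s, i, channel_of(b, "fwd")] <- sum(bases == b & fwd)
          counts[s, i, channel_of(b, "rev")] <- sum(bases == b & !fwd)
        }
      }
      quality[s, i] <- runif(1L, config$quality_range[1L],
                             config$quality_range[2L])
    }
  }
  acm <- allele_count_matrix(sites, isolates, counts, quality)
  # contigs and element evidence
  contigs <- list()
  ev_rows <- list()
  for (i in seq_len(n_i)) {
    iso <- isolates[i]
    carried_lin <- c(lineage_of[[iso]],
                     lineage_ancestry(truth$lineages, lineage_of[[iso]]))
    core_start <- sample.int(nchar(genome$replicons[[chrom]]) - 900L, 1L)
    cs <- c(core = substr(genome$replicons[[chrom]], core_start,
                          core_start + 799L))
    for (e in seq_len(nrow(truth$mobile_elements))) {
      el <- truth$mobile_elements[e, ]
      carrier <- el$carrier_lineage %in% carried_lin
      if (carrier) cs[el$element_id] <- el$sequence
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        element_id = el$element_id, isolate_id = iso,
        coverage_fraction = if (carrier) runif(1, 0.90, 1.0)
                            else runif(1, 0, 0.05),
        mean_depth = if (carrier)
          rnbinom(1L, mu = 1.3 * config$mean_depth,
                  size = config$depth_dispersion) + 61
          else runif(1, 0, 5),
        true_present = carrier, stringsAsFactors = FALSE)
    }
    contigs[[iso]] <- cs
  }
  list(metadata = metadata, counts = acm,
       true_genotypes = genotype_matrix(true_calls),
       isolate_lineage = lineage_of, contigs = contigs,
       element_evidence = if (length(ev_rows)) do.call(rbind, ev_rows)
                          else NULL)
}

#' Simulate a resident community: abundances and per-species SNP profiles
#'
#' Log-normal baseline abundances; competitor species' log-abundances are
#' negatively coupled to the probiotic's; per-species SNP counts accumulate
#' by Poisson increments between sampling days at class-specific rates
#' (competitor / non-competitor / placebo day-28 means from the config),
#' referenced to a zero day-0 baseline.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{abundance} (samples x species relative-abundance
#'   matrix, rows sum to 1), \code{sample_meta} (sample_id, subject_id,
#'   group, day), \code{profiles} (species_id, subject_id, group, day,
#'   snp_count), \code{competitors} (true competitor species ids) and
#'   \code{probiotic_species}.
#' @export
simulate_community <- function(config = sim_config()) {
  set.seed(config$seed + 140821L)
  n_sp <- config$community_n_species
  sp <- c("probiotic", sprintf("sp%02d", seq_len(n_sp - 1L)))
  competitors <- sprintf("sp%02d", seq_len(config$community_n_competitors))
  subjects <- data.frame(
    subject_id = c(sprintf("P%d", seq_len(config$community_probiotic_subjects)),
                   sprintf("C%d", seq_len(config$community_placebo_subjects))),
    group = rep(c("probiotic", "placebo"),
                c(config$community_probiotic_subjects,
                  config$community_placebo_subjects)),
    stringsAsFactors = FALSE)
  base_log <- setNames(rnorm(n_sp - 1L, log(1 / n_sp), 0.8), sp[-1L])
  rows <- list(); meta <- list()
  for (k in seq_len(nrow(subjects))) {
    days <- if (subjects$group[k] == "probiotic")
      config$community_probiotic_days else config$community_placebo_days
    for (d in days) {
      if (subjects$group[k] == "probiotic") {
        log_p <- log(0.08) - 0.06 * d + rnorm(1, 0, 0.4)
      } else {
        log_p <- log(1e-4) + rnorm(1, 0, 0.4)
      }
      z <- log_p - log(0.02)   # centered probiotic signal
      lg <- base_log + rnorm(n_sp - 1L, 0, config$abundance_noise_sd)
      lg[competitors] <- lg[competitors] - config$competitor_coupling * z
      ab <- c(probiotic = exp(log_p), exp(lg))
      rows[[length(rows) + 1L]] <- ab / sum(ab)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sprintf("%s_d%02d", subjects$subject_id[k], d),
        subject_id = subjects$subject_id[k], group = subjects$group[k],
        day = d, stringsAsFactors = FALSE)
    }
  }
  abundance <- do.call(rbind, rows)
  sample_meta <- do.call(rbind, meta)
  rownames(abundance) <- sample_meta$sample_id
  colnames(abundance) <- sp
  # SNP accumulation profiles (cumulative Poisson increments)
  max_day <- max(config$community_probiotic_days)
  rate_of <- function(group, species) {
    mean28 <- if (group == "placebo") config$placebo_day28_mean
      else if (species %in% competitors) config$competitor_day28_mean
      else config$noncompetitor_day28_mean
    mean28 / max_day
  }
  prof <- list()
  for (k in seq_len(nrow(subjects))) {
    days <- sort(unique(c(0L, if (subjects$group[k] == "probiotic")
      config$community_probiotic_days else config$community_placebo_days)))
    for (s in sp[-1L]) {
      count <- 0L
      prev <- 0L
      for (d in days) {
        if (d > 0L)
          count <- count + rpois(1L, rate_of(subjects$group[k], s) *
                                   (d - prev))
        prev <- d
        prof[[length(prof) + 1L]] <- data.frame(
          species_id = s, subject_id = subjects$subject_id[k],
          group = subjects$group[k], day = d, snp_count = count,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(abundance = abundance, sample_meta = sample_meta,
       profiles = do.call(rbind, prof), competitors = competitors,
       probiotic_species = "probiotic")
}
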