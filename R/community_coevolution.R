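# Resident-microbiome co-evolution statistics: CLR transformation,
# co-occurrence network with competitor labelling, and baseline-referenced
# SNP accumulation contrasts.

#' Centered log-ratio (CLR) transformation of a relative-abundance table
#'
#' Per sample (row): \code{log(x_i / geometric_mean(x))}; every transformed
#' row sums to zero. Zeros are handled before the transform either by
#' multiplicative replacement (each zero becomes \code{delta_factor} times
#' the smallest nonzero value of the table, nonzero entries rescaled so the
#' row still sums to its original total) or by adding a uniform pseudocount.
#'
#' @param abundance numeric matrix, samples in rows, species in columns;
#'   rows are relative abundances summing to 1 (checked to 1e-6) unless
#'   \code{check_rows = FALSE}.
#' @param zero_strategy \code{"multiplicative"} or \code{"pseudocount"}.
#' @param delta_factor multiplier on the minimum nonzero value used as the
#'   zero replacement (default 0.65, standard compositional practice).
#' @param check_rows verify rows sum to 1.
#' @return matrix of the same shape, rows summing to 0.
#' @export
clr_transform <- function(abundance,
                          zero_strategy = c("multiplicative", "pseudocount"),
                          delta_factor = 0.65, check_rows = TRUE) {
  zero_strategy <- match.arg(zero_strategy)
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("negative abundances")
  zero_rows <- rowSums(abundance) == 0
  if (any(zero_rows))
    stop("all-zero sample(s): ",
         paste(rownames(abundance)[zero_rows], collapse = ", "))
  if (check_rows && any(abs(rowSums(abundance) - 1) > 1e-6))
    stop("abundance rows must sum to 1")
  if (any(abundance == 0)) {
    if (zero_strategy == "multiplicative") {
      delta <- delta_factor * min(abundance[abundance > 0])
      out <- abundance
      for (r in seq_len(nrow(out))) {
        z <- out[r, ] == 0
        if (any(z)) {
          total <- sum(out[r, ])
          out[r, z] <- delta
          out[r, !z] <- out[r, !z] * (total - delta * sum(z)) /
            sum(abundance[r, !z])
        }
      }
      abundance <- out
    } else {
      abundance <- abundance + min(abundance[abundance > 0]) * delta_factor
    }
  }
  lg <- log(abundance)
  sweep(lg, 1, rowMeans(lg))
}

#' Co-occurrence network and competitor labelling from CLR abundances
#'
#' Computes pairwise rank (Spearman) correlations between species on the
#' CLR-transformed table, assigns each edge a permutation p-value (species
#' profiles permuted jointly across samples, seed-deterministic), controls
#' the FDR by Benjamini-Hochberg at \code{fdr_q}, and labels every species
#' by its significant edge to the probiotic: negative = \code{competitor},
#' positive = \code{positive_associate}, none = \code{non_competitor}; the
#' probiotic itself is \code{probiotic_self}. A documented stand-in for
#' sparse-inverse-covariance network inference; externally computed edge
#' lists can be substituted downstream.
#'
#' @param clr_table CLR-transformed matrix (samples x species, >= 8 rows).
#' @param probiotic_species column name of the probiotic.
#' @param fdr_q FDR level (default 0.05).
#' @param n_permutations permutations for the edge p-values.
#' @param seed RNG seed.
#' @return list with \code{edges} (data.frame \code{species_a, species_b,
#'   rho, p_value, q_value, significant}) and \code{labels} (data.frame
#'   \code{species_id, label, rho_with_probiotic}).
#' @export
cooccurrence_network <- function(clr_table, probiotic_species,
                                 fdr_q = 0.05, n_permutations = 999L,
                                 seed = 1L) {
  clr_table <- as.matrix(clr_table)
  if (nrow(clr_table) < 8L) stop("need >= 8 samples for network inference")
  if (!probiotic_species %in% colnames(clr_table))
    stop("probiotic species not in table: ", probiotic_species)
  vars <- apply(clr_table, 2, stats::var)
  if (any(vars == 0)) {
    warning("excluding zero-variance species: ",
            paste(colnames(clr_table)[vars == 0], collapse = ", "))
    clr_table <- clr_table[, vars > 0, drop = FALSE]
  }
  sp <- colnames(clr_table)
  obs <- stats::cor(clr_table, method = "spearman")
  pairs <- which(upper.tri(obs), arr.ind = TRUE)
  set.seed(seed)
  n <- nrow(clr_table)
  exceed <- matrix(0L, length(sp), length(sp))
  for (b in seq_len(n_permutations)) {
    perm <- stats::cor(clr_table[sample.int(n), , drop = FALSE],
                       clr_table, method = "spearman")
    exceed <- exceed + (abs(perm) >= abs(obs) - 1e-12)
  }
  pmat <- (exceed + 1) / (n_permutations + 1)
  p <- pmat[pairs]
  q <- p.adjust(p, method = "BH")
  edges <- data.frame(species_a = sp[pairs[, 1L]],
                      species_b = sp[pairs[, 2L]],
                      rho = obs[pairs], p_value = p, q_value = q,
                      significant = q <= fdr_q,
                      stringsAsFactors = FALSE)
  lab <- data.frame(species_id = sp, label = "non_competitor",
                    rho_with_probiotic = obs[, probiotic_species],
                    stringsAsFactors = FALSE)
  pe <- edges[(edges$species_a == probiotic_species |
               edges$species_b == probiotic_species) & edges$significant, ]
  other <- ifelse(pe$species_a == probiotic_species, pe$species_b,
                  pe$species_a)
  lab$label[lab$species_id %in% other[pe$rho < 0]] <- "competitor"
  lab$label[lab$species_id %in% other[pe$rho > 0]] <- "positive_associate"
  lab$label[lab$species_id == probiotic_species] <- "probiotic_self"
  rownames(lab) <- NULL
  list(edges = edges, labels = lab)
}

#' Baseline-referenced SNP accumulation statistics
#'
#' Consumes per-species, per-subject SNP counts referenced to the day-0
#' baseline and a competitor labelling, and reports: per group and day the
#' mean SNP count per species; per subject and day the Euclidean distance
#' of the species-count vector from its (all-zero) day-0 baseline; the
#' Wilcoxon rank-sum contrast of competitor vs non-competitor counts in
#' the probiotic group; and per-day accumulation rates (count / elapsed
#' days).
#'
#' @param profiles data.frame with columns \code{species_id, subject_id,
#'   group} (probiotic/placebo), \code{day}, \code{snp_count} (day-0 rows
#'   must be 0 by construction).
#' @param labels data.frame \code{species_id, label} from
#'   \code{\link{cooccurrence_network}} (or supplied externally).
#' @return list with \code{group_means}, \code{euclidean}, \code{rates}
#'   (data.frames) and \code{wilcoxon} (list \code{statistic, p_value,
#'   n_competitor, n_non_competitor}; NULL with a notice when a class is
#'   empty).
#' @export
snp_accumulation_stats <- function(profiles, labels) {
  stopifnot(all(c("species_id", "subject_id", "group", "day", "snp_count")
                %in% names(profiles)))
  if (any(profiles$snp_count < 0)) stop("negative SNP counts")
  day0 <- profiles$snp_count[profiles$day == 0]
  if (length(day0) && any(day0 != 0))
    stop("day-0 baseline counts must be 0 by construction")
  profiles <- merge(profiles, labels[c("species_id", "label")],
                    by = "species_id", all.x = TRUE)
  profiles$label[is.na(profiles$label)] <- "non_competitor"
  group_means <- aggregate(snp_count ~ group + label + day, data = profiles,
                           FUN = mean)
  names(group_means)[names(group_means) == "snp_count"] <- "mean_snps"
  # per-subject Euclidean distance of the species vector from day 0
  subj_days <- unique(profiles[c("subject_id", "group", "day")])
  subj_days <- subj_days[subj_days$day > 0, , drop = FALSE]
  euclid <- do.call(rbind, lapply(seq_len(nrow(subj_days)), function(k) {
    sub <- profiles[profiles$subject_id == subj_days$subject_id[k] &
                    profiles$day == subj_days$day[k], ]
    data.frame(subj_days[k, ],
               euclidean_from_day0 = sqrt(sum(sub$snp_count^2)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(euclid)) rownames(euclid) <- NULL
  rates <- profiles[profiles$day > 0, ]
  rates$snps_per_day <- rates$snp_count / rates$day
  rates <- aggregate(snps_per_day ~ group + label + day, data = rates,
                     FUN = mean)
  prob <- profiles[profiles$group == "probiotic" & profiles$day > 0, ]
  comp <- prob$snp_count[prob$label == "competitor"]
  nonc <- prob$snp_count[prob$label == "non_competitor"]
  wilcoxon <- NULL
  if (length(comp) >= 2L && length(nonc) >= 2L) {
    wt <- suppressWarnings(wilcox.test(comp, nonc,
                                       alternative = "greater"))
    wilcoxon <- list(statistic = unname(wt$statistic),
                     p_value = wt$p.value,
                     n_competitor = length(comp),
                     n_non_competitor = length(nonc))
  } else {
    message("a label class has < 2 observations; Wilcoxon test skipped")
  }
  list(group_means = group_means, euclidean = euclid, rates = rates,
       wilcoxon = wilcoxon)
}
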