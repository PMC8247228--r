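# Gene-level parallel-evolution detection: multiplicity + 2 kb span rule,
# with the perfect-co-occurrence exclusion when genotype data is available.

#' Detect genes under parallel evolution
#'
#' Groups SNPs by gene (intergenic SNPs are ignored) and labels each gene:
#' \itemize{
#'   \item \code{parallel} — at least two SNPs, the maximum pairwise genomic
#'     span between its SNPs is at most \code{window} bp, and, when a
#'     genotype matrix is supplied, not all of its SNP pairs are perfectly
#'     co-occurring (identical derived-isolate sets — two mutations that
#'     always travel together are one event, not parallel evolution);
#'   \item \code{single_mutation} — exactly one SNP;
#'   \item \code{excluded} — multiple SNPs failing the span or the
#'     co-occurrence condition.
#' }
#' The SNP density per 2000 bp of mutated span is reported as a diagnostic;
#' the span formulation is primary. When \code{metadata} is given, the rule
#' is additionally evaluated within each host species and a gene is flagged
#' \code{parallel_any_host} if it qualifies in at least one host alone.
#'
#' @param snps a \code{\link{snp_table}}.
#' @param geno optional \code{\link{genotype_matrix}} for the co-occurrence
#'   exclusion (skipped and flagged when absent).
#' @param window maximum pairwise SNP span in bp (default 2000).
#' @param metadata optional \code{\link{isolate_metadata}} for per-host
#'   scoping.
#' @return data.frame with one row per mutated gene: \code{gene_id, n_snps,
#'   snp_ids, max_span_bp, snps_per_2000bp, status, cooccurrence_checked,
#'   parallel_any_host, hosts_observed}.
#' @export
detect_parallel_genes <- function(snps, geno = NULL, window = 2000L,
                                  metadata = NULL) {
  coding <- snps[!is.na(snps$gene_id), , drop = FALSE]
  genes <- unique(coding$gene_id)
  qualifies <- function(sub) {
    # sub: snp_table rows of one gene (possibly restricted to one host)
    if (nrow(sub) < 2L) return(FALSE)
    span <- max(sub$pos) - min(sub$pos)
    if (span > window) return(FALSE)
    if (!is.null(geno)) {
      sets <- lapply(sub$snp_id, function(id)
        rownames(geno$calls)[geno$calls[, id] == "derived"])
      identical_pairs <- outer(seq_along(sets), seq_along(sets),
        Vectorize(function(i, j) setequal(sets[[i]], sets[[j]])))
      if (all(identical_pairs[upper.tri(identical_pairs)])) return(FALSE)
    }
    TRUE
  }
  res <- lapply(genes, function(g) {
    sub <- coding[coding$gene_id == g, , drop = FALSE]
    span <- if (nrow(sub) > 1L) max(sub$pos) - min(sub$pos) else 0L
    status <- if (nrow(sub) == 1L) "single_mutation"
              else if (qualifies(sub)) "parallel" else "excluded"
    any_host <- NA
    hosts_obs <- NA_character_
    if (!is.null(metadata) && !is.null(geno)) {
      host_names <- unique(metadata$host_species)
      per_host <- vapply(host_names, function(h) {
        iso <- intersect(metadata$isolate_id[metadata$host_species == h],
                         rownames(geno$calls))
        observed <- sub$snp_id[colSums(
          geno$calls[iso, sub$snp_id, drop = FALSE] == "derived") > 0L]
        qualifies(sub[sub$snp_id %in% observed, , drop = FALSE])
      }, logical(1))
      any_host <- any(per_host)
      carried <- vapply(host_names, function(h) {
        iso <- intersect(metadata$isolate_id[metadata$host_species == h],
                         rownames(geno$calls))
        any(geno$calls[iso, sub$snp_id, drop = FALSE] == "derived")
      }, logical(1))
      hosts_obs <- paste(host_names[carried], collapse = ",")
    }
    data.frame(gene_id = g, n_snps = nrow(sub),
               snp_ids = paste(sub$snp_id, collapse = ","),
               max_span_bp = span,
               snps_per_2000bp = nrow(sub) / max(span, 1L) * 2000,
               status = status,
               cooccurrence_checked = !is.null(geno),
               parallel_any_host = any_host,
               hosts_observed = hosts_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene_id = character(),
                                      n_snps = integer(),
                                      snp_ids = character(),
                                      max_span_bp = integer(),
                                      snps_per_2000bp = numeric(),
                                      status = character(),
                                      cooccurrence_checked = logical(),
                                      parallel_any_host = logical(),
                                      hosts_observed = character(),
                                      stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-gene, per-subject mutation frequencies across hosts
#'
#' For each mutated gene and each host subject, the fraction of that
#' subject's isolates carrying at least one derived allele in the gene —
#' the cross-host consistency statistic behind the parallel-evolution
#' heat map.
#'
#' @param snps a \code{\link{snp_table}} (intergenic rows ignored).
#' @param geno a \code{\link{genotype_matrix}}.
#' @param metadata an \code{\link{isolate_metadata}}.
#' @return data.frame with columns \code{gene_id, host_species, subject_id,
#'   n_isolates, frequency}. Subjects with zero isolates are omitted with a
#'   warning.
#' @export
cross_host_consistency <- function(snps, geno, metadata) {
  coding <- snps[!is.na(snps$gene_id), , drop = FALSE]
  subjects <- unique(metadata[c("host_species", "subject_id")])
  rows <- list()
  for (g in unique(coding$gene_id)) {
    ids <- coding$snp_id[coding$gene_id == g]
    for (k in seq_len(nrow(subjects))) {
      iso <- metadata$isolate_id[
        metadata$subject_id == subjects$subject_id[k] &
        metadata$host_species == subjects$host_species[k]]
      iso <- intersect(iso, rownames(geno$calls))
      if (!length(iso)) {
        warning("subject ", subjects$subject_id[k], " has no isolates; ",
                "row omitted")
        next
      }
      carrier <- rowSums(geno$calls[iso, ids, drop = FALSE] == "derived") > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, host_species = subjects$host_species[k],
        subject_id = subjects$subject_id[k], n_isolates = length(iso),
        frequency = mean(carrier), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
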