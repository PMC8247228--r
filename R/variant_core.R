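# Multi-isolate SNP filter cascade over stranded allele counts, six-class
# mutation typing, and coding-effect annotation against the reference.

BASES <- c("A", "C", "G", "T")

#' Call the genotype of one isolate at one site
#'
#' Applies the per-cell filters: site quality strictly below the threshold
#' (lower = stronger evidence), at least \code{min_strand_reads} reads on
#' the forward strand AND on the reverse strand, and a major-allele
#' frequency of at least \code{min_maf}. A missing cell fails with reason
#' \code{"missing"}; an exact tie for the majority allele can never reach
#' 90\% and is reported with no allele.
#'
#' @param counts integer vector of 8 stranded base counts, in channel order
#'   \code{A_fwd, A_rev, C_fwd, C_rev, G_fwd, G_rev, T_fwd, T_rev}.
#' @param quality site quality for this cell; \code{NA} = missing.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{allele} (base or \code{NA}), \code{pass}
#'   (logical) and \code{fail_reasons} (character vector, possibly empty).
#' @export
call_site_genotype <- function(counts, quality, config = pipeline_config()) {
  if (is.na(quality)) {
    return(list(allele = NA_character_, pass = FALSE,
                fail_reasons = "missing"))
  }
  counts <- as.numeric(counts)
  per_base <- counts[c(1, 3, 5, 7)] + counts[c(2, 4, 6, 8)]
  fwd <- sum(counts[c(1, 3, 5, 7)])
  rev <- sum(counts[c(2, 4, 6, 8)])
  total <- fwd + rev
  reasons <- character()
  if (quality >= config$quality_max) reasons <- c(reasons, "quality")
  if (fwd < config$min_strand_reads || rev < config$min_strand_reads)
    reasons <- c(reasons, "strand-depth")
  top <- which(per_base == max(per_base))
  tie <- length(top) > 1L || total == 0
  allele <- if (tie) NA_character_ else BASES[top]
  maf <- if (total == 0) 0 else max(per_base) / total
  if (maf < config$min_maf) reasons <- c(reasons, "major-allele-frequency")
  list(allele = allele, pass = length(reasons) == 0L, fail_reasons = reasons)
}

#' Run the multi-isolate SNP filter cascade
#'
#' A candidate site is retained iff (i) at least one pair of isolates with
#' passing calls is discordant on the called base, (ii) the median total
#' coverage across isolates (missing cells contribute 0) is at least
#' \code{min_median_coverage} reads, and (iii) the fraction of isolates
#' failing the per-cell filters is strictly below 1/3, compared exactly in
#' rationals. Each retained site yields one SNP record (alt = the most
#' common non-ancestral allele among passing calls) and one genotype-matrix
#' column; failing isolates, and passing isolates carrying a third allele,
#' are called ambiguous.
#'
#' @param acm an \code{\link{allele_count_matrix}} covering >= 2 isolates.
#' @param genome the ancestral \code{\link{reference_genome}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param annotate if \code{TRUE}, annotate coding effects of retained SNPs.
#' @return list with \code{snps} (a \code{snp_table}), \code{genotypes}
#'   (a \code{genotype_matrix}) and \code{audit} (one row per input site
#'   with retention status and rejection reasons).
#' @export
filter_candidate_sites <- function(acm, genome, config = pipeline_config(),
                                   annotate = TRUE) {
  n_iso <- length(acm$isolates)
  if (n_iso < 2L) stop("filter cascade requires >= 2 isolates")
  n_sites <- nrow(acm$sites)
  keep <- logical(n_sites)
  reason <- character(n_sites)
  alt <- ref <- character(n_sites)
  calls <- matrix("ambiguous", n_sites, n_iso,
                  dimnames = list(NULL, acm$isolates))
  for (s in seq_len(n_sites)) {
    anc <- ancestral_base(genome, acm$sites$replicon[s], acm$sites$pos[s])
    ref[s] <- anc
    cell_calls <- lapply(seq_len(n_iso), function(i)
      call_site_genotype(acm$counts[s, i, ], acm$quality[s, i], config))
    pass <- vapply(cell_calls, `[[`, logical(1), "pass")
    alleles <- vapply(cell_calls, `[[`, character(1), "allele")
    coverage <- apply(acm$counts[s, , , drop = FALSE], 2, sum)
    coverage[is.na(acm$quality[s, ])] <- 0
    n_fail <- sum(!pass)
    fail_frac_hit <- n_fail * config$max_fail_fraction_den >=
      n_iso * config$max_fail_fraction_num
    med_cov <- median(coverage)
    pa <- alleles[pass]
    discordant <- length(unique(pa)) >= 2L
    reasons <- character()
    if (!discordant) reasons <- c(reasons, "no-discordant-pair")
    if (med_cov < config$min_median_coverage)
      reasons <- c(reasons, "median-coverage")
    if (fail_frac_hit) reasons <- c(reasons, "isolate-failure-fraction")
    if (length(reasons)) {
      reason[s] <- paste(reasons, collapse = ";")
      next
    }
    non_anc <- pa[pa != anc]
    if (!length(non_anc)) {  # discordant but no non-ancestral allele cannot occur
      reason[s] <- "no-non-ancestral-allele"
      next
    }
    tab <- sort(table(non_anc), decreasing = TRUE)
    alt[s] <- names(tab)[1L]
    keep[s] <- TRUE
    reason[s] <- if (length(tab) > 1L)
      paste0("multi-allelic:", paste(names(tab)[-1L], collapse = ",")) else ""
    calls[s, pass & alleles == anc] <- "ancestral"
    calls[s, pass & alleles == alt[s]] <- "derived"
  }
  audit <- data.frame(replicon = acm$sites$replicon, pos = acm$sites$pos,
                      retained = keep, note = reason,
                      stringsAsFactors = FALSE)
  idx <- which(keep)
  snp_ids <- sprintf("SNP_%s_%d", acm$sites$replicon[idx],
                     acm$sites$pos[idx])
  snps <- snp_table(snp_ids, acm$sites$replicon[idx], acm$sites$pos[idx],
                    ref[idx], alt[idx])
  if (annotate && nrow(snps)) snps <- annotate_coding_effect(snps, genome)
  m <- t(calls[idx, , drop = FALSE])
  colnames(m) <- snp_ids
  geno <- genotype_matrix(m)
  list(snps = snps, genotypes = geno, audit = audit)
}

ancestral_base <- function(genome, replicon, pos) {
  seq <- genome$replicons[[replicon]]
  if (is.null(seq)) stop("unknown replicon: ", replicon)
  if (pos < 1L || pos > nchar(seq)) stop("position outside replicon: ", pos)
  substr(seq, pos, pos)
}

#' Classify a substitution into the six strand-symmetric mutation classes
#'
#' The 12 ordered base pairs partition into 6 classes; a substitution and
#' its reverse complement map to the same class (e.g. T>C and A>G are both
#' A:T>G:C). Vectorised over \code{ref}/\code{alt}.
#'
#' @param ref,alt single uppercase bases, \code{ref != alt}.
#' @return character vector over the levels of \code{\link{mutation_classes}}.
#' @export
classify_mutation_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  if (!all(c(ref, alt) %in% BASES)) stop("bases must be A/C/G/T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # canonical representative: pyrimidine-ref orientation of each pair
  canon_ref <- ifelse(ref %in% c("C", "T"), ref, comp[ref])
  canon_alt <- ifelse(ref %in% c("C", "T"), alt, comp[alt])
  key <- paste0(canon_ref, canon_alt)
  map <- c(TC = "A:T>G:C", CT = "G:C>A:T", TG = "A:T>C:G",
           CA = "G:C>T:A", TA = "A:T>T:A", CG = "G:C>C:G")
  unname(map[key])
}

#' The six strand-symmetric mutation classes, in canonical order
#'
#' @return character vector of length 6.
#' @export
mutation_classes <- function() {
  c("A:T>G:C", "G:C>A:T", "A:T>C:G", "G:C>T:A", "A:T>T:A", "G:C>C:G")
}

#' Annotate coding effects of SNPs against the reference annotation
#'
#' Each SNP falling inside an annotated gene is translated in its reference
#' and alternate codon (standard bacterial code), respecting strand; the
#' amino-acid change is reported as \code{"X<pos>Y"} with a 1-based protein
#' position. SNPs covered by no annotation are intergenic. A SNP overlapping
#' two genes is annotated against the first gene in coordinate order; a gene
#' whose length is not a multiple of 3 yields a warning and an ambiguous
#' effect.
#'
#' @param snps a \code{\link{snp_table}}.
#' @param genome a \code{\link{reference_genome}} with annotations.
#' @return the \code{snp_table} with \code{gene_id}, \code{coding_effect}
#'   and \code{aa_change} filled in.
#' @export
annotate_coding_effect <- function(snps, genome) {
  ann <- genome$annotations
  for (k in seq_len(nrow(snps))) {
    hits <- which(ann$replicon == snps$replicon[k] &
                  ann$start <= snps$pos[k] & ann$end >= snps$pos[k])
    if (!length(hits)) {
      snps$gene_id[k] <- NA_character_
      snps$coding_effect[k] <- "intergenic"
      snps$aa_change[k] <- NA_character_
      next
    }
    if (length(hits) > 1L)
      log_msg("SNP %s overlaps %d genes; annotating against %s",
              snps$snp_id[k], length(hits), ann$gene_id[hits[1L]])
    g <- ann[hits[1L], ]
    snps$gene_id[k] <- g$gene_id
    glen <- g$end - g$start + 1L
    if (glen %% 3L != 0L) {
      warning("gene ", g$gene_id, " length not a multiple of 3; ",
              "coding effect ambiguous")
      snps$coding_effect[k] <- "ambiguous"
      snps$aa_change[k] <- NA_character_
      next
    }
    seq <- genome$replicons[[g$replicon]]
    gene_seq <- substr(seq, g$start, g$end)
    offset <- snps$pos[k] - g$start  # 0-based within gene on + strand
    ref_b <- snps$ref[k]; alt_b <- snps$alt[k]
    if (substr(gene_seq, offset + 1L, offset + 1L) != ref_b)
      warning("SNP ", snps$snp_id[k], " ref allele disagrees with reference")
    if (g$strand == "-") {
      gene_seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(gene_seq)))
      offset <- glen - 1L - offset
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_b <- comp[ref_b]; alt_b <- comp[alt_b]
    }
    codon_i <- offset %/% 3L            # 0-based codon index
    within <- offset %% 3L
    codon <- substr(gene_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_codon <- codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_b
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(alt_codon)
    snps$coding_effect[k] <- if (aa_ref == aa_alt) "synonymous" else
      "nonsynonymous"
    snps$aa_change[k] <- sprintf("%s%d%s", aa_ref, codon_i + 1L, aa_alt)
  }
  snps
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}
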