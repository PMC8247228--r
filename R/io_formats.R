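#' @importFrom stats median sd setNames rbinom rnbinom rpois rlnorm rnorm runif
#' @importFrom stats cor p.adjust wilcox.test dist complete.cases aggregate
#' @importFrom utils read.delim write.table head
NULL

# External files are 1-based inclusive throughout; any 0-based arithmetic is
# confined to the bodies of the functions in this file.

#' Read a reference genome (FASTA + gene annotation table)
#'
#' The annotation table is a 6-column TSV with columns
#' \code{gene_id, replicon, start, end, strand, product}; coordinates are
#' 1-based inclusive, matching the convention of the published SNP table.
#'
#' @param fasta_path path to a FASTA file of replicon sequences (A/C/G/T/N).
#' @param annotation_path path to the gene annotation TSV, or \code{NULL} for
#'   an annotation-free genome.
#' @return an object of class \code{reference_genome}: a list with
#'   \code{$replicons} (named character vector of sequences) and
#'   \code{$annotations} (data.frame of gene records, ordered by coordinate).
#' @export
read_reference <- function(fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("reference FASTA contains no sequences")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate replicon ids in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  replicons <- setNames(toupper(as.character(seqs)), nm)
  bad <- grepl("[^ACGTN]", replicons)
  if (any(bad)) {
    off <- regexpr("[^ACGTN]", replicons[bad][1L])
    stop(sprintf("non-ACGTN character in replicon '%s' at position %d",
                 nm[bad][1L], off))
  }
  ann <- if (is.null(annotation_path)) empty_annotation() else
    read_annotations(annotation_path)
  reference_genome(replicons, ann)
}

empty_annotation <- function() {
  data.frame(gene_id = character(), replicon = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), stringsAsFactors = FALSE)
}

read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "replicon", "start", "end", "strand", "product")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  ann[need]
}

#' Construct a validated reference genome object
#'
#' @param replicons named character vector of uppercase nucleotide sequences.
#' @param annotations data.frame of gene annotations (may be empty).
#' @return a \code{reference_genome} object.
#' @export
reference_genome <- function(replicons, annotations = empty_annotation()) {
  stopifnot(is.character(replicons), !is.null(names(replicons)))
  if (any(nchar(replicons) == 0L)) stop("empty replicon sequence")
  if (anyDuplicated(names(replicons))) stop("duplicate replicon ids")
  ann <- annotations
  if (nrow(ann)) {
    if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotations")
    unknown <- setdiff(ann$replicon, names(replicons))
    if (length(unknown))
      stop("annotation references absent replicon for gene(s) ",
           paste(ann$gene_id[ann$replicon %in% unknown], collapse = ", "),
           ": ", paste(unknown, collapse = ", "))
    if (any(ann$start > ann$end)) stop("annotation with start > end: ",
      paste(ann$gene_id[ann$start > ann$end], collapse = ", "))
    lens <- nchar(replicons)[ann$replicon]
    out_of_bounds <- ann$start < 1L | ann$end > lens
    if (any(out_of_bounds))
      stop("annotation outside replicon bounds: ",
           paste(ann$gene_id[out_of_bounds], collapse = ", "))
    if (!all(ann$strand %in% c("+", "-")))
      stop("annotation strand must be '+' or '-'")
    ann <- ann[order(match(ann$replicon, names(replicons)), ann$start), ,
               drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(replicons = replicons, annotations = ann),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome: %d replicon(s), %s bp total, %d gene(s)\n",
              length(x$replicons),
              format(sum(nchar(x$replicons)), big.mark = ","),
              nrow(x$annotations)))
  invisible(x)
}

#' Write a reference genome back to FASTA + annotation TSV
#'
#' @param genome a \code{reference_genome}.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(genome, fasta_path, annotation_path = NULL) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$replicons), fasta_path)
  if (!is.null(annotation_path))
    write.table(genome$annotations, annotation_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

# ---- allele-count matrices ----------------------------------------------

#' Construct an allele-count matrix
#'
#' Dense container of stranded base counts per (replicon, position, isolate)
#' with one site-quality score per cell. Lower quality means stronger variant
#' evidence (a call passes at quality < 60, mirroring bcftools FQ usage).
#' Cells never observed in the input are zero-count with quality \code{NA}
#' ("missing"), which is distinct from observed zero coverage.
#'
#' @param sites data.frame with columns \code{replicon, pos}.
#' @param isolates character vector of isolate ids.
#' @param counts integer array \code{[site, isolate, 8]}; the third axis is
#'   \code{A_fwd, A_rev, C_fwd, C_rev, G_fwd, G_rev, T_fwd, T_rev}.
#' @param quality numeric matrix \code{[site, isolate]}; \code{NA} = missing.
#' @return an \code{allele_count_matrix} object.
#' @export
allele_count_matrix <- function(sites, isolates, counts, quality) {
  stopifnot(nrow(sites) == dim(counts)[1L],
            length(isolates) == dim(counts)[2L],
            dim(counts)[3L] == 8L,
            all(dim(quality) == dim(counts)[1:2]))
  if (any(counts < 0)) stop("negative allele counts")
  if (anyDuplicated(isolates)) stop("duplicate isolate ids")
  if (anyDuplicated(paste(sites$replicon, sites$pos))) stop("duplicate sites")
  dimnames(counts) <- list(NULL, isolates, count_channels())
  dimnames(quality) <- list(NULL, isolates)
  structure(list(sites = sites, isolates = isolates, counts = counts,
                 quality = quality),
            class = "allele_count_matrix")
}

count_channels <- function() {
  c("A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev", "T_fwd", "T_rev")
}

#' @export
print.allele_count_matrix <- function(x, ...) {
  cat(sprintf("allele_count_matrix: %d site(s) x %d isolate(s), %d missing cell(s)\n",
              nrow(x$sites), length(x$isolates), sum(is.na(x$quality))))
  invisible(x)
}

#' Read per-isolate stranded allele counts from long-format TSV
#'
#' Expected columns: \code{replicon, pos, isolate_id, A_fwd, A_rev, C_fwd,
#' C_rev, G_fwd, G_rev, T_fwd, T_rev, site_quality}. Any (site, isolate)
#' cell absent from the file is marked missing.
#'
#' @param tsv_path path to the counts TSV.
#' @return an \code{allele_count_matrix}.
#' @export
read_allele_counts <- function(tsv_path) {
  d <- read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("replicon", "pos", "isolate_id", count_channels(), "site_quality")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("counts TSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(as.matrix(d[count_channels()]) < 0)) stop("negative counts in TSV")
  key <- paste(d$replicon, d$pos, d$isolate_id)
  if (anyDuplicated(key)) stop("duplicate (replicon, pos, isolate) rows")
  sites <- unique(d[c("replicon", "pos")])
  sites <- sites[order(sites$replicon, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  isolates <- sort(unique(d$isolate_id))
  n_s <- nrow(sites); n_i <- length(isolates)
  counts <- array(0L, c(n_s, n_i, 8L))
  quality <- matrix(NA_real_, n_s, n_i)
  si <- match(paste(d$replicon, d$pos), paste(sites$replicon, sites$pos))
  ii <- match(d$isolate_id, isolates)
  for (k in seq_len(8L))
    counts[cbind(si, ii, k)] <- as.integer(d[[count_channels()[k]]])
  quality[cbind(si, ii)] <- d$site_quality
  allele_count_matrix(sites, isolates, counts, quality)
}

#' Write an allele-count matrix as long-format TSV
#'
#' Missing cells are omitted from the file so a read/write round trip
#' preserves missingness.
#'
#' @param acm an \code{allele_count_matrix}.
#' @param tsv_path output path.
#' @return invisibly, the path.
#' @export
write_allele_counts <- function(acm, tsv_path) {
  n_s <- nrow(acm$sites); n_i <- length(acm$isolates)
  si <- rep(seq_len(n_s), times = n_i)
  ii <- rep(seq_len(n_i), each = n_s)
  keep <- !is.na(acm$quality[cbind(si, ii)])
  si <- si[keep]; ii <- ii[keep]
  d <- data.frame(replicon = acm$sites$replicon[si],
                  pos = acm$sites$pos[si],
                  isolate_id = acm$isolates[ii],
                  stringsAsFactors = FALSE)
  for (k in seq_len(8L)) d[[count_channels()[k]]] <- acm$counts[cbind(si, ii, k)]
  d$site_quality <- acm$quality[cbind(si, ii)]
  d <- d[order(d$replicon, d$pos, d$isolate_id), , drop = FALSE]
  write.table(d, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

# ---- SNP tables ----------------------------------------------------------

#' Construct a table of confirmed SNP records
#'
#' @param snp_id,replicon,pos,ref,alt vectors describing each variant
#'   (1-based coordinates; single uppercase bases).
#' @param gene_id gene assignment or \code{NA} for intergenic.
#' @param coding_effect \code{"synonymous"}, \code{"nonsynonymous"},
#'   \code{"intergenic"} or \code{NA} (unannotated).
#' @param aa_change amino-acid change "X<pos>Y" or \code{NA}.
#' @return data.frame of class \code{snp_table} with a
#'   \code{mutation_class} column filled by \code{\link{classify_mutation_type}}.
#' @export
snp_table <- function(snp_id, replicon, pos, ref, alt, gene_id = NA,
                      coding_effect = NA, aa_change = NA) {
  n <- length(snp_id)
  d <- data.frame(snp_id = as.character(snp_id),
                  replicon = rep_len(as.character(replicon), n),
                  pos = rep_len(as.integer(pos), n),
                  ref = rep_len(toupper(as.character(ref)), n),
                  alt = rep_len(toupper(as.character(alt)), n),
                  gene_id = rep_len(as.character(gene_id), n),
                  coding_effect = rep_len(as.character(coding_effect), n),
                  aa_change = rep_len(as.character(aa_change), n),
                  stringsAsFactors = FALSE)
  if (nrow(d)) {
    if (any(d$ref == d$alt)) stop("SNP with ref == alt: ",
      paste(d$snp_id[d$ref == d$alt], collapse = ", "))
    if (!all(c(d$ref, d$alt) %in% c("A", "C", "G", "T")))
      stop("ref/alt must be single bases A/C/G/T")
    if (anyDuplicated(d$snp_id)) stop("duplicate snp_id")
    d$mutation_class <- classify_mutation_type(d$ref, d$alt)
  } else {
    d$mutation_class <- character()
  }
  class(d) <- c("snp_table", "data.frame")
  d
}

#' Read the bundled published 22-SNP table
#'
#' The confirmed-SNP table printed in the source study (22 PCR-verified
#' variants, 12 mutated genes, 3 intergenic sites), bundled as a plain-text
#' fixture for desk-scale reproduction of the headline counts.
#'
#' @return a \code{snp_table} with 22 rows.
#' @export
published_snp_table <- function() {
  path <- system.file("extdata", "snp_table_published.tsv",
                      package = "gutevolve", mustWork = TRUE)
  read_snp_table(path)
}

#' Read a SNP table from TSV
#'
#' @param path TSV with columns \code{snp_id, replicon, pos, ref, alt} and
#'   optionally \code{gene_id, mt} (S/N) or \code{coding_effect},
#'   \code{aa_change}.
#' @return a \code{snp_table}.
#' @export
read_snp_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  effect <- if ("coding_effect" %in% names(d)) d$coding_effect
            else if ("mt" %in% names(d))
              c(S = "synonymous", N = "nonsynonymous")[d$mt]
            else NA
  effect[is.na(effect) & is.na(d$gene_id)] <- "intergenic"
  snp_table(d$snp_id, d$replicon, d$pos, d$ref, d$alt,
            gene_id = if ("gene_id" %in% names(d)) d$gene_id else NA,
            coding_effect = effect,
            aa_change = if ("aa_change" %in% names(d)) d$aa_change else NA)
}

#' Write a SNP table as TSV or minimal VCF
#'
#' The TSV dialect mirrors the published table's column semantics; the VCF
#' dialect is a minimal 1-based VCF 4.2 with INFO keys \code{GENE}, \code{MT}
#' and \code{AAC}.
#'
#' @param snps a \code{snp_table}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return invisibly, the path.
#' @export
write_snp_table <- function(snps, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- snps
    out$mt <- c(synonymous = "S", nonsynonymous = "N")[out$coding_effect]
    out <- out[c("snp_id", "replicon", "pos", "ref", "alt", "gene_id",
                 "mt", "aa_change")]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
      "##INFO=<ID=MT,Number=1,Type=String,Description=\"Coding effect\">",
      "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino acid change\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(snps)) {
      info <- sprintf("GENE=%s;MT=%s;AAC=%s",
                      ifelse(is.na(snps$gene_id), ".", snps$gene_id),
                      ifelse(is.na(snps$coding_effect), ".", snps$coding_effect),
                      ifelse(is.na(snps$aa_change), ".", snps$aa_change))
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                         snps$replicon, snps$pos, snps$snp_id,
                         snps$ref, snps$alt, info), con)
    }
  }
  invisible(path)
}

# ---- genotype matrices ---------------------------------------------------

#' Construct a genotype matrix
#'
#' @param calls character matrix, isolates in rows, SNP ids in columns,
#'   entries in \code{"ancestral"}, \code{"derived"}, \code{"ambiguous"}.
#' @return a \code{genotype_matrix} object.
#' @export
genotype_matrix <- function(calls) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            ncol(calls) == 0L || !is.null(colnames(calls)))
  ok <- calls %in% c("ancestral", "derived", "ambiguous")
  if (!all(ok)) stop("genotype calls must be ancestral/derived/ambiguous")
  structure(list(calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d isolate(s) x %d SNP(s) (%.1f%% ambiguous)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(x$calls == "ambiguous")))
  invisible(x)
}

#' Write/read genotype matrices as TSV
#'
#' @param geno a \code{genotype_matrix}.
#' @param path TSV path (isolates in rows).
#' @return \code{write_genotypes}: the path, invisibly;
#'   \code{read_genotypes}: a \code{genotype_matrix}.
#' @export
write_genotypes <- function(geno, path) {
  d <- data.frame(isolate_id = rownames(geno$calls), geno$calls,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[-1L])
  rownames(m) <- d$isolate_id
  genotype_matrix(m)
}

# ---- isolate metadata ----------------------------------------------------

#' Construct an isolate metadata table
#'
#' @param isolate_id unique isolate ids.
#' @param host_species \code{"human"}, \code{"mouse"} or \code{"zebrafish"}.
#' @param subject_id host subject identifier.
#' @param day non-negative integer days after stopping probiotic intake.
#' @param group \code{"probiotic"}, \code{"placebo"} or \code{"invitro"}.
#' @return data.frame of class \code{isolate_metadata}.
#' @export
isolate_metadata <- function(isolate_id, host_species, subject_id, day,
                             group = "probiotic") {
  d <- data.frame(isolate_id = as.character(isolate_id),
                  host_species = as.character(host_species),
                  subject_id = as.character(subject_id),
                  day = as.integer(day),
                  group = as.character(group),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$isolate_id)) stop("duplicate isolate_id")
  if (!all(d$host_species %in% c("human", "mouse", "zebrafish")))
    stop("host_species must be human/mouse/zebrafish")
  if (any(d$day < 0L)) stop("negative day")
  if (!all(d$group %in% c("probiotic", "placebo", "invitro")))
    stop("group must be probiotic/placebo/invitro")
  class(d) <- c("isolate_metadata", "data.frame")
  d
}

# ---- pipeline configuration ---------------------------------------------

#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline, with defaults equal to the
#' published values: call quality < 60 passes, >= 7 reads on each strand,
#' major-allele frequency >= 0.90, site median coverage >= 10, isolate
#' failure fraction < 1/3, parallel-evolution window 2000 bp,
#' mobile-element presence at coverage > 0.80 and depth > 60x, absence at
#' coverage < 0.20 or depth < 60x, minimum 4 isolates per trajectory SNP.
#'
#' @param ... named overrides of individual defaults.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    quality_max = 60,          # site quality must be strictly below this
    min_strand_reads = 7L,     # per strand, both strands
    min_maf = 0.90,            # major-allele frequency
    min_median_coverage = 10,  # across isolates, missing counted as 0
    max_fail_fraction_num = 1L,   # failure fraction must be < 1/3,
    max_fail_fraction_den = 3L,   # compared exactly in rationals
    parallel_window = 2000L,   # bp, max pairwise SNP span within a gene
    presence_min_coverage = 0.80,
    absence_max_coverage = 0.20,
    presence_min_depth = 60,
    min_isolates_per_snp = 4L, # trajectory inclusion rule
    trajectory_grid_step = 0.5,  # days
    jaccard_presence_threshold = 0,  # freq > threshold => SNP in day set
    n_permutations = 999L,
    fdr_q = 0.05,
    aligner_id_core = 0.90,
    aligner_id_dedup = 0.90,
    aligner_aln_frac = 0.85,
    aligner_min_length = 100L,   # alignment-length floor (e-value proxy)
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (JSON round trip)
#'
#' @param config a \code{pipeline_config}.
#' @param path JSON path.
#' @return \code{write_config}: the path invisibly; \code{read_config}: a
#'   \code{pipeline_config} identical to the one written.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_fields <- c("min_strand_reads", "max_fail_fraction_num",
                  "max_fail_fraction_den", "parallel_window",
                  "min_isolates_per_snp", "n_permutations",
                  "aligner_min_length", "seed")
  for (f in names(raw))
    if (is.numeric(raw[[f]]))
      raw[[f]] <- if (f %in% int_fields) as.integer(raw[[f]])
                  else as.numeric(raw[[f]])
  do.call(pipeline_config, raw)
}

# ---- logging -------------------------------------------------------------

log_msg <- function(fmt, ...) {
  if (isTRUE(getOption("gutevolve.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(paste0("[gutevolve] ", fmt), ...))
}
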