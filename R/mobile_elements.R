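# Accessory-contig ("mobile element") identification and per-isolate
# presence/absence calls from read coverage and depth.

#' Default local aligner (Biostrings-based)
#'
#' Local alignment satisfying the identity / aligned-fraction contract of
#' the accessory-contig rules. Production users can inject any engine with
#' the same signature (e.g. a BLAST wrapper); this bundled default uses
#' \code{Biostrings::pairwiseAlignment} and is adequate at desk scale.
#'
#' @param query,subject character sequences.
#' @return list with \code{identity} (fraction, of the aligned region),
#'   \code{aln_length} (bases of query aligned) and \code{query_frac}
#'   (aligned fraction of the query).
#' @export
biostrings_aligner <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", gapOpening = 10, gapExtension = 0.5)
  alen <- Biostrings::nchar(Biostrings::pattern(aln))
  list(identity = Biostrings::pid(aln) / 100,
       aln_length = alen,
       query_frac = alen / nchar(query))
}

#' Identify accessory contigs (candidate mobile elements)
#'
#' Contigs shorter than 500 bp are dropped. A contig aligning to any
#' reference replicon at identity >= \code{id_core} over at least
#' \code{aln_frac} of its length (with an alignment-length floor standing
#' in for the e-value cutoff of a database search) belongs to the core
#' genome and is removed. The surviving strain-specific contigs are
#' mutually deduplicated at identity >= \code{id_dedup} over >=
#' \code{aln_frac} aligned length; the non-redundant remainder are the
#' mobile elements, ordered by decreasing length then lexicographic source.
#'
#' @param isolate_contigs named list: isolate id -> named character vector
#'   of contig sequences.
#' @param genome a \code{\link{reference_genome}}.
#' @param config a \code{\link{pipeline_config}} (fields
#'   \code{aligner_id_core, aligner_id_dedup, aligner_aln_frac,
#'   aligner_min_length}).
#' @param aligner an alignment function with the contract of
#'   \code{\link{biostrings_aligner}}.
#' @param min_length contig length floor in bp.
#' @return data.frame with one row per element: \code{element_id, length,
#'   sequence, source_isolates, n_source_contigs}.
#' @export
identify_accessory_contigs <- function(isolate_contigs, genome,
                                       config = pipeline_config(),
                                       aligner = biostrings_aligner,
                                       min_length = 500L) {
  contigs <- list()
  for (iso in sort(names(isolate_contigs))) {
    cs <- isolate_contigs[[iso]]
    cs <- cs[nchar(cs) >= min_length]
    for (k in seq_along(cs))
      contigs[[length(contigs) + 1L]] <- list(isolate = iso, seq = cs[[k]])
  }
  if (!length(contigs)) return(empty_elements())
  # alignment verdicts are cached per unique sequence; exact substrings of
  # the reference are core by definition (100% identity, full length)
  seqs <- vapply(contigs, `[[`, character(1), "seq")
  core_cache <- new.env(parent = emptyenv())
  core_of <- function(sq) {
    hit <- get0(sq, envir = core_cache)
    if (!is.null(hit)) return(hit)
    res <- any(vapply(genome$replicons, function(r)
      grepl(sq, r, fixed = TRUE), logical(1)))
    if (!res) {
      for (rep_seq in genome$replicons) {
        a <- aligner(sq, rep_seq)
        if (a$identity >= config$aligner_id_core &&
            a$query_frac >= config$aligner_aln_frac &&
            a$aln_length >= config$aligner_min_length) {
          res <- TRUE
          break
        }
      }
    }
    assign(sq, res, envir = core_cache)
    res
  }
  is_core <- vapply(seqs, core_of, logical(1), USE.NAMES = FALSE)
  acc <- contigs[!is_core]
  if (!length(acc)) return(empty_elements())
  # deterministic order: longest first, then by isolate id
  ord <- order(-vapply(acc, function(x) nchar(x$seq), numeric(1)),
               vapply(acc, `[[`, character(1), "isolate"))
  acc <- acc[ord]
  reps <- list()   # cluster representatives
  members <- list()
  for (ct in acc) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (identical(ct$seq, reps[[r]]$seq)) {
        members[[r]] <- c(members[[r]], ct$isolate)
        placed <- TRUE
        break
      }
      a <- aligner(ct$seq, reps[[r]]$seq)
      if (a$identity >= config$aligner_id_dedup &&
          a$query_frac >= config$aligner_aln_frac) {
        members[[r]] <- c(members[[r]], ct$isolate)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- ct
      members[[length(members) + 1L]] <- ct$isolate
    }
  }
  data.frame(
    element_id = sprintf("ME%03d", seq_along(reps)),
    length = vapply(reps, function(x) nchar(x$seq), numeric(1)),
    sequence = vapply(reps, `[[`, character(1), "seq"),
    source_isolates = vapply(members, function(m)
      paste(sort(unique(m)), collapse = ","), character(1)),
    n_source_contigs = lengths(members),
    stringsAsFactors = FALSE)
}

empty_elements <- function() {
  data.frame(element_id = character(), length = numeric(),
             sequence = character(), source_isolates = character(),
             n_source_contigs = integer(), stringsAsFactors = FALSE)
}

#' Presence/absence call for a mobile element in one isolate
#'
#' Present iff coverage > 0.80 and depth > 60x; absent iff coverage < 0.20
#' or depth < 60x, with the absent rule winning when both apply; any other
#' combination (e.g. intermediate coverage at high depth) satisfies neither
#' printed rule and is called \code{ambiguous} rather than silently forced
#' to a binary call. Vectorised.
#'
#' @param coverage_fraction fraction of the element covered by reads, in
#'   [0, 1].
#' @param mean_depth mean read depth over the element, >= 0.
#' @param config a \code{\link{pipeline_config}}.
#' @return character vector in \code{present/absent/ambiguous}.
#' @export
call_presence <- function(coverage_fraction, mean_depth,
                          config = pipeline_config()) {
  stopifnot(all(coverage_fraction >= 0 & coverage_fraction <= 1),
            all(mean_depth >= 0))
  absent <- coverage_fraction < config$absence_max_coverage |
    mean_depth < config$presence_min_depth
  present <- coverage_fraction > config$presence_min_coverage &
    mean_depth > config$presence_min_depth
  ifelse(absent, "absent", ifelse(present, "present", "ambiguous"))
}

#' Mobile-element presence trajectories per host and day
#'
#' Per element, host species and day: the fraction of isolates with a
#' definite call that are present. Days where every isolate is ambiguous
#' are reported as missing (NA), not zero. A log10 mean-depth series is
#' included for plotting.
#'
#' @param evidence data.frame with columns \code{element_id, isolate_id,
#'   coverage_fraction, mean_depth} (one row per element x isolate).
#' @param metadata an \code{\link{isolate_metadata}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame with columns \code{element_id, host_species, day,
#'   n_isolates, n_present, n_absent, n_ambiguous, frequency,
#'   log10_mean_depth}.
#' @export
element_trajectory <- function(evidence, metadata,
                               config = pipeline_config()) {
  evidence$state <- call_presence(evidence$coverage_fraction,
                                  evidence$mean_depth, config)
  m <- merge(evidence, metadata, by = "isolate_id")
  groups <- unique(m[c("element_id", "host_species", "day")])
  groups <- groups[order(groups$element_id, groups$host_species, groups$day), ]
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    sub <- m[m$element_id == groups$element_id[k] &
             m$host_species == groups$host_species[k] &
             m$day == groups$day[k], ]
    n_p <- sum(sub$state == "present")
    n_a <- sum(sub$state == "absent")
    data.frame(groups[k, ], n_isolates = nrow(sub), n_present = n_p,
               n_absent = n_a, n_ambiguous = sum(sub$state == "ambiguous"),
               frequency = if (n_p + n_a > 0L) n_p / (n_p + n_a) else NA_real_,
               log10_mean_depth = log10(mean(sub$mean_depth) + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
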