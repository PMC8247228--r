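# SNP distance matrices, ancestor-rooted neighbor-joining trees, dMRCA and
# the six-class mutation spectrum.

#' Pairwise SNP distances between isolates
#'
#' The distance between two isolates is the number of SNP positions at
#' which both carry an unambiguous call and the calls differ; positions
#' ambiguous in either isolate are excluded and the per-pair count of
#' comparable positions is recorded.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param include_ancestor add a pseudo-isolate \code{"ancestor"} that is
#'   ancestral at every SNP (used to root trees).
#' @return list with \code{d} (symmetric numeric matrix), \code{comparable}
#'   (matrix of comparable-position counts; pairs with zero comparable
#'   positions have distance \code{NA}).
#' @export
pairwise_snp_distance <- function(geno, include_ancestor = FALSE) {
  calls <- geno$calls
  if (include_ancestor) {
    anc <- matrix("ancestral", 1L, ncol(calls),
                  dimnames = list("ancestor", colnames(calls)))
    calls <- rbind(calls, anc)
  }
  n <- nrow(calls)
  if (n < 2L) stop("need >= 2 isolates")
  derived <- calls == "derived"
  known <- calls != "ambiguous"
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  comp <- matrix(ncol(calls), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- known[i, ] & known[j, ]
    comp[i, j] <- comp[j, i] <- sum(both)
    d[i, j] <- d[j, i] <-
      if (any(both)) sum(derived[i, both] != derived[j, both]) else NA_real_
  }
  diag(comp) <- ncol(calls)
  list(d = d, comparable = comp)
}

#' Neighbor-joining tree rooted on the ancestral strain
#'
#' Standard NJ agglomeration (via \code{ape::nj}) on the pairwise SNP
#' distance matrix, rooted on the \code{"ancestor"} leaf; negative NJ
#' branch lengths are clamped to zero and the clamped deficit is recorded.
#' Fewer than 3 taxa yield the trivial 2-leaf tree.
#'
#' @param dist_result output of \code{\link{pairwise_snp_distance}} (or any
#'   list with a symmetric matrix \code{$d}); no \code{NA} distances allowed.
#' @param root_on_ancestor root the tree on the \code{"ancestor"} leaf if
#'   present.
#' @return list with \code{tree} (an \code{ape::phylo}) and
#'   \code{clamped_length} (total negative branch length set to zero).
#' @export
build_nj_tree <- function(dist_result, root_on_ancestor = TRUE) {
  d <- dist_result$d
  if (any(is.na(d))) stop("undefined (NA) distances; cannot build NJ tree")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  if (n == 2L) {
    tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
      rownames(d)[1L], d[1, 2] / 2, rownames(d)[2L], d[1, 2] / 2))
    return(list(tree = tree, clamped_length = 0))
  }
  tree <- ape::nj(stats::as.dist(d))
  clamped <- sum(pmin(tree$edge.length, 0))
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (root_on_ancestor && "ancestor" %in% tree$tip.label)
    tree <- ape::root(tree, outgroup = "ancestor", resolve.root = TRUE)
  list(tree = tree, clamped_length = -clamped)
}

#' Write a tree to newick
#'
#' @param tree an \code{ape::phylo} (or the list returned by
#'   \code{\link{build_nj_tree}}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Mean distance to the most recent common ancestor (dMRCA)
#'
#' Restricted to SNP positions that are polymorphic among the isolates of
#' the given subset (both ancestral and derived calls observed; ambiguous
#' calls are excluded from both the polymorphism determination and the
#' per-isolate counts), counts the derived alleles per isolate and returns
#' the mean. A single-isolate subset has no within-subset polymorphism and
#' returns 0.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param isolates non-empty character vector of isolate ids.
#' @return a single number.
#' @export
dmrca <- function(geno, isolates = rownames(geno$calls)) {
  if (!length(isolates)) stop("empty isolate subset")
  missing_iso <- setdiff(isolates, rownames(geno$calls))
  if (length(missing_iso)) stop("unknown isolate(s): ",
                                paste(missing_iso, collapse = ", "))
  calls <- geno$calls[isolates, , drop = FALSE]
  poly <- apply(calls, 2, function(col)
    any(col == "derived") && any(col == "ancestral"))
  if (!any(poly)) return(0)
  mean(rowSums(calls[, poly, drop = FALSE] == "derived"))
}

#' dMRCA per host model and sampling day
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param metadata an \code{\link{isolate_metadata}} covering the isolates.
#' @return data.frame with columns \code{host_species, day, n_isolates,
#'   dmrca}.
#' @export
dmrca_by_timepoint <- function(geno, metadata) {
  metadata <- metadata[metadata$isolate_id %in% rownames(geno$calls), ]
  groups <- unique(metadata[c("host_species", "day")])
  groups <- groups[order(groups$host_species, groups$day), , drop = FALSE]
  groups$n_isolates <- NA_integer_
  groups$dmrca <- NA_real_
  for (k in seq_len(nrow(groups))) {
    ids <- metadata$isolate_id[metadata$host_species == groups$host_species[k] &
                               metadata$day == groups$day[k]]
    groups$n_isolates[k] <- length(ids)
    groups$dmrca[k] <- dmrca(geno, ids)
  }
  rownames(groups) <- NULL
  groups
}

#' Six-class mutation spectrum, per host, with mean and SD across hosts
#'
#' Under \code{per_snp} weighting each SNP contributes once to its class;
#' under \code{per_isolate} weighting each SNP is weighted by the number of
#' isolates carrying its derived allele (a genotype matrix is then
#' required). When metadata is supplied the tally is computed per host
#' species and the per-class mean and standard deviation across hosts are
#' reported; otherwise a single pooled tally is returned.
#'
#' @param snps a \code{\link{snp_table}}.
#' @param weighting \code{"per_snp"} or \code{"per_isolate"}.
#' @param geno genotype matrix (required for \code{per_isolate}).
#' @param metadata optional \code{\link{isolate_metadata}}; for
#'   \code{per_snp} weighting, hosts are taken from \code{hosts} instead.
#' @param hosts optional named list host -> character vector of snp_ids
#'   observed in that host (per-host scoping for \code{per_snp}).
#' @return list with \code{per_host} (matrix hosts x 6 classes),
#'   \code{mean}, \code{sd} (named 6-vectors) and \code{pooled} (6-vector).
#' @export
mutation_spectrum <- function(snps, weighting = c("per_snp", "per_isolate"),
                              geno = NULL, metadata = NULL, hosts = NULL) {
  weighting <- match.arg(weighting)
  cls <- mutation_classes()
  tally <- function(ids, weights) {
    v <- setNames(numeric(6L), cls)
    if (length(ids)) {
      w <- tapply(weights, factor(snps$mutation_class[match(ids, snps$snp_id)],
                                  levels = cls), sum)
      w[is.na(w)] <- 0
      v[] <- w
    }
    v
  }
  weight_of <- function(ids, iso_subset = NULL) {
    if (weighting == "per_snp") return(rep(1, length(ids)))
    if (is.null(geno)) stop("per_isolate weighting requires a genotype matrix")
    calls <- geno$calls
    if (!is.null(iso_subset)) calls <- calls[iso_subset, , drop = FALSE]
    colSums(calls[, ids, drop = FALSE] == "derived")
  }
  all_ids <- snps$snp_id
  pooled <- tally(all_ids, weight_of(all_ids))
  per_host <- NULL
  if (!is.null(metadata) && !is.null(geno)) {
    host_names <- sort(unique(metadata$host_species))
    per_host <- matrix(0, length(host_names), 6L,
                       dimnames = list(host_names, cls))
    for (h in host_names) {
      iso <- metadata$isolate_id[metadata$host_species == h]
      iso <- intersect(iso, rownames(geno$calls))
      observed <- all_ids[colSums(
        geno$calls[iso, all_ids, drop = FALSE] == "derived") > 0L]
      w <- if (weighting == "per_snp") rep(1, length(observed)) else
        weight_of(observed, iso)
      per_host[h, ] <- tally(observed, w)
    }
  } else if (!is.null(hosts)) {
    per_host <- t(vapply(hosts, function(ids) tally(ids, weight_of(ids)),
                         numeric(6L)))
    colnames(per_host) <- cls
  }
  res <- list(pooled = pooled, per_host = per_host)
  if (!is.null(per_host)) {
    res$mean <- colMeans(per_host)
    res$sd <- apply(per_host, 2, sd)
  }
  res
}
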