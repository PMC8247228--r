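# SNP-frequency trajectories, lineage nesting from genotype data, Muller
# parent/child decomposition, and cross-host trajectory comparison.

#' Per-day derived-allele frequencies of SNPs
#'
#' SNPs whose derived allele is observed in fewer than
#' \code{min_isolates} isolates overall are dropped (reproducibility rule).
#' For each retained SNP and sampling day, frequency = derived isolates /
#' isolates with an unambiguous call that day; days with no isolates yield
#' no observation and are left to the interpolant.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param metadata an \code{\link{isolate_metadata}}.
#' @param min_isolates minimum derived-isolate count (default 4).
#' @param scope \code{"pooled"} (all isolates), \code{"host"} or
#'   \code{"subject"}.
#' @return data.frame with columns \code{snp_id, scope, day, n_called,
#'   n_derived, frequency}; \code{scope} is \code{"all"}, the host species
#'   or the subject id.
#' @export
snp_frequencies <- function(geno, metadata, min_isolates = 4L,
                            scope = c("pooled", "host", "subject")) {
  scope <- match.arg(scope)
  metadata <- metadata[metadata$isolate_id %in% rownames(geno$calls), ]
  calls <- geno$calls[metadata$isolate_id, , drop = FALSE]
  keep <- colSums(calls == "derived") >= min_isolates
  calls <- calls[, keep, drop = FALSE]
  scope_of <- switch(scope,
    pooled = rep("all", nrow(metadata)),
    host = metadata$host_species,
    subject = metadata$subject_id)
  groups <- unique(data.frame(scope = scope_of, day = metadata$day,
                              stringsAsFactors = FALSE))
  groups <- groups[order(groups$scope, groups$day), , drop = FALSE]
  rows <- list()
  for (id in colnames(calls)) {
    for (k in seq_len(nrow(groups))) {
      sel <- scope_of == groups$scope[k] & metadata$day == groups$day[k]
      cc <- calls[sel, id]
      n_called <- sum(cc != "ambiguous")
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = id, scope = groups$scope[k], day = groups$day[k],
        n_called = n_called, n_derived = sum(cc == "derived"),
        frequency = if (n_called) sum(cc == "derived") / n_called
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(snp_id = character(),
    scope = character(), day = integer(), n_called = integer(),
    n_derived = integer(), frequency = numeric(), stringsAsFactors = FALSE)
  out
}

#' Monotone-preserving piecewise-cubic Bezier interpolation of a trajectory
#'
#' Fits one cubic Bezier segment per interval through the observed points,
#' with Catmull-Rom-derived handles clamped for monotonicity
#' (Fritsch-Carlson limiting): the curve passes exactly through every
#' observation, preserves monotone runs, and is clamped to [0, 1]. A single
#' observation yields a constant curve with a warning.
#'
#' @param days numeric vector of observation days (strictly increasing
#'   after NA-frequency removal).
#' @param freqs observed frequencies in [0, 1] (NA observations dropped).
#' @param grid_step evaluation step in days.
#' @return data.frame with columns \code{day, frequency}; evaluation points
#'   are the regular grid plus the observation days.
#' @export
interpolate_trajectory <- function(days, freqs, grid_step = 0.5) {
  ok <- !is.na(freqs)
  days <- days[ok]; freqs <- freqs[ok]
  o <- order(days)
  days <- days[o]; freqs <- freqs[o]
  if (length(days) == 0L) stop("no observations to interpolate")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  if (length(days) == 1L) {
    warning("single observation; returning a constant trajectory")
    return(data.frame(day = days, frequency = freqs))
  }
  grid <- sort(unique(c(seq(min(days), max(days), by = grid_step), days)))
  n <- length(days)
  h <- diff(days)
  delta <- diff(freqs) / h
  # Catmull-Rom tangents, one-sided at the boundary
  m <- numeric(n)
  m[1] <- delta[1]
  m[n] <- delta[n - 1L]
  if (n > 2L)
    m[2:(n - 1L)] <- (freqs[3:n] - freqs[1:(n - 2L)]) /
      (days[3:n] - days[1:(n - 2L)])
  # Fritsch-Carlson monotonicity limiting
  for (i in seq_len(n - 1L)) {
    if (delta[i] == 0) {
      m[i] <- m[i + 1L] <- 0
    } else {
      if (sign(m[i]) != sign(delta[i])) m[i] <- 0
      if (sign(m[i + 1L]) != sign(delta[i])) m[i + 1L] <- 0
      if (abs(m[i]) > 3 * abs(delta[i])) m[i] <- 3 * delta[i]
      if (abs(m[i + 1L]) > 3 * abs(delta[i])) m[i + 1L] <- 3 * delta[i]
    }
  }
  # evaluate each interval's cubic Bezier (Hermite form with control
  # points P1 = y0 + m0 h/3, P2 = y1 - m1 h/3)
  interval <- pmin(pmax(findInterval(grid, days), 1L), n - 1L)
  t <- (grid - days[interval]) / h[interval]
  y0 <- freqs[interval]; y1 <- freqs[interval + 1L]
  p1 <- y0 + m[interval] * h[interval] / 3
  p2 <- y1 - m[interval + 1L] * h[interval] / 3
  val <- (1 - t)^3 * y0 + 3 * (1 - t)^2 * t * p1 +
    3 * (1 - t) * t^2 * p2 + t^3 * y1
  val <- pmin(pmax(val, 0), 1)
  # exactness at observations, immune to rounding
  val[match(days, grid)] <- freqs
  data.frame(day = grid, frequency = val)
}

#' Nest SNP-defined lineages by derived-isolate-set inclusion
#'
#' SNPs with identical derived-isolate sets define one sublineage (they
#' travel on one branch); sublineages are ordered by strict inclusion of
#' their isolate sets into a tree. Pairs of sublineages whose isolate sets
#' overlap without nesting violate the clonal-tree assumption: the
#' conflicting isolates are reported and removed from the smaller set
#' (majority assignment), and if they exceed \code{conflict_threshold} of
#' all isolates the function stops and demands manual curation. Sublineage
#' names follow the E-notation: roots E1, E2, ...; children E1-A, E1-B;
#' grandchildren E1-B-1, E1-B-2; and so on, siblings ordered by decreasing
#' isolate count then SNP id.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param conflict_threshold maximum tolerated fraction of isolates in
#'   nesting conflicts (default 0.10).
#' @return an object of class \code{lineage_tree}: list with \code{nodes}
#'   (data.frame \code{lineage_id, parent, snp_ids, n_isolates}),
#'   \code{isolates} (named list lineage -> isolate ids, cumulative),
#'   and \code{conflicts} (data.frame of removed assignments).
#' @export
nest_lineages <- function(geno, conflict_threshold = 0.10) {
  calls <- geno$calls
  snp_ids <- colnames(calls)
  derived <- lapply(snp_ids, function(id)
    rownames(calls)[calls[, id] == "derived"])
  known <- lapply(snp_ids, function(id)
    rownames(calls)[calls[, id] != "ambiguous"])
  names(derived) <- names(known) <- snp_ids
  has <- lengths(derived) > 0L
  derived <- derived[has]; known <- known[has]
  if (!length(derived)) stop("no derived calls; nothing to nest")
  # group SNPs whose derived sets agree on all jointly unambiguous
  # isolates (same branch up to missing calls); union-find
  ids <- names(derived)
  comp <- seq_along(ids)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    both <- intersect(known[[i]], known[[j]])
    if (setequal(intersect(derived[[i]], both),
                 intersect(derived[[j]], both)) &&
        length(intersect(derived[[i]], both)) > 0L)
      comp[find(j)] <- find(i)
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  node_snps <- split(ids, roots)
  node_sets <- lapply(node_snps, function(s)
    sort(unique(unlist(derived[s]))))
  names(node_sets) <- names(node_snps) <- NULL
  # conflict detection and majority resolution
  conflicts <- list()
  n_iso_total <- nrow(calls)
  repeat {
    changed <- FALSE
    for (i in seq_along(node_sets)) for (j in seq_along(node_sets)) {
      if (i >= j) next
      a <- node_sets[[i]]; b <- node_sets[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !all(a %in% b) && !all(b %in% a)) {
        small <- if (length(a) <= length(b)) i else j
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          lineage = paste(node_snps[[small]], collapse = ","),
          isolate_id = inter, stringsAsFactors = FALSE)
        node_sets[[small]] <- setdiff(node_sets[[small]], inter)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(lineage = character(), isolate_id = character(),
               stringsAsFactors = FALSE)
  if (length(unique(conflicts$isolate_id)) > conflict_threshold * n_iso_total)
    stop("nesting conflicts affect > ", round(100 * conflict_threshold),
         "% of isolates; manual curation required")
  keep <- lengths(node_sets) > 0L
  node_sets <- node_sets[keep]; node_snps <- node_snps[keep]
  # parent = smallest strict superset
  nn <- length(node_sets)
  parent_idx <- rep(NA_integer_, nn)
  for (i in seq_len(nn)) {
    supers <- which(vapply(seq_len(nn), function(j)
      j != i && all(node_sets[[i]] %in% node_sets[[j]]) &&
        length(node_sets[[j]]) > length(node_sets[[i]]), logical(1)))
    if (length(supers))
      parent_idx[i] <- supers[which.min(lengths(node_sets)[supers])]
  }
  # deterministic sibling order: decreasing size, then first SNP id
  ord_key <- order(-lengths(node_sets),
                   vapply(node_snps, function(s) sort(s)[1L], character(1)))
  names_out <- rep(NA_character_, nn)
  assign_names <- function(parent, prefix, depth) {
    kids <- ord_key[ord_key %in% which(
      if (is.na(parent)) is.na(parent_idx) else parent_idx == parent)]
    labels <- if (depth == 0L) paste0("E", seq_along(kids))
      else if (depth %% 2L == 1L) paste0(prefix, "-", LETTERS[seq_along(kids)])
      else paste0(prefix, "-", seq_along(kids))
    for (k in seq_along(kids)) {
      names_out[kids[k]] <<- labels[k]
      assign_names(kids[k], labels[k], depth + 1L)
    }
  }
  assign_names(NA, "", 0L)
  nodes <- data.frame(
    lineage_id = names_out,
    parent = ifelse(is.na(parent_idx), NA_character_, names_out[parent_idx]),
    snp_ids = vapply(node_snps, function(s) paste(sort(s), collapse = ","),
                     character(1)),
    n_isolates = lengths(node_sets),
    stringsAsFactors = FALSE)
  o <- order(nodes$lineage_id)
  isolates <- setNames(node_sets, names_out)[o]
  nodes <- nodes[o, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, isolates = isolates, conflicts = conflicts),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d sublineage(s), %d nesting conflict(s)\n",
              nrow(x$nodes), nrow(x$conflicts)))
  print(x$nodes[c("lineage_id", "parent", "n_isolates")], row.names = FALSE)
  invisible(x)
}

#' Raw per-day lineage frequencies
#'
#' The raw (cumulative) frequency of a sublineage on a day is the fraction
#' of that day's isolates belonging to the sublineage or any of its
#' descendants — i.e. carrying the sublineage's defining SNPs.
#'
#' @param lt a \code{\link{nest_lineages}} result.
#' @param metadata an \code{\link{isolate_metadata}}.
#' @param host optional host species to restrict to (default: pooled).
#' @return data.frame with columns \code{lineage_id, day, n_isolates, raw}.
#' @export
lineage_frequencies <- function(lt, metadata, host = NULL) {
  if (!is.null(host))
    metadata <- metadata[metadata$host_species %in% host, , drop = FALSE]
  days <- sort(unique(metadata$day))
  rows <- list()
  for (lid in lt$nodes$lineage_id) {
    members <- lt$isolates[[lid]]
    for (d in days) {
      iso_day <- metadata$isolate_id[metadata$day == d]
      if (!length(iso_day)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lineage_id = lid, day = d, n_isolates = length(iso_day),
        raw = mean(iso_day %in% members), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Muller decomposition: exclusive sublineage frequencies
#'
#' Per day, the exclusive frequency of a parent sublineage is its raw
#' frequency minus the summed raw frequencies of its children, clamped at
#' zero when the children sum beyond the parent; leaves keep their raw
#' frequency. The output table feeds a stacked Muller plot directly.
#'
#' @param freq data.frame with columns \code{lineage_id, day, raw} (from
#'   \code{\link{lineage_frequencies}}, or any raw table).
#' @param nodes data.frame with columns \code{lineage_id, parent}; if
#'   omitted every lineage is treated as a leaf.
#' @return the input with an added \code{exclusive} column.
#' @export
muller_decompose <- function(freq, nodes = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(lineage_id = unique(freq$lineage_id),
                        parent = NA_character_, stringsAsFactors = FALSE)
  freq$exclusive <- freq$raw
  for (k in seq_len(nrow(freq))) {
    kids <- nodes$lineage_id[!is.na(nodes$parent) &
                             nodes$parent == freq$lineage_id[k]]
    if (!length(kids)) next
    kid_sum <- sum(freq$raw[freq$lineage_id %in% kids &
                            freq$day == freq$day[k]])
    freq$exclusive[k] <- max(0, freq$raw[k] - kid_sum)
  }
  freq
}

#' Compare lineage/SNP trajectory dynamics between two hosts (Mantel test)
#'
#' Builds, for each host, a Jaccard distance matrix between time points
#' over the sets of SNPs/lineages segregating there (a label is in a day's
#' set if its frequency exceeds \code{threshold}), then computes the Mantel
#' correlation between the two matrices with a permutation p-value
#' (seed-deterministic).
#'
#' @param freq_a,freq_b data.frames with columns \code{lineage_id} (or
#'   \code{snp_id}), \code{day}, and a frequency column (\code{raw} or
#'   \code{frequency}); both hosts must share the label set and time grid.
#' @param threshold presence threshold on the frequency (default 0: any
#'   nonzero frequency counts).
#' @param n_permutations Mantel permutations.
#' @param seed RNG seed.
#' @return list with \code{mantel_r}, \code{p_value},
#'   \code{n_permutations}; \code{mantel_r} is NA with a note when either
#'   distance matrix is constant (degenerate).
#' @export
compare_host_dynamics <- function(freq_a, freq_b, threshold = 0,
                                  n_permutations = 999L, seed = 1L) {
  inc <- function(freq) {
    lab_col <- if ("lineage_id" %in% names(freq)) "lineage_id" else "snp_id"
    f_col <- if ("raw" %in% names(freq)) "raw" else "frequency"
    labs <- sort(unique(freq[[lab_col]]))
    days <- sort(unique(freq$day))
    m <- matrix(0L, length(days), length(labs),
                dimnames = list(days, labs))
    sel <- !is.na(freq[[f_col]]) & freq[[f_col]] > threshold
    m[cbind(match(freq$day[sel], days), match(freq[[lab_col]][sel], labs))] <- 1L
    m
  }
  ma <- inc(freq_a); mb <- inc(freq_b)
  if (!identical(dimnames(ma)[[2]], dimnames(mb)[[2]]) ||
      !identical(dimnames(ma)[[1]], dimnames(mb)[[1]]))
    stop("hosts must share the label set and time grid")
  # a day with no segregating labels yields NA dissimilarities, caught
  # below as the degenerate case; few time points trigger vegan's complete
  # permutation enumeration, which is exactly what we want
  da <- suppressWarnings(vegan::vegdist(ma, method = "jaccard", binary = TRUE))
  db <- suppressWarnings(vegan::vegdist(mb, method = "jaccard", binary = TRUE))
  if (stats::sd(da) == 0 || stats::sd(db) == 0 ||
      any(is.na(da)) || any(is.na(db)))
    return(list(mantel_r = NA_real_, p_value = NA_real_,
                n_permutations = n_permutations,
                note = "degenerate (constant) distance matrix"))
  set.seed(seed)
  mt <- suppressMessages(suppressWarnings(
    vegan::mantel(da, db, permutations = n_permutations)))
  list(mantel_r = unname(mt$statistic), p_value = mt$signif,
       n_permutations = n_permutations)
}
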