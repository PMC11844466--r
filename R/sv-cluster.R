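# Copy-number-aware genotyping of complex CNV regions (IGHG4-style):
# extract region haplotypes with flanks via liftover, bin by copy
# number/length, compute pairwise distances within bins, cluster
# hierarchically with a distance cutoff, and genotype donors by cluster.

#' Extract a region haplotype (with flanks) from an assembly contig
#'
#' Lifts both flank anchors onto the contig through its alignment chains and
#' returns the intervening contig subsequence, orientation-normalized to the
#' reference strand. Returns NULL when either anchor is unliftable (e.g. the
#' contig ends inside the region).
#'
#' @param contig contig sequence.
#' @param chains chains of this contig against the reference
#'   (from [align_contig()]).
#' @param region integer c(start, end) of the CNV region on the reference.
#' @param flank flank length in bases (default 5000).
#' @param unit duplicated-block unit length for copy-number quantization
#'   (default: region length).
#' @param donor_id,haplotype_index bookkeeping labels.
#' @return object of class `region_haplotype` (donor_id, haplotype_index,
#'   seq, ref_span, copy_number_estimate, length_bin), or NULL.
#' @export
extract_sv_region <- function(contig, chains, region, flank = 5000L,
                              unit = NULL, donor_id = "donor",
                              haplotype_index = 1L) {
  left <- region[1] - flank
  right <- region[2] + flank
  if (left < 1L) stop("region/flank outside reference", call. = FALSE)
  lifts <- function(t1) {
    out <- list()
    for (ch in chains) {
      q <- liftover(c(t1, t1), ch, "ref2query")
      if (!is.null(q)) out[[length(out) + 1L]] <- list(q = q[1], strand = ch$strand)
    }
    out
  }
  la <- lifts(left); ra <- lifts(right)
  if (length(la) == 0L || length(ra) == 0L) return(NULL)
  # an anchor can lift more than once when the region recurs in the contig
  # (e.g. a dispersed multi-gene duplication): take the tightest same-strand
  # pairing so one region copy is extracted, not the span across copies
  best <- NULL
  for (l1 in la) for (r1 in ra) {
    if (l1$strand != r1$strand) next
    span <- abs(r1$q - l1$q) + 1L
    if (span < region[2] - region[1] + 1L) next
    if (is.null(best) || span < best$span)
      best <- list(qa = l1$q, qb = r1$q, strand = l1$strand, span = span)
  }
  if (is.null(best)) return(NULL)
  qa <- best$qa; qb <- best$qb; strand <- best$strand
  s <- substr(contig, min(qa, qb), max(qa, qb))
  if (strand == "-") s <- revcomp(s)
  ref_span <- right - left + 1L
  unit <- unit %||% (region[2] - region[1] + 1L)
  cn <- as.integer(round((nchar(s) - ref_span) / unit)) + 1L
  structure(list(donor_id = donor_id, haplotype_index = as.integer(haplotype_index),
                 id = sprintf("%s_h%d", donor_id, haplotype_index),
                 seq = s, ref_span = ref_span,
                 copy_number_estimate = cn, length_bin = sprintf("cn%d", cn)),
            class = "region_haplotype")
}

p_distance <- function(a, b) {
  if (a == b) return(0)
  if (nchar(a) == nchar(b)) return(mean(utf8ToInt(a) != utf8ToInt(b)))
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = nw_submat(),
                                      gapOpening = 4, gapExtension = 1)
  x <- utf8ToInt(as.character(Biostrings::alignedPattern(pa)))
  y <- utf8ToInt(as.character(Biostrings::alignedSubject(pa)))
  gap <- utf8ToInt("-")
  both <- x != gap & y != gap
  if (!any(both)) return(1)
  mean(x[both] != y[both])
}

#' Pairwise distance matrix of region haplotypes (length-binned)
#'
#' Haplotypes are first binned by copy-number/length class; within a bin the
#' distance is the gap-excluded p-distance of a pairwise global alignment
#' (plain Hamming p-distance for equal-length pairs). Cross-bin distances
#' are set to the sentinel 1.0 so different copy-number classes never merge.
#'
#' @param region_haplotypes list of `region_haplotype`s (>= 2).
#' @param cross_bin_distance sentinel distance between bins (default 1).
#' @return list: `matrix` (symmetric, zero diagonal), `bins` (named bin labels).
#' @export
region_distances <- function(region_haplotypes, cross_bin_distance = 1) {
  n <- length(region_haplotypes)
  if (n < 2L) stop("need at least two region haplotypes", call. = FALSE)
  ids <- vapply(region_haplotypes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate region haplotype ids", call. = FALSE)
  seqs <- vapply(region_haplotypes, `[[`, "", "seq")
  if (any(nchar(seqs) == 0L)) stop("empty region haplotype sequence", call. = FALSE)
  bins <- vapply(region_haplotypes, `[[`, "", "length_bin")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- if (bins[i] != bins[j]) cross_bin_distance else p_distance(seqs[i], seqs[j])
    m[i, j] <- d; m[j, i] <- d
  }
  list(matrix = m, bins = stats::setNames(bins, ids))
}

#' Hierarchically cluster region haplotypes at a distance cutoff
#'
#' Agglomerative clustering (default average linkage); the tree is cut at
#' `cutoff` and clusters are relabelled deterministically by decreasing size,
#' ties broken by smallest member id, so labels are invariant to input
#' permutation.
#'
#' @param dist either the list returned by [region_distances()] or a
#'   symmetric matrix with zero diagonal.
#' @param cutoff tree cut height (default 0.1).
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @return object of class `cluster_assignment`: `assignments` data.frame
#'   (id, cluster), `matrix`, `cutoff`, `linkage`, `n_clusters`.
#' @export
cluster_region_haplotypes <- function(dist, cutoff = 0.1, linkage = "average") {
  m <- if (is.list(dist) && !is.null(dist$matrix)) dist$matrix else dist
  if (any(is.na(m))) stop("NaN distances", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric", call. = FALSE)
  ids <- rownames(m)
  if (nrow(m) == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = linkage)
    cl <- stats::cutree(hc, h = cutoff)
  }
  # deterministic relabelling: size desc, then smallest member id
  key <- vapply(split(ids, cl), function(members)
    sprintf("%09d|%s", 1e9 - length(members), min(members)), "")
  new_lab <- stats::setNames(seq_along(key), names(key)[order(key)])
  relab <- new_lab[as.character(cl)]
  structure(list(assignments = data.frame(id = ids, cluster = as.integer(relab),
                                          stringsAsFactors = FALSE),
                 matrix = m, cutoff = cutoff, linkage = linkage,
                 n_clusters = length(unique(relab))),
            class = "cluster_assignment")
}

#' Genotype donors by region-haplotype cluster and tabulate frequencies
#'
#' @param assignment a `cluster_assignment` over haplotype ids of the form
#'   `<donor>_h<index>` (or provide `donor_map`).
#' @param donor_map optional data.frame(id, donor) overriding id parsing.
#' @param labels data.frame(donor, population).
#' @return list: `diplotypes` data.frame(donor, cluster1, cluster2) with the
#'   unordered cluster pair per donor, and `frequencies` (population x
#'   cluster, rows summing to 1 over observed haplotypes).
#' @export
genotype_clusters <- function(assignment, labels, donor_map = NULL) {
  a <- assignment$assignments
  if (is.null(donor_map))
    donor_map <- data.frame(id = a$id, donor = sub("_h[0-9]+$", "", a$id),
                            stringsAsFactors = FALSE)
  a$donor <- donor_map$donor[match(a$id, donor_map$id)]
  dips <- lapply(split(a, a$donor), function(d) {
    if (nrow(d) > 2L) stop("donor with more than two region haplotypes: ",
                           d$donor[1], call. = FALSE)
    cl <- sort(d$cluster)
    data.frame(donor = d$donor[1], cluster1 = cl[1],
               cluster2 = if (length(cl) > 1L) cl[2] else NA_integer_)
  })
  dips <- do.call(rbind, dips)
  rownames(dips) <- NULL
  a$population <- labels$population[match(a$donor, labels$donor)]
  tab <- table(a$population, a$cluster)
  freq <- sweep(tab, 1, rowSums(tab), "/")
  list(diplotypes = dips, frequencies = as.matrix(freq))
}
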