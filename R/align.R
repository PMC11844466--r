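# Toy-scale contig-to-reference alignment: anchoring on reference-unique
# k-mers, collinear chaining per strand, gap closure by global alignment,
# and exact-match X-drop end extension. Paralog copies carry at least one
# planted difference per kb, so unique 31-mers anchor each copy distinctly
# without seed-chain-extend machinery.
#
# Chain structure (class "alignment_chain"):
#   query_id, target_id, strand,
#   blocks: data.frame(qs, qe, ts, te, nmis) -- gapless aligned segments,
#     query coords always contig-forward; within-block mapping is
#     t = ts + (p - qs) on '+' and t = ts + (qe - p) on '-';
#   mismatches: data.frame(tpos, qpos, ref, alt).

new_chain <- function(query_id, target_id, strand, blocks, mismatches) {
  blocks <- blocks[order(blocks$ts), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(query_id = query_id, target_id = target_id, strand = strand,
                 blocks = blocks, mismatches = mismatches,
                 qstart = min(blocks$qs), qend = max(blocks$qe),
                 tstart = min(blocks$ts), tend = max(blocks$te)),
            class = "alignment_chain")
}

empty_mismatches <- function() {
  data.frame(tpos = integer(), qpos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("<chain %s->%s %s q[%d,%d] t[%d,%d] blocks=%d edits=%d>\n",
              x$query_id, x$target_id, x$strand, x$qstart, x$qend,
              x$tstart, x$tend, nrow(x$blocks), sum(x$blocks$nmis)))
  invisible(x)
}

#' Index the unique k-mers of a reference sequence
#'
#' K-mers occurring more than once in the target are discarded, so anchors
#' are position-unambiguous even across high-identity paralog blocks.
#'
#' @param seq character scalar or `locus_reference`.
#' @param k k-mer length (default 31).
#' @param id target id recorded in chains.
#' @return object of class `kmer_index`.
#' @export
kmer_index <- function(seq, k = 31L, id = NULL) {
  if (inherits(seq, "locus_reference")) {
    id <- id %||% seq$id
    seq <- seq$seq
  }
  id <- id %||% "target"
  stop_if_not_scalar_seq(seq)
  n <- nchar(seq)
  starts <- seq_len(max(0L, n - k + 1L))
  kmers <- substring(seq, starts, starts + k - 1L)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  structure(list(id = id, seq = seq, n = n, k = as.integer(k),
                 kmers = kmers[!dup], pos = starts[!dup]),
            class = "kmer_index")
}

as_kmer_index <- function(reference, k = 31L) {
  if (inherits(reference, "kmer_index")) reference else kmer_index(reference, k = k)
}

# exact-match-biased X-drop extension; returns number of bases to extend
xdrop_extend <- function(qb, tb, qpos, tpos, dir, limit, mis_pen = 3L) {
  m <- if (dir < 0L) min(qpos - 1L, tpos - 1L, limit)
       else min(length(qb) - qpos, length(tb) - tpos, limit)
  if (m <= 0L) return(0L)
  qi <- qpos + dir * seq_len(m)
  ti <- tpos + dir * seq_len(m)
  sc <- cumsum(ifelse(qb[qi] == tb[ti], 1L, -mis_pen))
  best <- which.max(sc)
  if (sc[best] <= 0L) 0L else best
}

# substitution matrix reused for gap closure and small global alignments
nw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = TRUE)
}

# global alignment of two gap substrings, decomposed into gapless blocks
# with coordinates offset by (qoff-1, toff-1); returns list(blocks, mismatches)
nw_resolve <- function(qseq, tseq, qoff, toff) {
  pa <- Biostrings::pairwiseAlignment(qseq, tseq, type = "global",
                                      substitutionMatrix = nw_submat(),
                                      gapOpening = 4, gapExtension = 1)
  p <- utf8ToInt(as.character(Biostrings::alignedPattern(pa)))
  s <- utf8ToInt(as.character(Biostrings::alignedSubject(pa)))
  gap <- utf8ToInt("-")
  qp <- qoff - 1L; tp <- toff - 1L
  blocks <- list(); mism <- list()
  i <- 1L; n <- length(p)
  while (i <= n) {
    if (p[i] != gap && s[i] != gap) {
      j <- i
      while (j < n && p[j + 1L] != gap && s[j + 1L] != gap) j <- j + 1L
      len <- j - i + 1L
      qs <- qp + 1L; ts <- tp + 1L
      seg_p <- p[i:j]; seg_s <- s[i:j]
      bad <- which(seg_p != seg_s)
      blocks[[length(blocks) + 1L]] <- c(qs, qs + len - 1L, ts, ts + len - 1L, length(bad))
      if (length(bad))
        mism[[length(mism) + 1L]] <- data.frame(
          tpos = ts + bad - 1L, qpos = qs + bad - 1L,
          ref = intToUtf8(seg_s[bad], multiple = TRUE),
          alt = intToUtf8(seg_p[bad], multiple = TRUE), stringsAsFactors = FALSE)
      qp <- qp + len; tp <- tp + len
      i <- j + 1L
    } else {
      if (p[i] == gap) tp <- tp + 1L else qp <- qp + 1L
      i <- i + 1L
    }
  }
  b <- as.data.frame(do.call(rbind, blocks))
  if (nrow(b)) names(b) <- c("qs", "qe", "ts", "te", "nmis")
  list(blocks = b,
       mismatches = if (length(mism)) do.call(rbind, mism) else empty_mismatches())
}

# build chains from anchors in native query space (forward for '+', rc for '-')
chain_native <- function(q, t, k, qb, tb, max_gap, merge_check = 500L,
                         max_merge_frac = 0.2, min_anchors = 2L,
                         gap_close_limit = 2000L, gap_span_limit = 60000L,
                         end_extend = 200L) {
  ord <- order(q)
  q <- q[ord]; t <- t[ord]
  n <- length(q)
  if (n == 0L) return(list())
  breaks <- c(TRUE, t[-1L] <= t[-n] | (q[-1L] - q[-n]) > max_gap |
                (t[-1L] - t[-n]) > max_gap)
  grp <- cumsum(breaks)
  chains <- list()
  for (g in unique(grp)) {
    qi <- q[grp == g]; ti <- t[grp == g]
    if (length(qi) < min_anchors) next
    # anchor runs -> raw blocks
    raw <- list()
    cs <- 1L
    for (i in seq_along(qi)[-1L]) {
      dq <- qi[i] - qi[i - 1L]; dt <- ti[i] - ti[i - 1L]
      split_here <- dq != dt
      if (!split_here && dq > merge_check) {
        gq <- (qi[i - 1L] + k):(qi[i] - 1L)
        gt <- (ti[i - 1L] + k):(ti[i] - 1L)
        if (length(gq) > 0L && mean(qb[gq] != tb[gt]) > max_merge_frac)
          split_here <- TRUE
      }
      if (split_here) {
        raw[[length(raw) + 1L]] <- c(qi[cs], qi[i - 1L] + k - 1L, ti[cs], ti[i - 1L] + k - 1L)
        cs <- i
      }
    }
    raw[[length(raw) + 1L]] <- c(qi[cs], qi[length(qi)] + k - 1L, ti[cs], ti[length(ti)] + k - 1L)
    b <- do.call(rbind, raw)
    colnames(b) <- c("qs", "qe", "ts", "te")
    b <- as.data.frame(b)
    # trim block-boundary overlaps from the later block
    for (i in seq_len(nrow(b))[-1L]) {
      d <- max(0L, b$qe[i - 1L] + 1L - b$qs[i], b$te[i - 1L] + 1L - b$ts[i])
      b$qs[i] <- b$qs[i] + d; b$ts[i] <- b$ts[i] + d
    }
    b <- b[b$qe >= b$qs & b$te >= b$ts, , drop = FALSE]
    if (nrow(b) == 0L) next
    # extend chain ends by exact-match-biased X-drop
    ext <- xdrop_extend(qb, tb, b$qs[1], b$ts[1], -1L, end_extend)
    b$qs[1] <- b$qs[1] - ext; b$ts[1] <- b$ts[1] - ext
    nlast <- nrow(b)
    ext <- xdrop_extend(qb, tb, b$qe[nlast], b$te[nlast], 1L, end_extend)
    b$qe[nlast] <- b$qe[nlast] + ext; b$te[nlast] <- b$te[nlast] + ext
    # resolve inter-block gaps
    out_blocks <- list(); out_mism <- list()
    push_block <- function(qs, qe, ts, te) {
      bad <- which(qb[qs:qe] != tb[ts:te])
      out_blocks[[length(out_blocks) + 1L]] <<- c(qs, qe, ts, te, length(bad))
      if (length(bad))
        out_mism[[length(out_mism) + 1L]] <<- data.frame(
          tpos = ts + bad - 1L, qpos = qs + bad - 1L,
          ref = intToUtf8(tb[ts + bad - 1L], multiple = TRUE),
          alt = intToUtf8(qb[qs + bad - 1L], multiple = TRUE),
          stringsAsFactors = FALSE)
    }
    push_block(b$qs[1], b$qe[1], b$ts[1], b$te[1])
    for (i in seq_len(nrow(b))[-1L]) {
      gq <- b$qs[i] - b$qe[i - 1L] - 1L
      gt <- b$ts[i] - b$te[i - 1L] - 1L
      if (gq > 0L && gt > 0L && min(gq, gt) <= gap_close_limit &&
          max(gq, gt) <= gap_span_limit) {
        res <- nw_resolve(intToUtf8(qb[(b$qe[i - 1L] + 1L):(b$qs[i] - 1L)]),
                          intToUtf8(tb[(b$te[i - 1L] + 1L):(b$ts[i] - 1L)]),
                          b$qe[i - 1L] + 1L, b$te[i - 1L] + 1L)
        for (j in seq_len(nrow(res$blocks)))
          push_block(res$blocks$qs[j], res$blocks$qe[j],
                     res$blocks$ts[j], res$blocks$te[j])
      }
      push_block(b$qs[i], b$qe[i], b$ts[i], b$te[i])
    }
    bl <- as.data.frame(do.call(rbind, out_blocks))
    names(bl) <- c("qs", "qe", "ts", "te", "nmis")
    chains[[length(chains) + 1L]] <-
      list(blocks = bl,
           mismatches = if (length(out_mism)) do.call(rbind, out_mism)
                        else empty_mismatches())
  }
  chains
}

#' Align a contig to a reference by unique k-mer anchoring and chaining
#'
#' Anchors the contig (both orientations) on reference-unique k-mers, chains
#' collinear anchors per strand, closes small gaps by global alignment, and
#' reports strand-discordant sub-chains separately (the inversion signal).
#' A query mapping to disjoint targets yields split chains. A contig with no
#' anchors yields an empty list.
#'
#' @param contig character scalar.
#' @param reference a `locus_reference`, character scalar, or prebuilt
#'   [kmer_index()] (pass the index when aligning many contigs).
#' @param k anchor k-mer length (used only if `reference` is not an index).
#' @param stride contig k-mer sampling stride; breakpoint precision is about
#'   `stride + k` before end extension, exact after gap closure.
#' @param max_gap maximum within-chain anchor gap before splitting.
#' @param query_id id recorded on the chains.
#' @return list of `alignment_chain`s sorted by query start.
#' @export
align_contig <- function(contig, reference, k = 31L, stride = 8L,
                         max_gap = 50000L, query_id = "contig") {
  stop_if_not_scalar_seq(contig, "contig")
  idx <- as_kmer_index(reference, k = k)
  k <- idx$k
  nq <- nchar(contig)
  if (nq < k) stop("contig shorter than anchor length", call. = FALSE)
  tb <- utf8ToInt(idx$seq)
  starts <- unique(c(seq.int(1L, nq - k + 1L, by = stride), nq - k + 1L))
  res <- list()
  for (strand in c("+", "-")) {
    qnative <- if (strand == "+") contig else revcomp(contig)
    qb <- utf8ToInt(qnative)
    hits <- match(substring(qnative, starts, starts + k - 1L), idx$kmers)
    ok <- !is.na(hits)
    if (!any(ok)) next
    chains <- chain_native(starts[ok], idx$pos[hits[ok]], k, qb, tb,
                           max_gap = max_gap)
    for (ch in chains) {
      bl <- ch$blocks; mm <- ch$mismatches
      if (strand == "-") {
        qs_f <- nq - bl$qe + 1L
        bl$qe <- nq - bl$qs + 1L
        bl$qs <- qs_f
        if (nrow(mm)) mm$qpos <- nq - mm$qpos + 1L
      }
      res[[length(res) + 1L]] <- new_chain(query_id, idx$id, strand, bl, mm)
    }
  }
  res[order(vapply(res, function(ch) ch$qstart, 0L))]
}

#' Lift an interval through an alignment chain
#'
#' Maps both endpoints through the chain's gapless blocks; returns NULL when
#' either endpoint falls in an unaligned gap or outside the chain span.
#' Strand-aware: on '-' chains the mapped interval's ends flip.
#'
#' @param interval integer c(start, end), 1-based closed, in the source
#'   coordinate space.
#' @param chain an `alignment_chain`.
#' @param direction "ref2query" or "query2ref".
#' @return integer c(start, end) with attribute `strand`, or NULL.
#' @export
liftover <- function(interval, chain, direction = c("ref2query", "query2ref")) {
  direction <- match.arg(direction)
  b <- chain$blocks
  map1 <- function(x) {
    if (direction == "ref2query") {
      i <- which(b$ts <= x & b$te >= x)
      if (length(i) == 0L) return(NA_integer_)
      i <- i[1]
      if (chain$strand == "+") b$qs[i] + (x - b$ts[i]) else b$qe[i] - (x - b$ts[i])
    } else {
      i <- which(b$qs <= x & b$qe >= x)
      if (length(i) == 0L) return(NA_integer_)
      i <- i[1]
      if (chain$strand == "+") b$ts[i] + (x - b$qs[i]) else b$ts[i] + (b$qe[i] - x)
    }
  }
  a <- map1(interval[1]); z <- map1(interval[2])
  if (is.na(a) || is.na(z)) return(NULL)
  out <- sort(c(a, z))
  structure(stats::setNames(out, c("start", "end")), strand = chain$strand)
}

# ---- contig merging -----------------------------------------------------

# longest suffix(a)/prefix(b) overlap >= min_overlap with <= max_mismatch
# substitutions (no indels); probes are max_mismatch+1 disjoint 32-mers of
# b's prefix, so any qualifying overlap is discovered.
find_overlap <- function(a, b, min_overlap, max_mismatch) {
  la <- nchar(a); lb <- nchar(b)
  if (la < min_overlap || lb < min_overlap) return(0L)
  plen <- 32L
  offs <- unique(as.integer(round(seq(1L, min_overlap - plen + 1L,
                                      length.out = max_mismatch + 1L))))
  cand <- integer()
  for (o in offs) {
    probe <- substr(b, o, o + plen - 1L)
    hits <- gregexpr(probe, a, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    astart <- hits - o + 1L         # a-position aligned to b position 1
    cand <- union(cand, astart[astart >= 1L])
  }
  best <- 0L
  for (astart in cand) {
    L <- la - astart + 1L
    if (L < min_overlap || L > lb) next
    if (mismatch_count(substr(a, astart, la), substr(b, 1L, L)) <= max_mismatch)
      best <- max(best, L)
  }
  best
}

#' Greedily merge contigs by suffix/prefix overlap
#'
#' Joins pairs whose suffix/prefix overlap is at least `min_overlap` bases
#' with at most `max_mismatch` substitutions (any indel disqualifies the
#' candidate), iterating to a fixpoint. Candidate order is deterministic
#' (longest contig first, then lexicographic id), so the result is invariant
#' to input permutation. Unmergeable contigs pass through.
#'
#' @param contigs named character vector.
#' @param min_overlap minimum overlap in bases (default 2000).
#' @param max_mismatch maximum substitutions tolerated in the overlap (default 5).
#' @return named character vector of merged contigs.
#' @export
merge_contigs <- function(contigs, min_overlap = 2000L, max_mismatch = 5L) {
  if (length(contigs) == 0L) stop("contigs must be non-empty", call. = FALSE)
  contigs <- contigs[order(-nchar(contigs), names(contigs))]
  repeat {
    if (length(contigs) < 2L) break
    best <- NULL; best_L <- 0L
    ids <- names(contigs)
    for (i in seq_along(contigs)) for (j in seq_along(contigs)) {
      if (i == j) next
      L <- find_overlap(contigs[[i]], contigs[[j]], min_overlap, max_mismatch)
      if (L > best_L) { best_L <- L; best <- c(i, j) }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    merged <- paste0(contigs[[i]], substr(contigs[[j]], best_L + 1L, nchar(contigs[[j]])))
    nm <- names(contigs)[i]
    contigs <- contigs[-c(i, j)]
    contigs[nm] <- merged
    contigs <- contigs[order(-nchar(contigs), names(contigs))]
  }
  contigs
}

# ---- read mapping and pileups ------------------------------------------

#' Place reads on one or more target contigs (ungapped)
#'
#' Batch k-mer anchoring against each target's unique-k-mer index; each read
#' is placed at its modal anchor diagonal on the target with the fewest
#' mismatches (substitution-only error model, so placements are ungapped).
#' Reads with no forward anchors are retried reverse-complemented.
#'
#' @param reads named character vector of read sequences.
#' @param targets named character vector of target contigs, or a single
#'   [kmer_index()], or a list of them.
#' @param k anchor length.
#' @param stride read k-mer sampling stride.
#' @return data.frame: read_id, target, start, end, strand, nmis, seq (the
#'   read oriented and clipped to the placement). Unplaceable reads are
#'   omitted.
#' @export
map_reads <- function(reads, targets, k = 31L, stride = 25L) {
  if (length(reads) == 0L)
    return(data.frame(read_id = character(), target = character(),
                      start = integer(), end = integer(), strand = character(),
                      nmis = integer(), seq = character(), stringsAsFactors = FALSE))
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  idxs <- if (inherits(targets, "kmer_index")) list(targets)
          else if (is.list(targets)) targets
          else lapply(names(targets), function(nm) kmer_index(targets[[nm]], k = k, id = nm))
  place_pass <- function(seqs) {
    ns <- nchar(seqs)
    starts_list <- lapply(ns, function(n) {
      if (n < k) integer() else unique(c(seq.int(1L, n - k + 1L, by = stride), n - k + 1L))
    })
    read_of <- rep(seq_along(seqs), lengths(starts_list))
    qs <- unlist(starts_list)
    if (length(qs) == 0L) return(NULL)
    kms <- substring(seqs[read_of], qs, qs + k - 1L)
    best <- data.frame(read = seq_along(seqs), target = NA_integer_,
                       start = NA_integer_, nmis = NA_integer_)
    for (ti in seq_along(idxs)) {
      idx <- idxs[[ti]]
      hit <- match(kms, idx$kmers)
      ok <- !is.na(hit)
      if (!any(ok)) next
      diag <- idx$pos[hit[ok]] - qs[ok] + 1L
      sp <- split(diag, read_of[ok])
      tb <- utf8ToInt(idx$seq)
      for (rn in names(sp)) {
        r <- as.integer(rn)
        tb_start <- as.integer(names(which.max(table(sp[[rn]]))))
        s <- max(1L, tb_start)
        e <- min(idx$n, tb_start + ns[r] - 1L)
        if (e < s) next
        roff <- s - tb_start + 1L
        rb <- utf8ToInt(substr(seqs[r], roff, roff + (e - s)))
        nm <- sum(rb != tb[s:e]) + (ns[r] - (e - s + 1L))  # clipped bases count as edits
        if (is.na(best$nmis[r]) || nm < best$nmis[r]) {
          best$target[r] <- ti; best$start[r] <- tb_start; best$nmis[r] <- nm
        }
      }
    }
    best
  }
  fw <- place_pass(reads)
  strand <- rep("+", length(reads))
  unplaced <- which(is.na(fw$target))
  if (length(unplaced)) {
    rc <- vapply(reads[unplaced], revcomp, "")
    bw <- place_pass(rc)
    take <- which(!is.na(bw$target))
    if (length(take)) {
      fw$target[unplaced[take]] <- bw$target[take]
      fw$start[unplaced[take]] <- bw$start[take]
      fw$nmis[unplaced[take]] <- bw$nmis[take]
      strand[unplaced[take]] <- "-"
    }
  }
  keep <- which(!is.na(fw$target))
  out <- lapply(keep, function(r) {
    idx <- idxs[[fw$target[r]]]
    oriented <- if (strand[r] == "+") reads[[r]] else revcomp(reads[[r]])
    s <- max(1L, fw$start[r])
    e <- min(idx$n, fw$start[r] + nchar(oriented) - 1L)
    roff <- s - fw$start[r] + 1L
    data.frame(read_id = names(reads)[r], target = idx$id, start = s, end = e,
               strand = strand[r], nmis = fw$nmis[r],
               seq = substr(oriented, roff, roff + (e - s)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-base read depth over a target
#'
#' @param alignments data.frame with columns target, start, end (from
#'   [map_reads()] or constructed directly).
#' @param target_length target length in bases.
#' @param target_id restrict to alignments on this target (default: all rows).
#' @return object of class `depth_track` with per-base `depth`.
#' @export
pileup_depth <- function(alignments, target_length, target_id = NULL) {
  if (!is.null(target_id)) alignments <- alignments[alignments$target == target_id, ]
  if (nrow(alignments) && (any(alignments$end > target_length) || any(alignments$start < 1L)))
    stop("alignment beyond target end", call. = FALSE)
  d <- integer(target_length + 1L)
  for (i in seq_len(nrow(alignments))) {
    d[alignments$start[i]] <- d[alignments$start[i]] + 1L
    d[alignments$end[i] + 1L] <- d[alignments$end[i] + 1L] - 1L
  }
  structure(list(target_id = target_id %||% "all",
                 depth = cumsum(d[seq_len(target_length)])),
            class = "depth_track")
}

#' Fraction of target bases covered at least k-fold
#' @param track a `depth_track`.
#' @param k depth threshold.
#' @return fraction in \[0,1\].
#' @export
depth_fraction <- function(track, k) mean(track$depth >= k)

# per-base depth and assembly-agreement counts for one target
pileup_agreement <- function(alignments, reads_df = NULL, target_seq, target_id = NULL) {
  if (!is.null(target_id)) alignments <- alignments[alignments$target == target_id, ]
  L <- nchar(target_seq)
  tb <- utf8ToInt(target_seq)
  ddiff <- integer(L + 1L)
  matchv <- integer(L)
  buf <- vector("list", 256L); bi <- 0L; bn <- 0L
  flush <- function() {
    if (bi > 0L) {
      matchv <<- matchv + tabulate(unlist(buf[seq_len(bi)]), nbins = L)
      bi <<- 0L; bn <<- 0L
    }
  }
  for (i in seq_len(nrow(alignments))) {
    s <- alignments$start[i]; e <- alignments$end[i]
    if (s < 1L || e > L) stop("alignment beyond target end", call. = FALSE)
    ddiff[s] <- ddiff[s] + 1L
    ddiff[e + 1L] <- ddiff[e + 1L] - 1L
    rb <- utf8ToInt(alignments$seq[i])
    eq <- which(rb == tb[s:e])
    if (length(eq)) {
      bi <- bi + 1L
      buf[[bi]] <- s - 1L + eq
      bn <- bn + length(eq)
      if (bi == 256L || bn > 4e6) flush()
    }
  }
  flush()
  list(depth = cumsum(ddiff[seq_len(L)]), match = matchv)
}
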