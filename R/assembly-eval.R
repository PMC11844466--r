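# Assembly benchmarking against truth: greedy read-overlap reconstruction,
# windowed error rates, per-base read support, phase-switch counting, and
# diploid genotype concordance.

#' Reconstruct a haplotype from error-free tiled reads by greedy exact overlap
#'
#' A minimal overlap-layout reconstructor for benchmarking only: starting
#' from an unused seed read, the current contig is repeatedly extended right
#' and left by reads whose prefix/suffix overlaps the contig end exactly over
#' at least `min_overlap` bases. Candidate overlaps are found via a 64-mer
#' lookup of read ends, then verified over the full overlap, so paralog
#' copies (which differ in every 1 kb window) cannot cross-join. Not a
#' general assembler.
#'
#' @param reads character vector of read sequences (error-free).
#' @param min_overlap minimum exact overlap in bases (default 2000).
#' @return character vector of reconstructed contigs (longest first).
#' @export
reconstruct_haplotype <- function(reads, min_overlap = 2000L) {
  reads <- as.character(reads)
  reads <- reads[nchar(reads) > 0L]
  if (length(reads) == 0L) stop("no reads", call. = FALSE)
  probe <- 64L
  reads <- reads[nchar(reads) >= probe]
  n <- length(reads)
  lens <- nchar(reads)
  first64 <- substr(reads, 1L, probe)
  last64 <- substr(reads, lens - probe + 1L, lens)
  used <- logical(n)
  maxlen <- max(lens)
  # candidate reads extending the contig 3' end: their first 64-mer occurs in
  # the contig suffix window at an offset leaving >= min_overlap overlap
  extend_right <- function(contig) {
    nc <- nchar(contig)
    lo <- max(1L, nc - maxlen + 1L)
    hi <- nc - min_overlap + 1L
    if (hi < lo) return(NULL)
    wpos <- lo:hi
    wk <- substring(contig, wpos, wpos + probe - 1L)
    hits <- which(!used & first64 %in% wk)
    best <- NULL; best_gain <- 0L
    for (r in hits) {
      at <- wpos[wk == first64[r]]
      for (p in at) {
        L <- nc - p + 1L                      # overlap length
        if (L < min_overlap || L > lens[r]) next
        if (substr(contig, p, nc) == substr(reads[r], 1L, L)) {
          gain <- lens[r] - L
          if (gain > best_gain) { best_gain <- gain; best <- c(r, L) }
        }
      }
    }
    best
  }
  extend_left <- function(contig) {
    nc <- nchar(contig)
    hi <- min(nc, maxlen) - probe + 1L
    lo <- min_overlap - probe + 1L
    if (hi < lo) return(NULL)
    wpos <- lo:hi                              # contig 64-mer ending at overlap L
    wk <- substring(contig, wpos, wpos + probe - 1L)
    hits <- which(!used & last64 %in% wk)
    best <- NULL; best_gain <- 0L
    for (r in hits) {
      at <- wpos[wk == last64[r]]
      for (p in at) {
        L <- p + probe - 1L                    # overlap length at contig start
        if (L < min_overlap || L > lens[r]) next
        if (substr(contig, 1L, L) == substr(reads[r], lens[r] - L + 1L, lens[r])) {
          gain <- lens[r] - L
          if (gain > best_gain) { best_gain <- gain; best <- c(r, L) }
        }
      }
    }
    best
  }
  contigs <- character()
  ord <- order(-lens)
  for (seed_i in ord) {
    if (used[seed_i]) next
    used[seed_i] <- TRUE
    contig <- reads[seed_i]
    repeat {
      ext <- extend_right(contig)
      if (is.null(ext)) break
      used[ext[1]] <- TRUE
      contig <- paste0(contig, substr(reads[ext[1]], ext[2] + 1L, lens[ext[1]]))
    }
    repeat {
      ext <- extend_left(contig)
      if (is.null(ext)) break
      used[ext[1]] <- TRUE
      contig <- paste0(substr(reads[ext[1]], 1L, lens[ext[1]] - ext[2]), contig)
    }
    # absorb contained reads so they do not seed spurious duplicate contigs
    for (r in which(!used)) {
      if (lens[r] < nchar(contig) &&
          grepl(substr(reads[r], 1L, min(lens[r], 256L)), contig, fixed = TRUE) &&
          grepl(reads[r], contig, fixed = TRUE)) used[r] <- TRUE
    }
    contigs <- c(contigs, contig)
  }
  contigs[order(-nchar(contigs))]
}

#' Windowed error rate of a test sequence against a truth haplotype
#'
#' Aligns the test contigs to the truth sequence and counts edits
#' (mismatches plus indel bases, with insertions charged to their breakpoint
#' window) per truth-anchored window. The last partial window is kept and
#' weighted by its length in the mean. Windows with no aligned block are
#' reported as uncovered and excluded from the error mean.
#'
#' @param test character vector of test contigs (or single sequence).
#' @param truth truth haplotype sequence (character scalar).
#' @param window window size in bases (default 10 kb).
#' @return list: `windows` data.frame(start, end, covered, edits, rate),
#'   `accuracy` = 1 - length-weighted mean rate over covered windows,
#'   `uncovered_windows`, `total_edits`.
#' @export
window_error_rate <- function(test, truth, window = 10000L) {
  stop_if_not_scalar_seq(truth, "truth")
  test <- as.character(test)
  n <- nchar(truth)
  ws <- seq(1L, n, by = window)
  we <- pmin(ws + window - 1L, n)
  edits <- numeric(length(ws))
  covered <- logical(length(ws))
  idx <- kmer_index(truth, id = "truth")
  win_of <- function(pos) pmin((pos - 1L) %/% window + 1L, length(ws))
  for (ci in seq_along(test)) {
    chains <- align_contig(test[ci], idx, query_id = sprintf("contig%d", ci))
    for (ch in chains) {
      b <- ch$blocks
      for (i in seq_len(nrow(b))) {
        wa <- win_of(b$ts[i]); wb <- win_of(b$te[i])
        covered[wa:wb] <- TRUE
      }
      if (nrow(ch$mismatches)) {
        tw <- table(win_of(ch$mismatches$tpos))
        edits[as.integer(names(tw))] <- edits[as.integer(names(tw))] + as.integer(tw)
      }
      if (nrow(b) > 1L) {
        for (i in seq_len(nrow(b))[-1L]) {
          gq <- b$qs[i] - b$qe[i - 1L] - 1L
          gt <- b$ts[i] - b$te[i - 1L] - 1L
          if (gt > 0L && gq <= 0L) {            # deletion: charge deleted bases
            pos <- (b$te[i - 1L] + 1L):(b$ts[i] - 1L)
            tw <- table(win_of(pos))
            edits[as.integer(names(tw))] <- edits[as.integer(names(tw))] + as.integer(tw)
          } else if (gq > 0L && gt <= 0L) {     # insertion: charge at breakpoint
            w <- win_of(b$te[i - 1L])
            edits[w] <- edits[w] + gq
          }
          # gq>0 && gt>0 (unaligned gap): interior windows stay uncovered
          # unless another chain (e.g. an inversion sub-chain) spans them
        }
      }
    }
  }
  wlen <- we - ws + 1L
  rate <- ifelse(covered, pmin(1, edits / wlen), NA_real_)
  acc <- if (any(covered))
    1 - sum(rate[covered] * wlen[covered]) / sum(wlen[covered]) else NA_real_
  list(windows = data.frame(start = ws, end = we, covered = covered,
                            edits = edits, rate = rate),
       accuracy = acc,
       uncovered_windows = sum(!covered),
       total_edits = sum(edits[covered]))
}

#' Per-base read support of an assembly
#'
#' Realigns reads to the assembly contigs and, at every position, computes
#' the fraction of mapped reads agreeing with the assembly base. The summary
#' is the fraction of included positions (depth >= `inclusion_depth`) whose
#' agreement is at least `min_fraction` (inclusive).
#'
#' @param contigs named character vector of assembly contigs.
#' @param reads named character vector of reads.
#' @param min_fraction agreement threshold (default 0.8, inclusive).
#' @param inclusion_depth minimum depth for a position to enter the summary
#'   (default 10, i.e. the ">9x" rule).
#' @param alignments optional precomputed [map_reads()] result.
#' @return object of class `support_table`: per-contig data.frames of depth,
#'   match counts and agreement, plus `summary` (supported fraction of
#'   included bases) and `included_fraction`.
#' @export
base_support <- function(contigs, reads, min_fraction = 0.8,
                         inclusion_depth = 10L, alignments = NULL) {
  if (is.null(alignments)) alignments <- map_reads(reads, contigs)
  if (nrow(alignments) == 0L) {
    warning("zero mapped reads; empty support table")
    return(structure(list(tracks = list(), summary = NA_real_,
                          included_fraction = 0), class = "support_table"))
  }
  tracks <- list()
  n_inc <- 0L; n_sup <- 0L; n_tot <- 0L
  for (nm in names(contigs)) {
    pa <- pileup_agreement(alignments, target_seq = contigs[[nm]], target_id = nm)
    agree <- ifelse(pa$depth > 0L, pa$match / pa$depth, NA_real_)
    inc <- pa$depth >= inclusion_depth
    n_inc <- n_inc + sum(inc)
    n_sup <- n_sup + sum(inc & agree >= min_fraction)
    n_tot <- n_tot + length(pa$depth)
    tracks[[nm]] <- data.frame(pos = seq_along(pa$depth), depth = pa$depth,
                               match = pa$match, agreement = agree)
  }
  structure(list(tracks = tracks,
                 summary = if (n_inc > 0L) n_sup / n_inc else NA_real_,
                 included_fraction = n_inc / n_tot,
                 min_fraction = min_fraction, inclusion_depth = inclusion_depth),
            class = "support_table")
}

#' Count phase switches of a contig against a truth marker map
#'
#' Projects the contig onto heterozygous marker positions via its alignment
#' chain and counts transitions between haplotype-of-origin labels. A contig
#' covering fewer than two markers is not assessable.
#'
#' @param contig contig sequence.
#' @param marker_map data.frame(pos, h1_base, h2_base) of reference-frame
#'   heterozygous markers with each haplotype's base.
#' @param reference reference (or [kmer_index()]) the marker positions refer to.
#' @return list: `switches` (integer or NA if not assessable), `labels`
#'   (ordered H1/H2 calls at covered markers), `n_markers`.
#' @export
phase_switch_count <- function(contig, marker_map, reference) {
  idx <- as_kmer_index(reference)
  chains <- align_contig(contig, idx, query_id = "contig")
  labels <- character()
  pos_seen <- integer()
  for (i in seq_len(nrow(marker_map))) {
    p <- marker_map$pos[i]
    base <- NA_character_
    for (ch in chains) {
      q <- liftover(c(p, p), ch, "ref2query")
      if (!is.null(q)) {
        b <- substr(contig, q[1], q[1])
        if (ch$strand == "-") b <- revcomp(b)
        base <- b
        break
      }
    }
    if (is.na(base)) next
    lab <- if (base == marker_map$h1_base[i]) "H1"
           else if (base == marker_map$h2_base[i]) "H2" else NA_character_
    if (!is.na(lab)) { labels <- c(labels, lab); pos_seen <- c(pos_seen, p) }
  }
  if (length(labels) < 2L)
    return(list(switches = NA_integer_, labels = labels, n_markers = length(labels)))
  list(switches = sum(labels[-1L] != labels[-length(labels)]),
       labels = labels, n_markers = length(labels))
}

#' Diploid genotype concordance between a test and a truth callset
#'
#' Compares genotype classes (hom-ref / het / hom-alt) at every truth-assessed
#' reference position. A position is "missing" unless spanned by the diploid
#' test assembly and covered by at least `min_reads` reads; missing positions
#' are excluded from the concordance denominator.
#'
#' @param test_calls data.frame(pos, gt) of test genotypes at variant
#'   positions (gt in "0/0","0/1","1/1"; positions absent are hom-ref).
#' @param truth_calls data.frame(pos, gt) of truth genotypes.
#' @param assessed_positions integer vector of reference positions assessed
#'   (the truth diploid span, SV/indel positions already excluded).
#' @param diploid_span logical vector or integer positions spanned by both
#'   test haplotypes.
#' @param read_depths integer vector of per-position read depth (reference
#'   frame), or a single value recycled.
#' @param min_reads minimum read depth to call (default 4).
#' @return object of class `concordance_report`: counts (concordant,
#'   discordant, missing), `concordance` percentage, and the per-position
#'   class table.
#' @export
genotype_concordance <- function(test_calls, truth_calls, assessed_positions,
                                 diploid_span, read_depths, min_reads = 4L) {
  pos <- sort(unique(as.integer(assessed_positions)))
  if (is.logical(diploid_span)) diploid_span <- which(diploid_span)
  depth <- if (length(read_depths) == 1L) rep(read_depths, length(pos))
           else read_depths[pos]
  spanned <- pos %in% diploid_span
  gt_of <- function(calls, p) {
    g <- calls$gt[match(p, calls$pos)]
    ifelse(is.na(g), "0/0", g)
  }
  test_gt <- gt_of(test_calls, pos)
  truth_gt <- gt_of(truth_calls, pos)
  class <- ifelse(!spanned | depth < min_reads, "missing",
                  ifelse(test_gt == truth_gt, "concordant", "discordant"))
  n_con <- sum(class == "concordant")
  n_dis <- sum(class == "discordant")
  n_mis <- sum(class == "missing")
  structure(list(counts = c(concordant = n_con, discordant = n_dis, missing = n_mis),
                 concordance = if (n_con + n_dis > 0) 100 * n_con / (n_con + n_dis)
                               else NA_real_,
                 positions = data.frame(pos = pos, test = test_gt, truth = truth_gt,
                                        depth = depth, class = class)),
            class = "concordance_report")
}
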