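# Diploid SNV calling from assembly chains with SV masking, read-pileup
# candidate rescue, callset combination (read priority), SV detection and
# genotyping from chain signatures, and callset comparison.

in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals)))
    out <- out | (pos >= intervals$start[i] & pos <= intervals$end[i])
  out
}

chain_coverage <- function(chains, n) {
  cov <- logical(n)
  for (ch in chains) for (i in seq_len(nrow(ch$blocks)))
    cov[ch$blocks$ts[i]:ch$blocks$te[i]] <- TRUE
  cov
}

chain_indel_gaps <- function(chains, min_size = 1L, max_size = 49L) {
  rows <- list()
  for (ch in chains) {
    b <- ch$blocks
    for (i in seq_len(nrow(b))[-1L]) {
      gq <- b$qs[i] - b$qe[i - 1L] - 1L
      gt <- b$ts[i] - b$te[i - 1L] - 1L
      if (ch$strand == "-") gq <- b$qs[i - 1L] - b$qe[i] - 1L  # forward-coord order flips
      sz <- abs(gt - gq)
      if (sz >= min_size && sz <= max_size && (gq == 0L || gt == 0L))
        rows[[length(rows) + 1L]] <- data.frame(
          pos = b$te[i - 1L] + 1L, size = sz,
          type = if (gt > gq) "del" else "ins", stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(pos = integer(), size = integer(), type = character())
}

hap_variant_table <- function(chains) {
  mm <- do.call(rbind, lapply(chains, `[[`, "mismatches"))
  if (is.null(mm) || nrow(mm) == 0L) return(empty_mismatches())
  mm[!duplicated(mm$tpos), , drop = FALSE]
}

#' Call diploid SNVs from assembly-to-reference alignment chains
#'
#' At every reference position covered by both haplotypes, the two aligned
#' bases define the genotype (hom-ref positions are implied, not emitted).
#' Short indels are recorded but flagged for exclusion; records inside the
#' SV mask are flagged masked and excluded from downstream statistics.
#' Positions covered by a single haplotype are emitted half-missing ("1/.")
#' rather than forced homozygous.
#'
#' @param chains_by_hap list of 1 or 2 chain lists (one per haplotype), each
#'   from [align_contig()] against the same reference.
#' @param reference a `locus_reference` (or character sequence).
#' @param mask data.frame(start, end) of masked SV regions, or NULL.
#' @return object of class `callset`: `records` data.frame(pos, ref, alt, gt,
#'   source, masked, type), plus `diploid_span` (positions covered by all
#'   haplotypes) and `indels`.
#' @export
call_from_assembly <- function(chains_by_hap, reference, mask = NULL) {
  if (!length(chains_by_hap) %in% 1:2)
    stop("a donor has 1 or 2 haplotype chain sets", call. = FALSE)
  refseq <- if (inherits(reference, "locus_reference")) reference$seq else reference
  n <- nchar(refseq)
  covs <- lapply(chains_by_hap, chain_coverage, n = n)
  vars <- lapply(chains_by_hap, hap_variant_table)
  diploid <- Reduce(`&`, covs)
  pos_all <- sort(unique(unlist(lapply(vars, `[[`, "tpos"))))
  recs <- list()
  for (p in pos_all) {
    ref <- substr(refseq, p, p)
    alleles <- vapply(seq_along(vars), function(h) {
      if (!covs[[h]][p]) return(NA_character_)
      i <- match(p, vars[[h]]$tpos)
      if (is.na(i)) ref else vars[[h]]$alt[i]
    }, "")
    if (length(alleles) == 1L) alleles <- c(alleles, NA_character_)
    alts <- sort(unique(alleles[!is.na(alleles) & alleles != ref]))
    if (length(alts) == 0L) next
    code <- function(a) if (is.na(a)) "." else if (a == ref) "0" else match(a, alts)
    codes <- c(code(alleles[1]), code(alleles[2]))
    codes <- codes[order(codes == ".", codes)]  # unphased: numeric first, ascending
    gt <- paste(codes, collapse = "/")
    recs[[length(recs) + 1L]] <- data.frame(
      pos = p, ref = ref, alt = paste(alts, collapse = ","), gt = gt,
      stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(pos = integer(), ref = character(), alt = character(),
                             gt = character(), stringsAsFactors = FALSE)
  records$source <- rep("assembly", nrow(records))
  records$masked <- in_intervals(records$pos, mask)
  records$type <- rep("snv", nrow(records))
  indels <- do.call(rbind, lapply(chains_by_hap, chain_indel_gaps))
  structure(list(records = records, diploid_span = which(diploid),
                 coverage = covs, indels = indels, mask = mask),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset: %d records (%d masked), %d short indels, diploid span %d bp>\n",
              nrow(x$records), sum(x$records$masked), nrow(x$indels),
              length(x$diploid_span)))
  invisible(x)
}

#' Rescue SNV candidate positions from a read pileup
#'
#' A position is a candidate iff the fraction of non-reference bases among
#' mapped reads is at least `minrel` (inclusive). Zero-depth positions are
#' skipped.
#'
#' @param pileup list with per-base `depth` and `match` counts against the
#'   chosen reference (see [base_support()] internals), or an alignments
#'   data.frame plus `reference`.
#' @param reference reference sequence (required when `pileup` is an
#'   alignments data.frame).
#' @param minrel minimum non-reference fraction (default 0.05).
#' @return data.frame(pos, depth, nonref_fraction).
#' @export
snv_candidates_from_reads <- function(pileup, reference = NULL, minrel = 0.05) {
  if (is.data.frame(pileup)) {
    refseq <- if (inherits(reference, "locus_reference")) reference$seq else reference
    stop_if_not_scalar_seq(refseq, "reference")
    pileup <- pileup_agreement(pileup, target_seq = refseq)
  }
  depth <- pileup$depth
  nonref <- depth - pileup$match
  keep <- depth > 0L & nonref / pmax(depth, 1L) >= minrel
  data.frame(pos = which(keep), depth = depth[keep],
             nonref_fraction = (nonref / depth)[keep])
}

# base counts (A/C/G/T) at selected positions from ungapped read placements
read_base_counts <- function(alignments, positions) {
  counts <- matrix(0L, nrow = length(positions), ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(nrow(alignments))) {
    s <- alignments$start[i]; e <- alignments$end[i]
    hit <- which(positions >= s & positions <= e)
    if (!length(hit)) next
    b <- substring(alignments$seq[i], positions[hit] - s + 1L, positions[hit] - s + 1L)
    for (j in seq_along(hit)) {
      col <- match(b[j], DNA_BASES)
      if (!is.na(col)) counts[hit[j], col] <- counts[hit[j], col] + 1L
    }
  }
  counts
}

#' Call diploid SNVs from reads against the reference
#'
#' Candidate positions come from [snv_candidates_from_reads()]; genotypes are
#' assigned from base fractions (alt fraction at least `hom_threshold` gives
#' hom-alt, at least `het_threshold` gives het, else hom-ref and the record
#' is dropped).
#'
#' @param alignments [map_reads()] placements on the reference.
#' @param reference reference sequence or `locus_reference`.
#' @param minrel candidate threshold (default 0.05).
#' @param het_threshold,hom_threshold alt-fraction genotype cutoffs.
#' @param mask optional data.frame(start, end) SV mask.
#' @return a `callset` with source "read".
#' @export
call_from_reads <- function(alignments, reference, minrel = 0.05,
                            het_threshold = 0.25, hom_threshold = 0.85,
                            mask = NULL) {
  refseq <- if (inherits(reference, "locus_reference")) reference$seq else reference
  cand <- snv_candidates_from_reads(alignments, refseq, minrel)
  recs <- list()
  if (nrow(cand)) {
    counts <- read_base_counts(alignments, cand$pos)
    for (i in seq_len(nrow(cand))) {
      p <- cand$pos[i]
      ref <- substr(refseq, p, p)
      cc <- counts[i, ]
      cc[ref] <- 0L
      alt <- names(which.max(cc))
      f <- cc[alt] / cand$depth[i]
      if (f >= hom_threshold) gt <- "1/1"
      else if (f >= het_threshold) gt <- "0/1"
      else next
      recs[[length(recs) + 1L]] <- data.frame(pos = p, ref = ref, alt = alt, gt = gt,
                                              stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(pos = integer(), ref = character(), alt = character(),
                             gt = character(), stringsAsFactors = FALSE)
  records$source <- rep("read", nrow(records))
  records$masked <- in_intervals(records$pos, mask)
  records$type <- rep("snv", nrow(records))
  structure(list(records = records, diploid_span = integer(), coverage = NULL,
                 indels = NULL, mask = mask), class = "callset")
}

#' Combine assembly- and read-derived callsets (read priority)
#'
#' Union of positions; at overlapping positions the read-derived record wins
#' and provenance is preserved per record. Idempotent.
#'
#' @param assembly_calls,read_calls `callset`s on the same reference.
#' @return combined `callset`.
#' @export
combine_callsets <- function(assembly_calls, read_calls) {
  a <- assembly_calls$records
  r <- read_calls$records
  keep_a <- a[!a$pos %in% r$pos, , drop = FALSE]
  rec <- rbind(r, keep_a)
  rec <- rec[order(rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, diploid_span = assembly_calls$diploid_span,
                 coverage = assembly_calls$coverage, indels = assembly_calls$indels,
                 mask = assembly_calls$mask %||% read_calls$mask),
            class = "callset")
}

# ---- SV detection -------------------------------------------------------

# q position in `chain` mapping to target position t1. When t1 falls in a
# deletion gap (block boundaries can slide by a few bases when flanking
# bases match by chance), extrapolate from the next downstream block.
lift_t_to_q <- function(chain, t1, max_extrapolate = 2000L) {
  q <- liftover(c(t1, t1), chain, "ref2query")
  if (!is.null(q)) return(q[1])
  if (chain$strand != "+") return(NA_integer_)
  b <- chain$blocks
  after <- which(b$ts > t1)
  if (!length(after)) return(NA_integer_)
  i <- after[which.min(b$ts[after])]
  if (b$ts[i] - t1 > max_extrapolate) return(NA_integer_)
  b$qs[i] - (b$ts[i] - t1)
}

detect_svs_one_hap <- function(chains, min_size = 50L, hap = 1L) {
  calls <- list()
  add <- function(kind, start, end, size, confidence = "high") {
    calls[[length(calls) + 1L]] <<- data.frame(
      kind = kind, start = as.integer(start), end = as.integer(end),
      size = as.integer(size), hap = hap, confidence = confidence,
      stringsAsFactors = FALSE)
  }
  # within-chain gap signatures
  for (ch in chains) {
    b <- ch$blocks
    for (i in seq_len(nrow(b))[-1L]) {
      gq <- b$qs[i] - b$qe[i - 1L] - 1L
      gt <- b$ts[i] - b$te[i - 1L] - 1L
      if (ch$strand == "-") gq <- b$qs[i - 1L] - b$qe[i] - 1L
      if (gt - gq >= min_size && gq < min_size)
        add("deletion", b$te[i - 1L] + 1L, b$ts[i] - 1L, gt - gq)
      else if (gq - gt >= min_size && gt < min_size)
        add("insertion", b$te[i - 1L], b$te[i - 1L], gq - gt)
      else if (gq >= min_size && gt >= min_size)
        add("complex", b$te[i - 1L] + 1L, b$ts[i] - 1L, max(gq, gt), "low")
    }
  }
  # inversions: strand-discordant sub-chains
  minus <- Filter(function(ch) ch$strand == "-", chains)
  plus <- Filter(function(ch) ch$strand == "+", chains)
  for (m in minus) {
    flanked <- any(vapply(plus, function(p) p$tstart < m$tstart, TRUE)) &&
               any(vapply(plus, function(p) p$tend > m$tend, TRUE))
    add("inversion", m$tstart, m$tend, m$tend - m$tstart + 1L,
        if (flanked) "high" else "low")
  }
  # cross-chain signatures on plus chains ordered by query
  recovered <- list()
  if (length(plus) > 1L) {
    ord <- order(vapply(plus, function(ch) ch$qstart, 0L))
    plus <- plus[ord]
    for (i in seq_along(plus)[-1L]) {
      c1 <- plus[[i - 1L]]; c2 <- plus[[i]]
      qgap <- c2$qstart - c1$qend - 1L
      tgap <- c2$tstart - c1$tend - 1L
      if (tgap <= -min_size && qgap < 2000L) {
        # query gap tolerance is loose here: anchors thin out near paralog
        # block edges (unique k-mers exist only at planted differences), but
        # the size arithmetic below is exact regardless of the gap
        # query re-covers an upstream target span: extra copy
        t_ins <- c1$tend
        recovered[[length(recovered) + 1L]] <- c(c2$tstart, t_ins)
        qstar <- lift_t_to_q(c2, t_ins + 1L)
        size <- if (!is.na(qstar)) qstar - c1$qend - 1L else -tgap
        gaps <- chain_indel_gaps(list(c2), min_size, .Machine$integer.max)
        tandem <- !any(gaps$pos <= t_ins)
        add(if (tandem) "duplication" else "insertion",
            c2$tstart, t_ins, size, if (is.na(qstar)) "low" else "high")
      } else if (tgap >= min_size && qgap < min_size) {
        add("deletion", c1$tend + 1L, c2$tstart - 1L, tgap - qgap)
      } else if (qgap >= min_size && tgap > -min_size && tgap < min_size) {
        add("insertion", c1$tend, c1$tend, qgap - max(0L, tgap))
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(kind = character(), start = integer(), end = integer(),
                         size = integer(), hap = integer(), confidence = character(),
                         stringsAsFactors = FALSE)
  # suppress the complex gap shadowing each inversion sub-chain; down-rank
  # calls inside a re-covered (duplicated) span, whose reference frame is ambiguous
  if (nrow(out)) {
    inv <- out[out$kind == "inversion", , drop = FALSE]
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(inv)))
      drop <- drop | (out$kind == "complex" & out$start <= inv$end[i] &
                        out$end >= inv$start[i])
    out <- out[!drop, , drop = FALSE]
    for (rc in recovered) {
      inside <- out$kind %in% c("deletion", "insertion", "complex") &
        out$start >= rc[1] & out$end <= rc[2] &
        !(out$kind %in% c("duplication", "insertion") & out$start == rc[1])
      out$confidence[inside] <- "low"
    }
    rownames(out) <- NULL
  }
  out
}

#' Detect and genotype structural variants from alignment chains
#'
#' Deletions are target gaps without query gaps; insertions query gaps
#' without target gaps; inversions strand-discordant sub-chains; extra
#' copies of a target span (query rewind between split chains) are tandem
#' duplications when the rewound chain is contiguous through the breakpoint,
#' else insertions of duplicated sequence. Sizes are exact block arithmetic.
#' Ambiguous signatures are reported with confidence "low", never dropped.
#'
#' @param chains_by_hap list of 1 or 2 chain lists (one per haplotype).
#' @param min_size minimum SV size (default 50; smaller events are indels).
#' @param match_tol breakpoint tolerance when pairing calls across
#'   haplotypes for genotyping (default 50).
#' @return list: `calls` (per-haplotype data.frame), `genotypes` (merged
#'   calls with gt in "0/1","1/1").
#' @export
detect_svs <- function(chains_by_hap, min_size = 50L, match_tol = 50L) {
  if (!length(chains_by_hap) %in% 1:2)
    stop("a donor has 1 or 2 haplotype chain sets", call. = FALSE)
  per_hap <- do.call(rbind, lapply(seq_along(chains_by_hap), function(h)
    detect_svs_one_hap(chains_by_hap[[h]], min_size, hap = h)))
  gts <- list()
  if (nrow(per_hap)) {
    left <- per_hap
    while (nrow(left)) {
      x <- left[1, ]
      mate <- which(left$kind == x$kind & left$hap != x$hap &
                      abs(left$start - x$start) <= match_tol)
      n_hap <- 1L + as.integer(length(mate) > 0L)
      gts[[length(gts) + 1L]] <- data.frame(
        kind = x$kind, start = x$start, end = x$end, size = x$size,
        gt = if (n_hap == length(chains_by_hap)) "1/1" else "0/1",
        confidence = x$confidence, stringsAsFactors = FALSE)
      left <- left[-c(1L, mate[1][!is.na(mate[1])]), , drop = FALSE]
    }
  }
  genotypes <- if (length(gts)) do.call(rbind, gts)
               else data.frame(kind = character(), start = integer(), end = integer(),
                               size = integer(), gt = character(),
                               confidence = character(), stringsAsFactors = FALSE)
  list(calls = per_hap, genotypes = genotypes)
}

# ---- callset comparison -------------------------------------------------

callset_positions <- function(x) {
  if (inherits(x, "callset")) {
    r <- x$records
    sort(unique(r$pos[!r$masked & r$type == "snv" & r$gt != "0/0"]))
  } else sort(unique(as.integer(x)))
}

#' Compare two callsets and a known-sites database
#'
#' @param set_a,set_b `callset`s or integer position vectors.
#' @param known_sites optional `callset`, VCF data.frame (with pos), or
#'   positions the callsets are checked for membership in.
#' @return list: counts of shared/private positions, private fractions, and
#'   membership fractions vs `known_sites`.
#' @export
compare_callsets <- function(set_a, set_b, known_sites = NULL) {
  pa <- callset_positions(set_a)
  pb <- callset_positions(set_b)
  shared <- intersect(pa, pb)
  out <- list(n_a = length(pa), n_b = length(pb),
              shared = length(shared),
              private_a = length(setdiff(pa, pb)),
              private_b = length(setdiff(pb, pa)),
              private_fraction_a = if (length(pa)) length(setdiff(pa, pb)) / length(pa) else NA_real_,
              private_fraction_b = if (length(pb)) length(setdiff(pb, pa)) / length(pb) else NA_real_)
  if (!is.null(known_sites)) {
    kp <- if (is.data.frame(known_sites)) sort(unique(known_sites$pos))
          else callset_positions(known_sites)
    out$membership_a <- if (length(pa)) mean(pa %in% kp) else NA_real_
    out$membership_b <- if (length(pb)) mean(pb %in% kp) else NA_real_
    out$novel_fraction_a <- if (length(pa)) 1 - out$membership_a else NA_real_
  }
  out
}

#' Upset-style intersection table of SNV positions across donors
#'
#' @param callsets named list of `callset`s (or position vectors), one per donor.
#' @return data.frame with one row per observed membership pattern and its count.
#' @export
upset_callsets <- function(callsets) {
  pos <- lapply(callsets, callset_positions)
  all_pos <- sort(unique(unlist(pos)))
  memb <- vapply(pos, function(p) all_pos %in% p, logical(length(all_pos)))
  if (length(all_pos) == 1L) memb <- matrix(memb, nrow = 1L,
                                            dimnames = list(NULL, names(callsets)))
  pat <- apply(memb, 1L, function(r) paste(ifelse(r, "1", "0"), collapse = ""))
  tab <- table(pat)
  data.frame(pattern = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
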