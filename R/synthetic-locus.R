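# Synthetic IGHC-like locus: reference + annotations, allele database,
# diploid cohorts with planted SNVs/SVs/alleles, and tiled simulated reads,
# all with machine-readable truth. Internal coordinates are 1-based closed;
# BED is 0-based half-open and VCF 1-based on export.

# Exon architectures (bp) loosely modelled on the human IGHC genes: CH
# domain exons ~290-340 bp, short hinge exons between CH1 and CH2 for the
# IgG/IgD classes (4 hinges in IGHG3), an extra CH4 exon for IgM/IgE.
ighc_gene_arch <- function() {
  list(
    IGHM  = c(CH1 = 294, CH2 = 330, CH3 = 318, CH4 = 322),
    IGHD  = c(CH1 = 294, H1 = 47, H2 = 47, CH2 = 330, CH3 = 323),
    IGHG3 = c(CH1 = 294, H1 = 47, H2 = 47, H3 = 47, H4 = 47, CH2 = 327, CH3 = 323),
    IGHG1 = c(CH1 = 294, H1 = 45, CH2 = 327, CH3 = 323),
    IGHA1 = c(CH1 = 293, CH2 = 330, CH3 = 340),
    IGHG2 = c(CH1 = 294, H1 = 36, CH2 = 327, CH3 = 323),
    IGHG4 = c(CH1 = 294, H1 = 36, CH2 = 327, CH3 = 323),
    IGHE  = c(CH1 = 290, CH2 = 315, CH3 = 318, CH4 = 323),
    IGHA2 = c(CH1 = 293, CH2 = 330, CH3 = 340)
  )
}

# Hinge exons sit 141 bp apart so one hinge exon plus its upstream intron is
# exactly 188 bp -- the size of the recurrent IGHG3 hinge-copy indel.
HINGE_INTRON <- 141L
CH_INTRON <- 350L

#' Default gene models for a synthetic IGHC-like locus
#'
#' Places the nine canonical constant genes (IGHM..IGHA2, 5'->3') along the
#' locus; the IGHG4 gene lands inside the default paralog source block so the
#' duplicated copy carries a second annotated IGHG4-like gene.
#'
#' @param locus_length locus size in bases.
#' @return data.frame with columns gene, exon, start, end, type, strand.
#' @export
default_gene_models <- function(locus_length = 400000L) {
  arch <- ighc_gene_arch()
  frac <- c(IGHM = 0.05, IGHD = 0.15, IGHG3 = 0.25, IGHG1 = 0.35, IGHA1 = 0.44,
            IGHG2 = 0.525, IGHG4 = 0.625, IGHE = 0.775, IGHA2 = 0.865)
  rows <- list()
  for (g in names(arch)) {
    start <- as.integer(round(locus_length * frac[[g]]))
    pos <- start
    ex <- arch[[g]]
    for (i in seq_along(ex)) {
      type <- names(ex)[i]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, exon = i, start = as.integer(pos), end = as.integer(pos + ex[[i]] - 1L),
        type = type, strand = "+", stringsAsFactors = FALSE)
      intron <- if (startsWith(type, "H") ||
                    (i < length(ex) && startsWith(names(ex)[i + 1L], "H")))
        HINGE_INTRON else CH_INTRON
      pos <- pos + ex[[i]] + intron
    }
  }
  do.call(rbind, rows)
}

#' Default paralog duplication blocks
#'
#' One high-identity tandem duplication: a 20 kb block containing the IGHG4
#' gene copied immediately downstream, diverged so that every 1 kb window of
#' the copy differs from its source (guaranteeing unambiguous exact overlaps
#' of 2 kb or more).
#'
#' @param locus_length locus size in bases.
#' @param per_kb_divergence planted differences per kb (>= 1).
#' @return data.frame with src_start, src_end, copy_start, copy_end, per_kb_divergence.
#' @export
default_paralog_blocks <- function(locus_length = 400000L, per_kb_divergence = 2) {
  g4 <- as.integer(round(locus_length * 0.625))
  block_len <- max(4000L, as.integer(round(locus_length * 0.05)))
  src_start <- g4 - as.integer(round(block_len * 0.25))
  src_end <- src_start + block_len - 1L
  data.frame(src_start = src_start, src_end = src_end,
             copy_start = src_end + 1L, copy_end = src_end + block_len,
             per_kb_divergence = per_kb_divergence)
}

#' Specification for a synthetic locus
#'
#' @param locus_length locus size in bases (default 400 kb).
#' @param gene_models data.frame of exon intervals (see [default_gene_models()]).
#' @param paralog_blocks data.frame of duplication blocks
#'   (see [default_paralog_blocks()]); may have zero rows.
#' @param seed integer seed.
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(locus_length = 400000L,
                       gene_models = default_gene_models(locus_length),
                       paralog_blocks = default_paralog_blocks(locus_length),
                       seed = 1L) {
  spec <- structure(list(locus_length = as.integer(locus_length),
                         gene_models = gene_models,
                         paralog_blocks = paralog_blocks,
                         seed = as.integer(seed)),
                    class = "locus_spec")
  validate_locus_spec(spec)
  spec
}

validate_locus_spec <- function(spec) {
  gm <- spec$gene_models
  if (any(gm$start < 1L) || any(gm$end > spec$locus_length))
    stop("exon outside locus", call. = FALSE)
  if (any(gm$end < gm$start)) stop("empty exon interval", call. = FALSE)
  ord <- order(gm$start)
  s <- gm$start[ord]; e <- gm$end[ord]
  if (any(s[-1L] <= e[-length(e)])) stop("overlapping exons", call. = FALSE)
  pb <- spec$paralog_blocks
  if (nrow(pb)) {
    if (any(pb$per_kb_divergence < 1)) stop("per_kb_divergence must be >= 1", call. = FALSE)
    if (any(pb$copy_end > spec$locus_length) || any(pb$src_start < 1L))
      stop("paralog block outside locus", call. = FALSE)
    if (any(pb$src_end - pb$src_start != pb$copy_end - pb$copy_start))
      stop("paralog source and copy must be the same length", call. = FALSE)
  }
  invisible(spec)
}

#' Build a synthetic locus reference
#'
#' Generates a random sequence, stamps each paralog copy as a diverged
#' duplicate of its source (at least one planted difference per 1 kb window),
#' and lifts annotations for genes fully inside a source block onto the copy
#' (suffix "B"). Deterministic given the spec seed.
#'
#' @param spec a [locus_spec()].
#' @return object of class `locus_reference` with fields id, seq, length,
#'   genes (exon table), paralog_blocks.
#' @export
build_locus <- function(spec = locus_spec()) {
  validate_locus_spec(spec)
  with_seed(spec$seed, {
    seqv <- sample(DNA_BASES, spec$locus_length, replace = TRUE)
    genes <- spec$gene_models
    pb <- spec$paralog_blocks
    for (i in seq_len(nrow(pb))) {
      src <- seqv[pb$src_start[i]:pb$src_end[i]]
      len <- length(src)
      copy <- src
      wins <- seq(1L, len, by = 1000L)
      nmut <- max(1L, as.integer(round(pb$per_kb_divergence[i])))
      for (ws in wins) {
        we <- min(ws + 999L, len)
        pos <- if (we - ws + 1L <= nmut) ws:we else sample(ws:we, nmut)
        copy[pos] <- vapply(copy[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      }
      seqv[pb$copy_start[i]:pb$copy_end[i]] <- copy
      off <- pb$copy_start[i] - pb$src_start[i]
      inside <- genes$start >= pb$src_start[i] & genes$end <= pb$src_end[i]
      for (g in unique(genes$gene[inside])) {
        sel <- genes$gene == g
        if (!all(inside[sel])) next  # gene only partially inside the block
        cp <- genes[sel, , drop = FALSE]
        cp$gene <- paste0(g, "B")
        cp$start <- cp$start + off
        cp$end <- cp$end + off
        genes <- rbind(genes, cp)
      }
    }
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    ref <- structure(list(id = "IGHC_syn", seq = paste(seqv, collapse = ""),
                          length = spec$locus_length, genes = genes,
                          paralog_blocks = pb, spec = spec),
                     class = "locus_reference")
    stopifnot(all(check_paralog_divergence(ref)$min_diffs >= 1L))
    ref
  })
}

#' Scan paralog blocks for per-window divergence
#'
#' @param reference a `locus_reference`.
#' @param window window size in bases.
#' @return data.frame with one row per block: min and mean differences per window.
#' @export
check_paralog_divergence <- function(reference, window = 1000L) {
  pb <- reference$paralog_blocks
  out <- lapply(seq_len(nrow(pb)), function(i) {
    src <- substr(reference$seq, pb$src_start[i], pb$src_end[i])
    cp <- substr(reference$seq, pb$copy_start[i], pb$copy_end[i])
    a <- utf8ToInt(src); b <- utf8ToInt(cp)
    diffs <- a != b
    starts <- seq(1L, length(diffs), by = window)
    per_win <- vapply(starts, function(s) sum(diffs[s:min(s + window - 1L, length(diffs))]), 0L)
    data.frame(block = i, min_diffs = min(per_win), mean_diffs = mean(per_win))
  })
  do.call(rbind, out)
}

#' @export
print.locus_reference <- function(x, ...) {
  cat(sprintf("<locus_reference %s: %d bp, %d genes, %d paralog block(s)>\n",
              x$id, x$length, length(unique(x$genes$gene)), nrow(x$paralog_blocks)))
  invisible(x)
}

gene_exons <- function(reference, gene) {
  ex <- reference$genes[reference$genes$gene == gene, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown gene: ", gene, call. = FALSE)
  ex[order(ex$exon), , drop = FALSE]
}

#' Spliced exon sequence of a gene from a reference
#' @param reference a `locus_reference`.
#' @param gene gene id.
#' @return character scalar (reverse-complemented for minus-strand genes).
#' @export
splice_gene <- function(reference, gene) {
  ex <- gene_exons(reference, gene)
  s <- paste(substring(reference$seq, ex$start, ex$end), collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

# ---- allele database ----------------------------------------------------

#' Generate a stand-in germline allele database
#'
#' For every annotated gene, allele *01 equals the reference spliced exon
#' sequence; additional alleles differ from *01 by 1-5 exonic substitutions.
#' All sequences within a gene are distinct.
#'
#' @param reference a `locus_reference`.
#' @param n_alleles_per_gene alleles per gene (>= 1).
#' @param seed integer seed.
#' @return object of class `allele_database`: data.frame(gene, allele, name,
#'   seq, exon_lengths).
#' @export
spawn_allele_database <- function(reference, n_alleles_per_gene = 3L, seed = 1L) {
  if (n_alleles_per_gene < 1L) stop("n_alleles_per_gene must be >= 1", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (g in unique(reference$genes$gene)) {
      ex <- gene_exons(reference, g)
      ref_seq <- splice_gene(reference, g)
      lens <- paste(ex$end - ex$start + 1L, collapse = ",")
      seqs <- ref_seq
      for (a in seq_len(n_alleles_per_gene)) {
        if (a == 1L) s <- ref_seq
        else repeat {
          k <- sample(1:5, 1L)
          pos <- sample(nchar(ref_seq), k)
          s <- substitute_bases(ref_seq, pos, mutate_base(substring(ref_seq, pos, pos)))
          if (!s %in% seqs) break
        }
        seqs <- union(seqs, s)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, allele = sprintf("*%02d", a),
          name = sprintf("%s*%02d", g, a), seq = s, exon_lengths = lens,
          stringsAsFactors = FALSE)
      }
    }
    structure(do.call(rbind, rows), class = c("allele_database", "data.frame"))
  })
}

#' Write an allele database as FASTA with structured headers
#'
#' Header grammar: `>GENE*NN|exons=l1,l2,...` where l's are exon lengths that
#' partition the spliced sequence.
#'
#' @param db an `allele_database`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_db <- function(db, path) {
  seqs <- db$seq
  names(seqs) <- paste0(db$name, "|exons=", db$exon_lengths)
  write_fasta(seqs, path)
}

#' @rdname write_allele_db
#' @export
read_allele_db <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  name <- sub("\\|.*$", "", hdr)
  db <- data.frame(gene = sub("\\*.*$", "", name),
                   allele = sub("^[^*]+", "", name),
                   name = name, seq = toupper(as.character(x)),
                   exon_lengths = sub("^.*exons=", "", hdr),
                   stringsAsFactors = FALSE)
  rownames(db) <- NULL
  structure(db, class = c("allele_database", "data.frame"))
}

# ---- SV events ----------------------------------------------------------

SV_KINDS <- c("deletion", "insertion", "inversion", "tandem_duplication",
              "hinge_exon_indel")

#' Construct a structural-variant event
#'
#' @param kind one of deletion, insertion, inversion, tandem_duplication,
#'   hinge_exon_indel (a deletion whose size defaults to 188 bp).
#' @param start 1-based reference start (insertion: payload inserted after
#'   this position).
#' @param end 1-based reference end (ignored for insertion).
#' @param payload inserted nucleotide sequence (insertion only).
#' @param copies extra copies appended (tandem_duplication only).
#' @param id optional event label.
#' @return object of class `sv_event`.
#' @export
sv_event <- function(kind, start, end = NULL, payload = NULL, copies = 1L, id = NULL) {
  kind <- match.arg(kind, SV_KINDS)
  start <- as.integer(start)
  if (kind == "hinge_exon_indel" && is.null(end)) end <- start + 187L
  if (kind == "insertion") {
    stop_if_not_scalar_seq(payload, "insertion payload")
    end <- start
    size <- nchar(payload)
  } else {
    end <- as.integer(end)
    if (is.null(end) || end < start) stop("event needs end >= start", call. = FALSE)
    size <- switch(kind,
                   tandem_duplication = (end - start + 1L) * as.integer(copies),
                   end - start + 1L)
  }
  if (size <= 0L) stop("event size must be > 0", call. = FALSE)
  structure(list(kind = kind, start = start, end = end, payload = payload,
                 copies = as.integer(copies), size = as.integer(size),
                 id = id %||% sprintf("%s_%d", kind, start)),
            class = "sv_event")
}

#' Default structural-variant events mirroring the locus's recurrent SV classes
#'
#' A 188 bp hinge-exon indel in IGHG3 (hinge copy 4 -> 3), a 4.5 kb
#' intergenic inversion between IGHG2 and the IGHG4 block, a ~19.5 kb
#' deletion removing the duplicated IGHG4-like block, a tandem extra copy of
#' the IGHG4 block (triplication), and a multi-gene insertion duplicating
#' the IGHG2..IGHE span.
#'
#' @param reference a `locus_reference` built from the default spec.
#' @return named list of `sv_event`s.
#' @export
default_sv_events <- function(reference) {
  genes <- reference$genes
  pb <- reference$paralog_blocks[1, ]
  h4 <- genes[genes$gene == "IGHG3" & genes$type == "H4", ]
  hinge <- sv_event("hinge_exon_indel", h4$start - HINGE_INTRON, h4$end,
                    id = "hinge_indel_188")
  g2_end <- max(genes$end[genes$gene == "IGHG2"])
  inv_start <- g2_end + 1000L
  inv_len <- min(4500L, pb$src_start - inv_start - 500L)  # 4.5 kb at default scale
  if (inv_len < 200L) stop("locus too small for the default inversion event", call. = FALSE)
  inv <- sv_event("inversion", inv_start, inv_start + inv_len - 1L, id = "inversion_4k5")
  # deletes the duplicated IGHG4-like block (19.5 kb at the default scale)
  region_del <- sv_event("deletion", pb$copy_start, pb$copy_end - 500L,
                         id = "region_del_19k5")
  trip <- sv_event("tandem_duplication", pb$copy_start, pb$copy_end, copies = 1L,
                   id = "g4_triplication")
  ins_at <- max(genes$end[genes$gene == "IGHE"]) + 2000L
  ins_src <- c(min(genes$start[genes$gene == "IGHG2"]) - 2000L, ins_at - 1000L)
  ins <- sv_event("insertion", ins_at,
                  payload = substr(reference$seq, ins_src[1], ins_src[2]),
                  id = "multigene_ins")
  list(hinge_indel = hinge, inversion = inv, region_del = region_del,
       triplication = trip, multigene_ins = ins)
}

validate_events <- function(events, locus_length) {
  if (length(events) == 0L) return(invisible(events))
  s <- vapply(events, function(e) e$start, 0L)
  e <- vapply(events, function(ev) ev$end, 0L)
  if (any(s < 1L) || any(e > locus_length)) stop("event outside locus", call. = FALSE)
  ord <- order(s)
  if (any(s[ord][-1L] <= e[ord][-length(ord)]))
    stop("overlapping events", call. = FALSE)
  invisible(events[ord])
}

apply_sv_events <- function(seq, events) {
  if (length(events) == 0L) return(seq)
  s <- vapply(events, function(e) e$start, 0L)
  for (ev in events[order(s, decreasing = TRUE)]) {
    left <- substr(seq, 1L, ev$start - 1L)
    seg <- substr(seq, ev$start, ev$end)
    right <- substr(seq, ev$end + 1L, nchar(seq))
    seq <- switch(ev$kind,
      deletion = , hinge_exon_indel = paste0(left, right),
      inversion = paste0(left, revcomp(seg), right),
      tandem_duplication = paste0(left, seg, strrep(seg, ev$copies), right),
      insertion = paste0(left, seg, ev$payload, right))
  }
  seq
}

exonic_mask <- function(reference) {
  ex <- reference$genes
  m <- logical(reference$length)
  for (i in seq_len(nrow(ex))) m[ex$start[i]:ex$end[i]] <- TRUE
  m
}

event_intervals <- function(events) {
  if (length(events) == 0L)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(events, function(e) e$start, 0L),
             end = vapply(events, function(e) e$end, 0L))
}

genes_hit_by_events <- function(reference, events) {
  iv <- event_intervals(events)
  hit <- character()
  for (i in seq_len(nrow(iv))) {
    ev <- events[[i]]
    g <- reference$genes
    ov <- if (ev$kind == "insertion")
      g$start < ev$start & g$end > ev$start  # breakpoint strictly inside an exon
    else g$start <= iv$end[i] & g$end >= iv$start[i]
    hit <- union(hit, unique(g$gene[ov]))
  }
  hit
}

# ---- haplotype simulation ----------------------------------------------

allele_substitutions <- function(reference, allele_db, gene, allele) {
  db <- allele_db[allele_db$gene == gene, , drop = FALSE]
  if (nrow(db) == 0L) stop("gene absent from allele database: ", gene, call. = FALSE)
  ref_seq <- db$seq[db$allele == "*01"]
  alt_seq <- db$seq[db$allele == allele]
  if (length(alt_seq) != 1L) stop("unknown allele ", gene, allele, call. = FALSE)
  if (nchar(alt_seq) != nchar(ref_seq))
    stop("only substitution alleles can be planted genomically", call. = FALSE)
  pos <- mismatch_positions(ref_seq, alt_seq)
  if (length(pos) == 0L)
    return(data.frame(pos = integer(), ref = character(), alt = character()))
  ex <- gene_exons(reference, gene)
  offs <- cumsum(c(0L, ex$end - ex$start + 1L))
  gpos <- as.integer(vapply(pos, function(p) {
    i <- findInterval(p - 1L, offs)
    ex$start[i] + (p - offs[i] - 1L)
  }, 0))
  data.frame(pos = gpos,
             ref = substring(reference$seq, gpos, gpos),
             alt = substring(alt_seq, pos, pos), stringsAsFactors = FALSE)
}

#' Simulate one haplotype from a reference
#'
#' Applies (in order) allele substitutions in exons, planted SNVs at
#' non-exonic positions, then structural variants right-to-left. The returned
#' event log replays to the exact sequence (see [replay_haplotype()]). Genes
#' whose exons intersect a structural variant are dropped from the allele
#' assignment truth (their spliced product is structurally altered).
#'
#' @param reference a `locus_reference`.
#' @param allele_db an `allele_database` (required when `alleles` given).
#' @param events list of [sv_event()]s (non-overlapping).
#' @param snvs data.frame(pos, alt) of planted SNVs (non-exonic unless
#'   `allow_exonic_snvs`), or NULL.
#' @param snv_rate per-base probability of planting a random non-exonic SNV
#'   (used only when `snvs` is NULL).
#' @param alleles named character vector gene -> allele label (e.g. "*02").
#' @param donor_id,haplotype_index truth bookkeeping labels.
#' @param allow_exonic_snvs permit planted SNVs inside exons.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return object of class `truth_haplotype`: donor_id, haplotype_index, seq,
#'   event_log (subs table + sv list), allele_assignments.
#' @export
simulate_haplotype <- function(reference, allele_db = NULL, events = list(),
                               snvs = NULL, snv_rate = 0, alleles = NULL,
                               donor_id = "donor", haplotype_index = 1L,
                               allow_exonic_snvs = FALSE, seed = 1L) {
  run <- function() {
    events <- validate_events(events, reference$length)
    exmask <- exonic_mask(reference)
    subs <- data.frame(pos = integer(), ref = character(), alt = character(),
                       kind = character(), gene = character(), stringsAsFactors = FALSE)
    if (!is.null(alleles) && length(alleles)) {
      if (is.null(allele_db)) stop("allele_db required to plant alleles", call. = FALSE)
      for (g in names(alleles)) {
        as_ <- allele_substitutions(reference, allele_db, g, alleles[[g]])
        if (nrow(as_))
          subs <- rbind(subs, cbind(as_, kind = "allele", gene = g))
      }
    }
    if (is.null(snvs) && snv_rate > 0) {
      elig <- which(!exmask)
      iv <- event_intervals(events)
      for (i in seq_len(nrow(iv))) elig <- elig[elig < iv$start[i] | elig > iv$end[i]]
      n <- stats::rbinom(1L, length(elig), snv_rate)
      if (n > 0L) {
        pos <- sort(sample(elig, n))
        snvs <- data.frame(pos = pos, alt = mutate_base(substring(reference$seq, pos, pos)))
      }
    }
    if (!is.null(snvs) && nrow(snvs)) {
      if (!allow_exonic_snvs && any(exmask[snvs$pos]))
        stop("planted SNV inside an exon (set allow_exonic_snvs)", call. = FALSE)
      subs <- rbind(subs, data.frame(pos = snvs$pos,
                                     ref = substring(reference$seq, snvs$pos, snvs$pos),
                                     alt = snvs$alt, kind = "snv", gene = NA_character_,
                                     stringsAsFactors = FALSE))
    }
    if (anyDuplicated(subs$pos)) stop("duplicate substitution positions", call. = FALSE)
    seq <- substitute_bases(reference$seq, subs$pos, subs$alt)
    seq <- apply_sv_events(seq, events)
    assignments <- alleles
    if (length(events) && !is.null(assignments)) {
      hit <- genes_hit_by_events(reference, events)
      assignments <- assignments[setdiff(names(assignments), hit)]
    }
    structure(list(donor_id = donor_id, haplotype_index = as.integer(haplotype_index),
                   seq = seq,
                   event_log = list(subs = subs[order(subs$pos), , drop = FALSE],
                                    svs = events),
                   allele_assignments = assignments),
              class = "truth_haplotype")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Replay a truth haplotype's event log against the reference
#' @param reference a `locus_reference`.
#' @param event_log the `event_log` field of a `truth_haplotype`.
#' @return reconstructed sequence (character scalar).
#' @export
replay_haplotype <- function(reference, event_log) {
  seq <- substitute_bases(reference$seq, event_log$subs$pos, event_log$subs$alt)
  apply_sv_events(seq, event_log$svs)
}

# ---- cohort simulation --------------------------------------------------

#' Specification of a simulated population cohort
#'
#' @param populations character vector of population labels.
#' @param donors_per_population donors per population (recycled).
#' @param snv_sites data.frame(pos, alt) of polymorphic non-exonic sites.
#' @param snv_freq matrix sites x populations of ALT allele frequencies.
#' @param sv_events list of [sv_event()]s segregating in the cohort.
#' @param sv_freq matrix events x populations of carrier-haplotype frequencies.
#' @param allele_freq named list (gene -> matrix alleles x populations, columns
#'   summing to 1) of allele frequencies.
#' @param fixed_sites optional data.frame(site, population): site index fixed
#'   ALT in that population and fixed REF elsewhere.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(populations, donors_per_population, snv_sites,
                            snv_freq, sv_events = list(), sv_freq = NULL,
                            allele_freq = list(), fixed_sites = NULL) {
  donors_per_population <- rep_len(as.integer(donors_per_population), length(populations))
  snv_freq <- as.matrix(snv_freq)
  colnames(snv_freq) <- populations
  if (!is.null(fixed_sites)) {
    for (i in seq_len(nrow(fixed_sites))) {
      snv_freq[fixed_sites$site[i], ] <- 0
      snv_freq[fixed_sites$site[i], fixed_sites$population[i]] <- 1
    }
  }
  if (any(snv_freq < 0 | snv_freq > 1)) stop("SNV frequencies outside [0,1]", call. = FALSE)
  if (length(sv_events)) {
    sv_freq <- as.matrix(sv_freq)
    colnames(sv_freq) <- populations
    if (any(sv_freq < 0 | sv_freq > 1)) stop("SV frequencies outside [0,1]", call. = FALSE)
  }
  for (g in names(allele_freq)) {
    m <- allele_freq[[g]]
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-8))
      stop("allele frequencies for ", g, " must be in [0,1] and sum to 1 per population",
           call. = FALSE)
  }
  structure(list(populations = populations,
                 donors_per_population = donors_per_population,
                 snv_sites = snv_sites, snv_freq = snv_freq,
                 sv_events = sv_events, sv_freq = sv_freq,
                 allele_freq = allele_freq, fixed_sites = fixed_sites),
            class = "population_spec")
}

#' Draw a randomized population specification for a reference
#'
#' Defaults emulate a small multi-population study: three populations,
#' population-specific SNV frequencies at non-exonic sites placed outside
#' every candidate SV footprint, segregating SVs, and per-population gene
#' allele frequencies.
#'
#' @param reference a `locus_reference`.
#' @param allele_db an `allele_database`.
#' @param populations population labels.
#' @param donors_per_population donors per population.
#' @param n_snv_sites number of polymorphic SNV sites.
#' @param sv_events candidate SVs (default [default_sv_events()]); use
#'   `list()` for an SV-free cohort.
#' @param sv_freq_range carrier-frequency range for each SV per population.
#' @param n_fixed number of sites forced to fixation in a single population.
#' @param seed integer seed.
#' @return a `population_spec`.
#' @export
random_population_spec <- function(reference, allele_db,
                                   populations = c("AFR", "EAS", "EUR"),
                                   donors_per_population = 5L,
                                   n_snv_sites = 120L,
                                   sv_events = default_sv_events(reference),
                                   sv_freq_range = c(0.1, 0.5),
                                   n_fixed = 2L, seed = 1L) {
  with_seed(seed, {
    exmask <- exonic_mask(reference)
    elig <- which(!exmask)
    iv <- event_intervals(sv_events)
    pad <- 200L
    for (i in seq_len(nrow(iv)))
      elig <- elig[elig < iv$start[i] - pad | elig > iv$end[i] + pad]
    pos <- sort(sample(elig, n_snv_sites))
    sites <- data.frame(pos = pos, alt = mutate_base(substring(reference$seq, pos, pos)))
    base <- stats::runif(n_snv_sites, 0.05, 0.95)
    freq <- vapply(seq_along(populations), function(j)
      pmin(1, pmax(0, base + stats::rnorm(n_snv_sites, 0, 0.25))), numeric(n_snv_sites))
    fixed <- NULL
    if (n_fixed > 0L) {
      fixed <- data.frame(site = sample(n_snv_sites, n_fixed),
                          population = sample(populations, n_fixed, replace = TRUE))
    }
    svf <- NULL
    if (length(sv_events))
      svf <- matrix(stats::runif(length(sv_events) * length(populations),
                                 sv_freq_range[1], sv_freq_range[2]),
                    nrow = length(sv_events),
                    dimnames = list(vapply(sv_events, function(e) e$id, ""), populations))
    af <- list()
    for (g in unique(allele_db$gene)) {
      alleles <- allele_db$allele[allele_db$gene == g]
      m <- matrix(stats::rgamma(length(alleles) * length(populations), shape = 1),
                  nrow = length(alleles), dimnames = list(alleles, populations))
      af[[g]] <- sweep(m, 2, colSums(m), "/")
    }
    population_spec(populations, donors_per_population, sites, freq,
                    sv_events, svf, af, fixed)
  })
}

#' Simulate a diploid cohort with full truth bookkeeping
#'
#' Each donor receives two haplotypes drawn independently from its
#' population's SNV, SV, and allele frequencies (no linkage model). Truth
#' tables record per-donor SNV dosages, SV genotypes, and per-haplotype
#' allele assignments.
#'
#' @param reference a `locus_reference`.
#' @param allele_db an `allele_database`.
#' @param pop_spec a `population_spec`.
#' @param seed integer seed.
#' @return object of class `cohort`: donors (list with two `truth_haplotype`s
#'   each), labels, truth (snv/sv/allele data.frames), reference, allele_db,
#'   pop_spec.
#' @export
simulate_cohort <- function(reference, allele_db, pop_spec, seed = 1L) {
  if (sum(pop_spec$donors_per_population) == 0L) stop("zero donors", call. = FALSE)
  with_seed(seed, {
    donors <- list(); labels <- list()
    snv_rows <- list(); sv_rows <- list(); allele_rows <- list()
    sites <- pop_spec$snv_sites
    n_sites <- nrow(sites)
    for (pi in seq_along(pop_spec$populations)) {
      pop <- pop_spec$populations[pi]
      for (d in seq_len(pop_spec$donors_per_population[pi])) {
        donor_id <- sprintf("%s_%02d", pop, d)
        haps <- list()
        carried <- matrix(FALSE, nrow = n_sites, ncol = 2L)
        sv_carried <- matrix(FALSE, nrow = length(pop_spec$sv_events), ncol = 2L)
        for (h in 1:2) {
          has_snv <- stats::runif(n_sites) < pop_spec$snv_freq[, pop]
          carried[, h] <- has_snv
          ev <- list()
          if (length(pop_spec$sv_events)) {
            has_sv <- stats::runif(length(pop_spec$sv_events)) < pop_spec$sv_freq[, pop]
            # overlapping SV pairs cannot co-occur on one haplotype: greedy keep
            keep <- logical(length(has_sv))
            occ <- data.frame(start = integer(), end = integer())
            for (k in order(vapply(pop_spec$sv_events, function(e) e$start, 0L))) {
              if (!has_sv[k]) next
              e <- pop_spec$sv_events[[k]]
              if (!nrow(occ) || all(e$end < occ$start | e$start > occ$end)) {
                keep[k] <- TRUE
                occ <- rbind(occ, data.frame(start = e$start, end = e$end))
              }
            }
            sv_carried[, h] <- keep
            ev <- pop_spec$sv_events[keep]
          }
          alleles <- character(0)
          for (g in names(pop_spec$allele_freq)) {
            m <- pop_spec$allele_freq[[g]]
            alleles[g] <- sample(rownames(m), 1L, prob = m[, pop])
          }
          haps[[h]] <- simulate_haplotype(
            reference, allele_db, events = ev,
            snvs = if (any(has_snv)) sites[has_snv, , drop = FALSE] else NULL,
            alleles = if (length(alleles)) alleles else NULL,
            donor_id = donor_id, haplotype_index = h, seed = NULL)
          aa <- haps[[h]]$allele_assignments
          if (length(aa))
            allele_rows[[length(allele_rows) + 1L]] <- data.frame(
              donor = donor_id, haplotype = h, gene = names(aa), allele = unname(aa),
              stringsAsFactors = FALSE)
        }
        if (n_sites)
          snv_rows[[length(snv_rows) + 1L]] <- data.frame(
            donor = donor_id, site = seq_len(n_sites), pos = sites$pos,
            ref = substring(reference$seq, sites$pos, sites$pos), alt = sites$alt,
            dosage = carried[, 1] + carried[, 2], stringsAsFactors = FALSE)
        if (length(pop_spec$sv_events))
          sv_rows[[length(sv_rows) + 1L]] <- data.frame(
            donor = donor_id,
            event = vapply(pop_spec$sv_events, function(e) e$id, ""),
            kind = vapply(pop_spec$sv_events, function(e) e$kind, ""),
            start = vapply(pop_spec$sv_events, function(e) e$start, 0L),
            end = vapply(pop_spec$sv_events, function(e) e$end, 0L),
            size = vapply(pop_spec$sv_events, function(e) e$size, 0L),
            dosage = sv_carried[, 1] + sv_carried[, 2], stringsAsFactors = FALSE)
        donors[[donor_id]] <- list(donor_id = donor_id, population = pop,
                                   haplotypes = haps)
        labels[[length(labels) + 1L]] <- data.frame(donor = donor_id, population = pop,
                                                    stringsAsFactors = FALSE)
      }
    }
    structure(list(reference = reference, allele_db = allele_db,
                   pop_spec = pop_spec, donors = donors,
                   labels = do.call(rbind, labels),
                   truth = list(
                     snv = if (length(snv_rows)) do.call(rbind, snv_rows) else NULL,
                     sv = if (length(sv_rows)) do.call(rbind, sv_rows) else NULL,
                     allele = if (length(allele_rows)) do.call(rbind, allele_rows) else NULL)),
              class = "cohort")
  })
}

# ---- read simulation ----------------------------------------------------

#' Specification for tiled read simulation
#'
#' "Random reads with overlapping boundaries" are realized as tiling passes
#' with step `read_length/2` plus jitter up to a quarter step, truncated to
#' the per-haplotype coverage cap.
#'
#' @param read_lengths read lengths in bases.
#' @param coverage_per_haplotype fold coverage per haplotype per length bin.
#' @param substitution_error_rate independent per-base substitution
#'   probability (no indel errors).
#' @param tiling_step tiling step; default half the read length.
#' @param seed integer seed.
#' @return object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_lengths = c(350L, 3000L, 6000L, 10000L),
                          coverage_per_haplotype = 15,
                          substitution_error_rate = 0,
                          tiling_step = NULL, seed = 1L) {
  if (coverage_per_haplotype <= 0) stop("coverage must be > 0", call. = FALSE)
  if (substitution_error_rate < 0 || substitution_error_rate >= 1)
    stop("error rate must be in [0,1)", call. = FALSE)
  structure(list(read_lengths = as.integer(read_lengths),
                 coverage_per_haplotype = coverage_per_haplotype,
                 substitution_error_rate = substitution_error_rate,
                 tiling_step = tiling_step, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate tiled reads from a haplotype
#'
#' For each length bin, tiling passes with random phase cover the haplotype;
#' reads are dropped from the final pass so total bases fall within 5% of
#' the requested coverage. Every read records its true source interval.
#'
#' @param haplotype a `truth_haplotype` or character sequence.
#' @param read_spec a [read_sim_spec()].
#' @param label source label used in read ids (defaults to donor/haplotype).
#' @return data.frame: read_id, source, length_bin, start, end, strand, seq.
#' @export
simulate_reads <- function(haplotype, read_spec = read_sim_spec(), label = NULL) {
  seq <- if (inherits(haplotype, "truth_haplotype")) haplotype$seq else haplotype
  stop_if_not_scalar_seq(seq, "haplotype")
  n <- nchar(seq)
  if (is.null(label)) {
    label <- if (inherits(haplotype, "truth_haplotype"))
      sprintf("%s_h%d", haplotype$donor_id, haplotype$haplotype_index) else "hap"
  }
  with_seed(read_spec$seed, {
    out <- list()
    for (L in read_spec$read_lengths) {
      if (L >= n) stop("read length must be smaller than the haplotype", call. = FALSE)
      step <- read_spec$tiling_step %||% max(1L, L %/% 2L)
      cov_per_pass <- L / step
      npass <- as.integer(ceiling(read_spec$coverage_per_haplotype / cov_per_pass))
      jmax <- max(1L, step %/% 4L)
      starts_by_pass <- vector("list", npass)
      for (p in seq_len(npass)) {
        s <- if (p == 1L) 1L else sample.int(step, 1L)
        starts <- integer()
        while (s <= n - 1L) {
          starts <- c(starts, s)
          s <- s + step + sample(seq(-jmax, jmax), 1L)
        }
        starts_by_pass[[p]] <- starts
      }
      starts <- unlist(starts_by_pass)
      pass <- rep(seq_len(npass), lengths(starts_by_pass))
      ends <- pmin(starts + L - 1L, n)
      target <- read_spec$coverage_per_haplotype * n
      total <- sum(ends - starts + 1L)
      if (total > target) {
        drop_pool <- sample(which(pass == npass))
        for (i in drop_pool) {
          len_i <- ends[i] - starts[i] + 1L
          if (total - len_i >= target * 0.995) {
            total <- total - len_i
            starts[i] <- NA_integer_
          }
          if (total <= target) break
        }
        keep <- !is.na(starts)
        starts <- starts[keep]; ends <- ends[keep]
      }
      ord <- order(starts)
      starts <- starts[ord]; ends <- ends[ord]
      seqs <- substring(seq, starts, ends)
      e <- read_spec$substitution_error_rate
      if (e > 0) {
        nerr <- stats::rbinom(length(seqs), nchar(seqs), e)
        for (i in which(nerr > 0L)) {
          pos <- sample(nchar(seqs[i]), nerr[i])
          seqs[i] <- substitute_bases(seqs[i], pos,
                                      mutate_base(substring(seqs[i], pos, pos)))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("%s_L%d_r%05d", label, L, seq_along(starts)),
        source = label, length_bin = L, start = starts, end = ends,
        strand = "+", seq = seqs, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# ---- truth emission -----------------------------------------------------

dosage_to_gt <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

#' Write a cohort's truth bundle to a directory
#'
#' Emits reference FASTA, exon/paralog BED annotations, all truth haplotype
#' FASTA, a truth VCF of planted SNV genotypes, SV and allele genotype TSVs,
#' and population labels. Files round-trip through the package readers
#' (see [read_truth()]).
#'
#' @param cohort a `cohort`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
emit_truth <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- cohort$reference
  paths <- c(reference = file.path(out_dir, "reference.fasta"),
             exons = file.path(out_dir, "exons.bed"),
             blocks = file.path(out_dir, "paralog_blocks.bed"),
             haplotypes = file.path(out_dir, "haplotypes.fasta"),
             vcf = file.path(out_dir, "truth_snv.vcf"),
             sv = file.path(out_dir, "truth_sv.tsv"),
             allele = file.path(out_dir, "truth_allele.tsv"),
             labels = file.path(out_dir, "populations.tsv"))
  write_fasta(stats::setNames(ref$seq, ref$id), paths["reference"])
  g <- ref$genes
  write_bed(data.frame(chrom = ref$id, start = g$start, end = g$end,
                       name = paste(g$gene, g$exon, g$type, sep = "|"),
                       score = 0L, strand = g$strand), paths["exons"])
  pb <- ref$paralog_blocks
  if (nrow(pb)) {
    write_bed(data.frame(chrom = ref$id,
                         start = c(pb$src_start, pb$copy_start),
                         end = c(pb$src_end, pb$copy_end),
                         name = rep(c("src", "copy"), each = nrow(pb))),
              paths["blocks"])
  } else file.create(paths["blocks"])
  haps <- unlist(unname(lapply(cohort$donors, function(d)
    stats::setNames(lapply(d$haplotypes, `[[`, "seq"),
                    sprintf("%s_h%d", d$donor_id, 1:2)))))
  write_fasta(haps, paths["haplotypes"])
  snv <- cohort$truth$snv
  if (!is.null(snv)) {
    sites <- unique(snv[, c("site", "pos", "ref", "alt")])
    rec <- data.frame(chrom = ref$id, pos = sites$pos, ref = sites$ref,
                      alt = sites$alt, source = "truth", masked = FALSE,
                      stringsAsFactors = FALSE)
    for (d in names(cohort$donors)) {
      dd <- snv[snv$donor == d, ]
      rec[[paste0("gt.", d)]] <- dosage_to_gt(dd$dosage[match(sites$site, dd$site)])
    }
    write_vcf(rec, paths["vcf"], contigs = stats::setNames(ref$length, ref$id))
  } else write_vcf(data.frame(), paths["vcf"])
  write_tsv(cohort$truth$sv %||%
              data.frame(donor = character(), event = character(), kind = character(),
                         start = integer(), end = integer(), size = integer(),
                         dosage = integer()), paths["sv"])
  write_tsv(cohort$truth$allele %||%
              data.frame(donor = character(), haplotype = integer(),
                         gene = character(), allele = character()), paths["allele"])
  write_tsv(cohort$labels, paths["labels"])
  invisible(paths)
}

#' Reload a truth bundle written by [emit_truth()]
#' @param dir directory containing the bundle.
#' @return list with reference sequence/annotations, haplotypes, snv VCF
#'   data.frame, sv and allele truth tables, population labels.
#' @export
read_truth <- function(dir) {
  list(reference = read_fasta(file.path(dir, "reference.fasta")),
       exons = read_bed(file.path(dir, "exons.bed")),
       haplotypes = read_fasta(file.path(dir, "haplotypes.fasta")),
       snv = read_vcf(file.path(dir, "truth_snv.vcf")),
       sv = if (file.exists(file.path(dir, "truth_sv.tsv")))
         read_tsv(file.path(dir, "truth_sv.tsv")) else NULL,
       allele = if (file.exists(file.path(dir, "truth_allele.tsv")))
         read_tsv(file.path(dir, "truth_allele.tsv")) else NULL,
       labels = read_tsv(file.path(dir, "populations.tsv")))
}
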