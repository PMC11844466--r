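# Allele curation: extraction of spliced constant-gene sequences from
# haplotype contigs, known/novel assignment against an allele database with
# invertible novel-name descriptors, read-support validation, paralog
# consolidation, and functional-residue flagging.

#' Extract a gene's spliced allele sequence from a contig
#'
#' Every exon must lift onto the contig through a single alignment chain
#' (the all-exons-on-one-contig rule); otherwise the result is a no-call.
#' Reverse-oriented contigs yield the same spliced sequence as forward ones.
#'
#' @param contig contig sequence.
#' @param gene gene id (present in `reference$genes`).
#' @param reference a `locus_reference`.
#' @param chains chains of this contig against the reference.
#' @return list: `seq` (spliced sequence or NA for no-call), `exon_intervals`
#'   (contig-frame data.frame qs, qe per exon), `strand`, `no_call_reason`.
#' @export
extract_allele <- function(contig, gene, reference, chains) {
  ex <- gene_exons(reference, gene)
  if (nrow(ex) == 0L) stop("gene model has no exons", call. = FALSE)
  ord <- order(ex$start)
  if (any(ex$start[ord][-1L] <= ex$end[ord][-nrow(ex)]))
    stop("overlapping exon intervals", call. = FALSE)
  no_call <- function(reason)
    list(seq = NA_character_, exon_intervals = NULL, strand = NA_character_,
         no_call_reason = reason)
  for (ch in chains) {
    qiv <- lapply(seq_len(nrow(ex)), function(i)
      liftover(c(ex$start[i], ex$end[i]), ch, "ref2query"))
    if (any(vapply(qiv, is.null, TRUE))) next
    lens_ok <- all(vapply(seq_len(nrow(ex)), function(i)
      (qiv[[i]][2] - qiv[[i]][1]) == (ex$end[i] - ex$start[i]), TRUE))
    if (!lens_ok) next
    segs <- vapply(qiv, function(q) substr(contig, q[1], q[2]), "")
    if (ch$strand == "-") segs <- vapply(segs, revcomp, "")
    spliced <- paste(segs, collapse = "")
    if (ex$strand[1] == "-") spliced <- revcomp(spliced)
    return(list(seq = spliced,
                exon_intervals = data.frame(qs = vapply(qiv, `[`, 0L, 1),
                                            qe = vapply(qiv, `[`, 0L, 2)),
                strand = ch$strand, no_call_reason = NA_character_))
  }
  no_call("exons not liftable through a single contig chain")
}

# ---- novel-name descriptors --------------------------------------------

# descriptors relative to the closest allele, 1-based spliced coordinates:
#   substitutions "<pos><ref>><alt>" (lowercase bases), insertions
#   "<pos>ins<SEQ>" (inserted after <pos>), deletions "<pos>del<n>".
# Applying descriptors to the closest allele regenerates the sequence.
diff_descriptors <- function(closest, observed) {
  if (closest == observed) return(character())
  if (nchar(closest) == nchar(observed)) {
    pos <- mismatch_positions(closest, observed)
    return(sprintf("%d%s>%s", pos,
                   tolower(substring(closest, pos, pos)),
                   tolower(substring(observed, pos, pos))))
  }
  pa <- Biostrings::pairwiseAlignment(observed, closest, type = "global",
                                      substitutionMatrix = nw_submat(),
                                      gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]  # observed
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]  # closest
  out <- character(); cpos <- 0L; i <- 1L; n <- length(p)
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      cpos <- cpos + 1L
      if (s[i] != p[i])
        out <- c(out, sprintf("%d%s>%s", cpos, tolower(s[i]), tolower(p[i])))
      i <- i + 1L
    } else if (s[i] == "-") {
      j <- i
      while (j < n && s[j + 1L] == "-") j <- j + 1L
      out <- c(out, sprintf("%dins%s", cpos, paste(p[i:j], collapse = "")))
      i <- j + 1L
    } else {
      j <- i
      while (j < n && p[j + 1L] == "-") j <- j + 1L
      out <- c(out, sprintf("%ddel%d", cpos + 1L, j - i + 1L))
      cpos <- cpos + (j - i + 1L)
      i <- j + 1L
    }
  }
  out
}

#' Apply novel-name descriptors to a database allele
#'
#' Inverse of the novel naming scheme: regenerates the observed spliced
#' sequence from the closest allele and the descriptor list.
#'
#' @param seq closest-allele spliced sequence.
#' @param descriptors character vector of descriptors (see [match_allele()]).
#' @return character scalar.
#' @export
apply_descriptors <- function(seq, descriptors) {
  if (length(descriptors) == 0L) return(seq)
  pos <- as.integer(sub("^([0-9]+).*$", "\\1", descriptors))
  for (i in order(pos, decreasing = TRUE)) {
    d <- descriptors[i]; p <- pos[i]
    if (grepl("ins", d, fixed = TRUE)) {
      ins <- toupper(sub("^[0-9]+ins", "", d))
      seq <- paste0(substr(seq, 1L, p), ins, substr(seq, p + 1L, nchar(seq)))
    } else if (grepl("del", d, fixed = TRUE)) {
      k <- as.integer(sub("^[0-9]+del", "", d))
      seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + k, nchar(seq)))
    } else {
      alt <- toupper(sub("^.*>", "", d))
      seq <- substitute_bases(seq, p, alt)
    }
  }
  seq
}

#' Assign a spliced sequence to a known or novel allele name
#'
#' Exact sequence matches take the database name. Otherwise the sequence is
#' assigned to the closest allele by Levenshtein distance over the spliced
#' exons (indel-tolerant, since hinge copy variation changes length) and a
#' novel name is built as `<closest>_<descriptor>_<descriptor>...`. Distance
#' ties are broken by lowest allele number; all tied alleles are reported.
#'
#' @param spliced spliced exon sequence.
#' @param db an `allele_database`.
#' @param gene_id gene to match within.
#' @return list: `type` ("exact"/"novel"), `name`, `closest`, `descriptors`,
#'   `distance`, `ties`.
#' @export
match_allele <- function(spliced, db, gene_id) {
  stop_if_not_scalar_seq(spliced, "spliced sequence")
  g <- db[db$gene == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("no database alleles for ", gene_id, call. = FALSE)
  g <- g[order(g$allele), , drop = FALSE]
  hit <- which(g$seq == spliced)
  if (length(hit)) {
    return(list(type = "exact", name = g$name[hit[1]], closest = g$name[hit[1]],
                descriptors = character(), distance = 0L, ties = character()))
  }
  d <- utils::adist(spliced, g$seq)[1, ]
  best <- which(d == min(d))
  closest <- g[best[1], ]
  desc <- diff_descriptors(closest$seq, spliced)
  list(type = "novel",
       name = paste(c(closest$name, desc), collapse = "_"),
       closest = closest$name, descriptors = desc,
       distance = as.integer(min(d)),
       ties = if (length(best) > 1L) g$name[best[-1L]] else character())
}

#' Validate an allele call with HiFi-read support
#'
#' Counts fully spanning reads (alignment covers the first through last
#' exonic base on the contig) with 100% agreement at exonic bases, and
#' computes per-exonic-base depth/agreement from all mapped reads at each
#' position regardless of spanning. Supported iff every exonic position has
#' depth >= `min_depth` and agreement >= `min_fraction` (both inclusive).
#'
#' @param exon_intervals contig-frame exon intervals (from [extract_allele()]).
#' @param contig the contig sequence the reads were aligned to.
#' @param alignments [map_reads()] placements on this contig.
#' @param min_depth minimum reads per exonic position (default 10).
#' @param min_fraction minimum agreeing fraction (default 0.8).
#' @return list: `verdict` ("supported"/"unsupported"), `spanning_reads`,
#'   `min_depth_observed`, `min_agreement_observed`, `per_base`.
#' @export
allele_read_support <- function(exon_intervals, contig, alignments,
                                min_depth = 10L, min_fraction = 0.8) {
  if (is.null(exon_intervals)) stop("no exon intervals (no-call?)", call. = FALSE)
  posv <- unlist(lapply(seq_len(nrow(exon_intervals)), function(i)
    exon_intervals$qs[i]:exon_intervals$qe[i]))
  if (is.null(alignments) || nrow(alignments) == 0L) {
    return(list(verdict = "unsupported", spanning_reads = 0L,
                min_depth_observed = 0L, min_agreement_observed = NA_real_,
                per_base = data.frame(pos = posv, depth = 0L, agreement = NA_real_)))
  }
  pa <- pileup_agreement(alignments, target_seq = contig)
  depth <- pa$depth[posv]
  agree <- ifelse(depth > 0L, pa$match[posv] / depth, NA_real_)
  span_lo <- min(exon_intervals$qs); span_hi <- max(exon_intervals$qe)
  cb <- utf8ToInt(contig)
  spanning <- 0L
  for (i in which(alignments$start <= span_lo & alignments$end >= span_hi)) {
    rb <- utf8ToInt(alignments$seq[i])
    off <- posv - alignments$start[i] + 1L
    if (all(rb[off] == cb[posv])) spanning <- spanning + 1L
  }
  ok <- all(depth >= min_depth) && all(!is.na(agree)) && all(agree >= min_fraction)
  list(verdict = if (ok) "supported" else "unsupported",
       spanning_reads = spanning,
       min_depth_observed = min(depth),
       min_agreement_observed = if (all(is.na(agree))) NA_real_ else min(agree, na.rm = TRUE),
       per_base = data.frame(pos = posv, depth = depth, agreement = agree))
}

#' Curate alleles for all genes of one haplotype contig
#'
#' Convenience wrapper running [extract_allele()] + [match_allele()] over
#' every annotated gene.
#'
#' @param contig contig sequence.
#' @param reference a `locus_reference`.
#' @param db an `allele_database`.
#' @param chains precomputed chains (default: computed here).
#' @param donor_id,haplotype_index bookkeeping labels.
#' @return data.frame: donor, haplotype, gene, called (logical), type, name,
#'   closest, distance, n_descriptors.
#' @export
curate_alleles <- function(contig, reference, db, chains = NULL,
                           donor_id = "donor", haplotype_index = 1L) {
  if (is.null(chains)) chains <- align_contig(contig, reference, query_id = donor_id)
  rows <- list()
  for (g in unique(reference$genes$gene)) {
    exr <- extract_allele(contig, g, reference, chains)
    if (is.na(exr$seq)) {
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor_id, haplotype = haplotype_index, gene = g, called = FALSE,
        type = "no-call", name = NA_character_, closest = NA_character_,
        distance = NA_integer_, n_descriptors = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    m <- match_allele(exr$seq, db, g)
    rows[[length(rows) + 1L]] <- data.frame(
      donor = donor_id, haplotype = haplotype_index, gene = g, called = TRUE,
      type = m$type, name = m$name, closest = m$closest, distance = m$distance,
      n_descriptors = length(m$descriptors), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarize allele genotypes, heterozygosity and novel-allele counts
#'
#' Paralog-group genes are consolidated into one non-redundant allele set
#' (name multiplicity collapses; distinct sequences/names are preserved).
#'
#' @param calls data.frame from [curate_alleles()] rows (donor, haplotype,
#'   gene, type, name; no-calls ignored).
#' @param labels data.frame(donor, population).
#' @param paralog_groups named list of gene-id vectors to consolidate
#'   (e.g. `list(IGHG4 = c("IGHG4", "IGHG4B"))`).
#' @return list: `diplotypes` (donor x gene allele pairs + het flag),
#'   `heterozygosity` (gene x population), `novel_counts` (per donor),
#'   `allele_sets` (per consolidated gene, unique allele names).
#' @export
summarize_allele_genotypes <- function(calls, labels, paralog_groups = list()) {
  calls <- calls[calls$called %||% TRUE & !is.na(calls$name), , drop = FALSE]
  group_of <- stats::setNames(calls$gene, calls$gene)
  for (gn in names(paralog_groups))
    group_of[calls$gene %in% paralog_groups[[gn]]] <- gn
  calls$group <- unname(group_of[calls$gene])
  dips <- list()
  for (key in unique(paste(calls$donor, calls$gene))) {
    sel <- calls[paste(calls$donor, calls$gene) == key, , drop = FALSE]
    if (nrow(sel) > 2L) {
      warning("conflicting duplicate calls for ", key, " (kept, flagged)")
    }
    nm <- sort(sel$name)
    dips[[length(dips) + 1L]] <- data.frame(
      donor = sel$donor[1], gene = sel$gene[1],
      a1 = nm[1], a2 = if (length(nm) > 1L) nm[2] else NA_character_,
      het = length(unique(nm)) > 1L, stringsAsFactors = FALSE)
  }
  dips <- do.call(rbind, dips)
  dips$population <- labels$population[match(dips$donor, labels$donor)]
  het <- tapply(dips$het, list(dips$gene, dips$population), mean)
  novel <- calls[calls$type == "novel", , drop = FALSE]
  novel_counts <- if (nrow(novel))
    stats::aggregate(list(n_novel = novel$name), by = list(donor = novel$donor),
                     FUN = function(x) length(unique(x)))
  else data.frame(donor = character(), n_novel = integer())
  all_donors <- unique(calls$donor)
  missing <- setdiff(all_donors, novel_counts$donor)
  if (length(missing))
    novel_counts <- rbind(novel_counts, data.frame(donor = missing, n_novel = 0L))
  sets <- lapply(split(calls$name, calls$group), function(x) sort(unique(x)))
  list(diplotypes = dips, heterozygosity = het,
       novel_counts = novel_counts[order(novel_counts$donor), ],
       allele_sets = sets)
}

# ---- functional residues ------------------------------------------------

translate_dna <- function(seq) {
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Flag amino-acid substitutions at annotated functional residues
#'
#' Translates the observed allele and the gene's reference allele (*01),
#' reports every amino-acid difference, and marks differences falling on
#' annotated functional residues with their annotation tag. Synonymous
#' nucleotide changes yield no residue entry. A variant-introduced internal
#' stop codon (absent from the reference allele at that codon) flags
#' the allele but substitutions are still reported.
#'
#' @param spliced observed spliced sequence.
#' @param db an `allele_database`.
#' @param gene_id gene id.
#' @param residue_list data.frame(gene, residue, tag) of functional residues
#'   in translated (domain) coordinates.
#' @return list: `substitutions` data.frame(residue, ref_aa, alt_aa, tag),
#'   `internal_stop`, `n_nt_diffs`.
#' @export
flag_functional_substitutions <- function(spliced, db, gene_id, residue_list) {
  g <- db[db$gene == gene_id & db$allele == "*01", , drop = FALSE]
  if (nrow(g) == 0L) stop("no reference allele for ", gene_id, call. = FALSE)
  ref_nt <- g$seq[1]
  aa_ref <- translate_dna(ref_nt)
  aa_obs <- translate_dna(spliced)
  L <- min(nchar(aa_ref), nchar(aa_obs))
  ra <- strsplit(substr(aa_ref, 1L, L), "")[[1]]
  oa <- strsplit(substr(aa_obs, 1L, L), "")[[1]]
  dif <- which(ra != oa)
  rl <- residue_list[residue_list$gene == gene_id, , drop = FALSE]
  subs <- data.frame(residue = dif, ref_aa = ra[dif], alt_aa = oa[dif],
                     tag = rl$tag[match(dif, rl$residue)], stringsAsFactors = FALSE)
  # a stop is "internal" when the variant introduces it at a codon where the
  # reference allele has none (synthetic references are not open reading
  # frames, so absolute stop positions are uninformative)
  new_stop <- any(oa[dif] == "*" & ra[dif] != "*" & dif < nchar(aa_obs))
  nt_diffs <- if (nchar(spliced) == nchar(ref_nt))
    mismatch_count(spliced, ref_nt) else utils::adist(spliced, ref_nt)[1, 1]
  list(substitutions = subs, internal_stop = new_stop,
       n_nt_diffs = as.integer(nt_diffs))
}
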