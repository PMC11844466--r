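# Standard-format I/O. FASTA/FASTQ go through Biostrings; BED, PAF (with
# cg:Z CIGAR tags) and a minimal VCF v4.2 dialect (CHROM POS ID REF ALT QUAL
# FILTER INFO FORMAT + per-donor GT, INFO flags SOURCE=/MASKED) are written
# by hand so the package controls its custom tags exactly.

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return named character vector of sequences (qualities discarded).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with uniform Q30 qualities
#' @param seqs named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("?", n), "")  # Q30 = '?' (Phred+33)
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read a BED file (0-based half-open on disk, 1-based closed in memory)
#' @param path file path.
#' @return data.frame with chrom, start, end (1-based closed), name, score, strand
#'   (columns present only if in the file).
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  names(x) <- cols[seq_len(ncol(x))]
  x$start <- x$start + 1L  # to 1-based closed
  x
}

#' Write a BED file (converts 1-based closed intervals to BED dialect)
#' @param df data.frame with chrom, start, end and optionally name, score, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- df
  out$start <- out$start - 1L
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(out))
  utils::write.table(out[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- PAF ----------------------------------------------------------------

chain_to_cigar <- function(chain) {
  # CIGAR in query order over the chain span: M blocks, I (query gap), D (target gap)
  b <- chain$blocks
  n <- nrow(b)
  ops <- character()
  for (i in seq_len(n)) {
    if (i > 1L) {
      dq <- b$qs[i] - b$qe[i - 1L] - 1L
      prev_t <- if (chain$strand == "+") b$te[i - 1L] else b$ts[i - 1L]
      dt <- if (chain$strand == "+") b$ts[i] - b$te[i - 1L] - 1L
            else b$ts[i - 1L] - b$te[i] - 1L
      if (dq > 0L) ops <- c(ops, paste0(dq, "I"))
      if (dt > 0L) ops <- c(ops, paste0(dt, "D"))
    }
    ops <- c(ops, paste0(b$qe[i] - b$qs[i] + 1L, "M"))
  }
  paste(ops, collapse = "")
}

#' Write alignment chains as PAF records with cg:Z CIGAR tags
#' @param chains list of alignment chains (see [align_contig()]).
#' @param path output path.
#' @param query_lengths named integer vector of query lengths.
#' @param target_lengths named integer vector of target lengths.
#' @return `path`, invisibly.
#' @export
write_paf <- function(chains, path, query_lengths, target_lengths) {
  lines <- vapply(chains, function(ch) {
    b <- ch$blocks
    alen <- sum(b$qe - b$qs + 1L)
    nm <- sum(b$nmis)
    paste(ch$query_id, query_lengths[[ch$query_id]],
          min(b$qs) - 1L, max(b$qe),           # PAF query coords 0-based half-open
          ch$strand,
          ch$target_id, target_lengths[[ch$target_id]],
          min(b$ts) - 1L, max(b$te),
          alen - nm, alen, 60L,
          paste0("cg:Z:", chain_to_cigar(ch)),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read PAF records (with cg:Z tags) back into alignment chains
#'
#' External alignments (e.g. minimap2 with --cs/-c) expressed as PAF with
#' cg:Z CIGARs are converted to the same chain structure produced by
#' [align_contig()], so they are interchangeable downstream.
#'
#' @param path PAF file path.
#' @return list of alignment chains.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", f, value = TRUE)[1])
    strand <- f[5]
    qs <- as.integer(f[3]) + 1L; ts <- as.integer(f[8]) + 1L
    te_all <- as.integer(f[9])
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
    blocks <- list(); q <- qs
    t <- if (strand == "+") ts else te_all
    for (i in seq_along(ops)) {
      L <- lens[i]
      if (ops[i] == "M") {
        if (strand == "+") {
          blocks[[length(blocks) + 1L]] <- c(q, q + L - 1L, t, t + L - 1L)
          t <- t + L
        } else {
          blocks[[length(blocks) + 1L]] <- c(q, q + L - 1L, t - L + 1L, t)
          t <- t - L
        }
        q <- q + L
      } else if (ops[i] == "I") q <- q + L
      else t <- if (strand == "+") t + L else t - L
    }
    b <- as.data.frame(do.call(rbind, blocks))
    names(b) <- c("qs", "qe", "ts", "te")
    b$nmis <- 0L
    new_chain(query_id = f[1], target_id = f[6], strand = strand, blocks = b,
              mismatches = empty_mismatches())
  })
}

# ---- VCF ----------------------------------------------------------------

#' Write a minimal VCF v4.2 file
#'
#' Records carry CHROM/POS/REF/ALT, per-sample GT, and INFO flags
#' `SOURCE=` (assembly/read/combined) and `MASKED` for records inside
#' structural-variant masks.
#'
#' @param records data.frame with columns chrom, pos, ref, alt (comma-joined
#'   for multi-allelic), and one `gt.<sample>` column per sample (strings like
#'   "0/1"); optional columns source, masked.
#' @param path output path.
#' @param contigs named integer vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, contigs = NULL) {
  gt_cols <- grep("^gt\\.", names(records), value = TRUE)
  samples <- sub("^gt\\.", "", gt_cols)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplokit",
           if (!is.null(contigs))
             paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
           "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Call provenance\">",
           "##INFO=<ID=MASKED,Number=0,Type=Flag,Description=\"Inside SV mask\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", samples), collapse = "\t"))
  if (nrow(records) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  info <- rep(".", nrow(records))
  if (!is.null(records$source)) info <- paste0("SOURCE=", records$source)
  if (!is.null(records$masked)) {
    info <- ifelse(records$masked,
                   ifelse(info == ".", "MASKED", paste0(info, ";MASKED")), info)
  }
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", info, "GT", sep = "\t")
  for (g in gt_cols) body <- paste(body, records[[g]], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file written by [write_vcf()] (or any minimal GT-only VCF)
#' @param path file path.
#' @return data.frame with chrom, pos, ref, alt, source, masked and `gt.<sample>` columns.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines, value = TRUE)
  samples <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), source = character(), masked = logical(),
                      stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("gt.", s)]] <- character()
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 4],
                    alt = m[, 5], stringsAsFactors = FALSE)
  out$source <- ifelse(grepl("SOURCE=", m[, 8]),
                       sub(".*SOURCE=([^;]+).*", "\\1", m[, 8]), NA_character_)
  out$masked <- grepl("(^|;)MASKED($|;)", m[, 8])
  if (length(samples)) {
    gt_idx <- which(strsplit(m[1, 9], ":")[[1]] == "GT")
    for (j in seq_along(samples)) {
      vals <- vapply(f, function(r) strsplit(r[9L + j], ":", fixed = TRUE)[[1]][gt_idx], "")
      out[[paste0("gt.", samples[j])]] <- vals
    }
  }
  out
}

#' Read/write TSV tables (thin wrappers with fixed conventions)
#' @param df data.frame to write.
#' @param path file path.
#' @return `path` (write) or data.frame (read).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
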