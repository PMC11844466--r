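test_that("contig alignment: identity, inversion signal, and no-anchor input", {
  ref <- tiny_ref()
  idx <- tiny_idx()
  # exact reference substring -> one clean '+' chain
  sub <- substr(ref$seq, 10001L, 25000L)
  ch <- align_contig(sub, idx)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$strand, "+")
  expect_equal(sum(ch[[1]]$blocks$nmis), 0L)
  expect_equal(c(ch[[1]]$tstart, ch[[1]]$tend), c(10001L, 25000L))
  expect_equal(c(ch[[1]]$qstart, ch[[1]]$qend), c(1L, 15000L))
  # internal reverse-complemented segment -> middle sub-chain on '-'
  contig <- paste0(substr(ref$seq, 1L, 29999L),
                   revcomp(substr(ref$seq, 30000L, 34499L)),
                   substr(ref$seq, 34500L, 60000L))
  ch2 <- align_contig(contig, idx)
  strands <- vapply(ch2, `[[`, "", "strand")
  expect_equal(sum(strands == "-"), 1L)
  minus <- ch2[[which(strands == "-")]]
  expect_equal(c(minus$tstart, minus$tend), c(30000L, 34499L))
  # sequence absent from the reference -> empty result, not an error
  expect_length(align_contig(random_seq(5000L, seed = 123L), idx), 0L)
})

test_that("aligning a haplotype to itself yields one full-length edit-free chain", {
  ref <- tiny_ref()
  h <- simulate_haplotype(ref, tiny_db(), snv_rate = 1e-4,
                          alleles = c(IGHM = "*02"), seed = 8L)
  ch <- align_contig(h$seq, kmer_index(h$seq, id = "self"))
  expect_length(ch, 1L)
  expect_equal(nrow(ch[[1]]$blocks), 1L)
  expect_equal(sum(ch[[1]]$blocks$nmis), 0L)
  expect_equal(c(ch[[1]]$qstart, ch[[1]]$qend), c(1L, nchar(h$seq)))
  expect_equal(c(ch[[1]]$tstart, ch[[1]]$tend), c(1L, nchar(h$seq)))
})

test_that("chain edit counts agree with a brute-force DP aligner", {
  withr::with_seed(31L, {
    base <- random_seq(5000L, seed = 311L)
    for (nmut in c(0L, 3L, 12L)) {
      pos <- sample(4900L, nmut) + 50L
      mut <- base
      for (p in pos) {
        old <- substr(mut, p, p)
        mut <- substitute_bases(mut, p, sample(setdiff(c("A", "C", "G", "T"), old), 1L))
      }
      ch <- align_contig(mut, kmer_index(base, id = "b"), stride = 4L)
      expect_length(ch, 1L)
      expect_equal(sum(ch[[1]]$blocks$nmis), edit_distance_oracle(mut, base))
    }
    # a clean 40 bp deletion: edit distance = 40, chain gap matches
    del <- paste0(substr(base, 1, 2000), substr(base, 2041, 5000))
    chd <- align_contig(del, kmer_index(base, id = "b"), stride = 4L)
    gaps <- sum(chd[[1]]$blocks$ts[-1] - chd[[1]]$blocks$te[-nrow(chd[[1]]$blocks)] - 1L)
    expect_equal(gaps + sum(chd[[1]]$blocks$nmis), edit_distance_oracle(del, base))
  })
})

test_that("liftover maps through blocks, shifts across indels, and refuses gaps", {
  ref <- tiny_ref()
  idx <- tiny_idx()
  ch <- align_contig(ref$seq, idx)[[1]]
  expect_equal(as.integer(liftover(c(5000L, 6000L), ch, "ref2query")), c(5000L, 6000L))
  # query with a 1000 bp deletion upstream: downstream intervals shift by -1000
  del <- paste0(substr(ref$seq, 1L, 9999L), substr(ref$seq, 11000L, 60000L))
  chd <- align_contig(del, idx)[[1]]
  lv <- liftover(c(20000L, 21000L), chd, "ref2query")
  expect_equal(as.integer(lv), c(19000L, 20000L))
  # an endpoint inside the deleted (unaligned) reference span -> none
  expect_null(liftover(c(10050L, 20000L), chd, "ref2query"))
  # round trip wherever both directions are defined
  for (iv in list(c(2000L, 2500L), c(30000L, 31000L), c(55000L, 59000L))) {
    q <- liftover(iv, chd, "ref2query")
    if (!is.null(q)) expect_equal(as.integer(liftover(as.integer(q), chd, "query2ref")), iv)
  }
})

test_that("liftover is strand-aware on reverse-oriented contigs", {
  ref <- tiny_ref()
  rc_contig <- revcomp(substr(ref$seq, 10001L, 20000L))
  ch <- align_contig(rc_contig, tiny_idx())[[1]]
  expect_equal(ch$strand, "-")
  q <- liftover(c(10001L, 10100L), ch, "ref2query")
  expect_equal(as.integer(q), c(9901L, 10000L))  # flipped to the contig's far end
  expect_identical(revcomp(substr(rc_contig, q[1], q[2])),
                   substr(ref$seq, 10001L, 10100L))
})

test_that("contig merging enforces the 2 kb / 5 mismatch rule exactly", {
  a <- random_seq(10000L, seed = 51L)
  b_tail <- random_seq(8000L, seed = 52L)
  b <- paste0(substr(a, 8001L, 10000L), b_tail)  # exact 2000 bp junction
  m <- merge_contigs(c(x = a, y = b))
  expect_length(m, 1L)
  expect_equal(nchar(m[[1]]), 18000L)
  expect_identical(unname(m[[1]]), paste0(a, b_tail))
  # exactly 5 mismatches in the overlap: still merges
  b5 <- b
  for (p in c(100L, 500L, 900L, 1300L, 1700L))
    b5 <- substitute_bases(b5, p, if (substr(b5, p, p) == "A") "C" else "A")
  expect_length(merge_contigs(c(x = a, y = b5)), 1L)
  # 6 mismatches: not merged
  b6 <- substitute_bases(b5, 1900L, if (substr(b5, 1900L, 1900L) == "A") "C" else "A")
  expect_length(merge_contigs(c(x = a, y = b6)), 2L)
  # 1999 bp overlap with 0 mismatches: not merged
  b_short <- paste0(substr(a, 8002L, 10000L), b_tail)
  expect_length(merge_contigs(c(x = a, y = b_short)), 2L)
})

test_that("contig merging is invariant to input permutation", {
  base <- random_seq(30000L, seed = 61L)
  pieces <- c(p1 = substr(base, 1L, 12000L),
              p2 = substr(base, 9001L, 22000L),
              p3 = substr(base, 19001L, 30000L))
  m1 <- merge_contigs(pieces)
  m2 <- merge_contigs(pieces[c(3, 1, 2)])
  m3 <- merge_contigs(pieces[c(2, 3, 1)])
  expect_identical(sort(unname(m1)), sort(unname(m2)))
  expect_identical(sort(unname(m1)), sort(unname(m3)))
  expect_identical(unname(m1[[1]]), base)
})

test_that("pileup depth tracks and summaries behave", {
  aln0 <- data.frame(target = character(), start = integer(), end = integer())
  t0 <- pileup_depth(aln0, 100L)
  expect_true(all(t0$depth == 0L))
  expect_equal(depth_fraction(t0, 1L), 0)
  t1 <- pileup_depth(data.frame(target = "t", start = 1L, end = 100L), 100L)
  expect_true(all(t1$depth == 1L))
  expect_error(pileup_depth(data.frame(target = "t", start = 90L, end = 101L), 100L),
               "beyond")
  # simulated 15x tiling: mean depth within 10% of 15
  hap <- random_seq(40000L, seed = 71L)
  rd <- simulate_reads(hap, read_sim_spec(read_lengths = 3000L,
                                          coverage_per_haplotype = 15, seed = 72L))
  tr <- pileup_depth(data.frame(target = "h", start = rd$start, end = rd$end), 40000L)
  expect_lt(abs(mean(tr$depth) - 15) / 15, 0.1)
})

test_that("read mapping recovers true placements on a diploid target", {
  ref <- tiny_ref()
  h1 <- simulate_haplotype(ref, tiny_db(), snv_rate = 2e-4, seed = 81L)
  rd <- simulate_reads(h1$seq, read_sim_spec(read_lengths = 3000L,
                                             coverage_per_haplotype = 4,
                                             substitution_error_rate = 0.001,
                                             seed = 82L), label = "h1")
  aln <- map_reads(stats::setNames(rd$seq, rd$read_id), c(h1 = h1$seq))
  expect_equal(nrow(aln), nrow(rd))
  m <- match(aln$read_id, rd$read_id)
  expect_true(all(aln$start == rd$start[m]))
  # reverse-complemented reads map on '-' with the same placement
  flip <- seq(1L, nrow(rd), by = 7L)
  seqs <- rd$seq
  seqs[flip] <- vapply(seqs[flip], revcomp, "")
  aln2 <- map_reads(stats::setNames(seqs, rd$read_id), c(h1 = h1$seq))
  m2 <- match(rd$read_id[flip], aln2$read_id)
  expect_true(all(aln2$strand[m2] == "-"))
  expect_true(all(aln2$start[m2] == rd$start[flip]))
})

test_that("PAF round trip preserves chain block structure", {
  ref <- tiny_ref()
  idx <- tiny_idx()
  del <- paste0(substr(ref$seq, 1L, 19999L), substr(ref$seq, 21000L, 60000L))
  chains <- align_contig(del, idx, query_id = "q1")
  tmp <- tempfile(fileext = ".paf")
  write_paf(chains, tmp, query_lengths = c(q1 = nchar(del)),
            target_lengths = stats::setNames(ref$length, ref$id))
  back <- read_paf(tmp)
  expect_length(back, length(chains))
  for (i in seq_along(chains)) {
    expect_equal(back[[i]]$blocks[, c("qs", "qe", "ts", "te")],
                 chains[[i]]$blocks[, c("qs", "qe", "ts", "te")])
    expect_equal(back[[i]]$strand, chains[[i]]$strand)
  }
  # lifted coordinates agree between internal and PAF-loaded chains
  lv1 <- liftover(c(30000L, 30500L), chains[[1]], "ref2query")
  lv2 <- liftover(c(30000L, 30500L), back[[1]], "ref2query")
  expect_equal(as.integer(lv1), as.integer(lv2))
})

test_that("FASTA/FASTQ/BED/VCF round trips, with an independent VCF reader", {
  seqs <- c(s1 = random_seq(500L, seed = 91L), s2 = random_seq(300L, seed = 92L))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, fq)
  expect_identical(read_fastq(fq), seqs)
  bed <- data.frame(chrom = "c", start = c(100L, 300L), end = c(200L, 400L),
                    name = c("a", "b"), score = 0L, strand = "+")
  bf <- tempfile(fileext = ".bed")
  write_bed(bed, bf)
  expect_equal(read_bed(bf), bed)
  raw <- utils::read.table(bf, sep = "\t")
  expect_equal(raw$V2, c(99L, 299L))  # BED is 0-based on disk
  rec <- data.frame(chrom = "c", pos = c(10L, 20L), ref = c("A", "G"),
                    alt = c("T", "C,A"), source = "assembly",
                    masked = c(FALSE, TRUE),
                    gt.d1 = c("0/1", "1/2"), gt.d2 = c("0/0", "0/1"),
                    stringsAsFactors = FALSE)
  vf <- tempfile(fileext = ".vcf")
  write_vcf(rec, vf, contigs = c(c = 1000L))
  back <- read_vcf(vf)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$masked, rec$masked)
  expect_equal(back$gt.d1, rec$gt.d1)
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(vf, verbose = FALSE))
  expect_equal(as.integer(v@fix[, "POS"]), rec$pos)
  expect_equal(unname(v@gt[, "d1"]), rec$gt.d1)
})
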