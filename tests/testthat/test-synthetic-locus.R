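test_that("locus construction is seed-deterministic and annotation-valid", {
  r1 <- build_locus(tiny_spec())
  r2 <- build_locus(tiny_spec())
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$genes, r2$genes)
  expect_equal(nchar(r1$seq), 60000L)
  g <- r1$genes[order(r1$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))     # exons non-overlapping
  expect_true(all(g$end <= 60000L) && all(g$start >= 1L))
  # the duplicated block carries a second annotated IGHG4-like gene
  expect_true("IGHG4B" %in% g$gene)
})

test_that("every 1 kb window of a paralog copy differs from its source", {
  ref <- tiny_ref()
  pb <- ref$paralog_blocks
  src <- strsplit(substr(ref$seq, pb$src_start, pb$src_end), "")[[1]]
  cp <- strsplit(substr(ref$seq, pb$copy_start, pb$copy_end), "")[[1]]
  for (ws in seq(1L, length(src), by = 1000L)) {
    we <- min(ws + 999L, length(src))
    expect_gte(sum(src[ws:we] != cp[ws:we]), 1L)
  }
  expect_true(all(check_paralog_divergence(ref)$min_diffs >= 1L))
})

test_that("spec validation rejects malformed gene models", {
  gm <- default_gene_models(60000L)
  gm$end[2] <- gm$start[3] + 5L   # overlap
  expect_error(locus_spec(60000L, gene_models = gm,
                          paralog_blocks = default_paralog_blocks(60000L)),
               "overlapping")
  gm2 <- default_gene_models(60000L)
  gm2$end[nrow(gm2)] <- 60001L
  expect_error(locus_spec(60000L, gene_models = gm2,
                          paralog_blocks = default_paralog_blocks(60000L)),
               "outside")
})

test_that("allele database: *01 equals reference splice, alleles distinct", {
  ref <- tiny_ref()
  db1 <- spawn_allele_database(ref, 1L, seed = 5L)
  expect_true(all(db1$allele == "*01"))
  for (g in unique(ref$genes$gene))
    expect_identical(db1$seq[db1$gene == g], splice_gene(ref, g))
  db3a <- spawn_allele_database(ref, 3L, seed = 6L)
  db3b <- spawn_allele_database(ref, 3L, seed = 6L)
  expect_identical(db3a, db3b)
  for (g in unique(db3a$gene)) {
    seqs <- db3a$seq[db3a$gene == g]
    d <- utils::adist(seqs)
    expect_true(all(d[upper.tri(d)] >= 1L))
  }
  expect_error(spawn_allele_database(ref, 0L), ">= 1")
})

test_that("haplotype simulation: identity, inversion, hinge deletion", {
  ref <- tiny_ref()
  h0 <- simulate_haplotype(ref, seed = 1L)
  expect_identical(h0$seq, ref$seq)
  inv <- sv_event("inversion", 30001L, 34500L)
  hi <- simulate_haplotype(ref, events = list(inv), seed = 1L)
  expect_equal(nchar(hi$seq), ref$length)
  expect_identical(substr(hi$seq, 30001L, 34500L),
                   revcomp(substr(ref$seq, 30001L, 34500L)))
  expect_identical(substr(hi$seq, 1L, 30000L), substr(ref$seq, 1L, 30000L))
  hd <- sv_event("hinge_exon_indel", 20000L)
  expect_equal(hd$size, 188L)
  hh <- simulate_haplotype(ref, events = list(hd), seed = 1L)
  expect_equal(nchar(hh$seq), ref$length - 188L)
})

test_that("haplotype simulation rejects invalid events and exonic SNVs", {
  ref <- tiny_ref()
  e1 <- sv_event("deletion", 1000L, 3000L)
  e2 <- sv_event("deletion", 2500L, 4000L)
  expect_error(simulate_haplotype(ref, events = list(e1, e2)), "overlap")
  expect_error(simulate_haplotype(ref, events = list(sv_event("deletion", 59990L, 60010L))),
               "outside")
  exon1 <- ref$genes$start[1]
  expect_error(simulate_haplotype(ref, snvs = data.frame(pos = exon1, alt = "A")),
               "exon")
  expect_silent(simulate_haplotype(ref, snvs = data.frame(pos = exon1, alt = "A"),
                                   allow_exonic_snvs = TRUE, seed = 1L))
})

test_that("event-log replay reconstructs every haplotype byte-for-byte", {
  ref <- mid_ref()
  db <- mid_db()
  evs <- default_sv_events(ref)
  for (s in 1:4) {
    pick <- withr::with_seed(100L + s,
                             evs[sample(c(TRUE, FALSE), length(evs), TRUE)])
    # greedy drop of overlapping picks
    pick <- tryCatch({ validate_events(unname(pick), ref$length); pick },
                     error = function(e) pick["inversion"])
    h <- simulate_haplotype(ref, db, events = unname(pick), snv_rate = 1e-4,
                            alleles = c(IGHM = "*02", IGHE = "*03"), seed = s)
    expect_identical(replay_haplotype(ref, h$event_log), h$seq)
  }
})

test_that("cohort draws respect degenerate and fixed frequencies", {
  ref <- tiny_ref()
  db <- tiny_db()
  sites <- pick_sites(ref, 3L)
  # degenerate: one population, frequency 0 everywhere -> identical haplotypes
  ps0 <- population_spec("P1", 3L, sites, matrix(0, 3, 1))
  co0 <- simulate_cohort(ref, db, ps0, seed = 3L)
  seqs <- unlist(lapply(co0$donors, function(d) lapply(d$haplotypes, `[[`, "seq")))
  expect_equal(length(unique(seqs)), 1L)
  # forced fixation: ALT fixed in A, REF elsewhere, realized counts exact
  psf <- population_spec(c("A", "B"), 4L, sites,
                         matrix(0.5, 3, 2),
                         fixed_sites = data.frame(site = 2L, population = "A"))
  cof <- simulate_cohort(ref, db, psf, seed = 4L)
  tr <- cof$truth$snv
  site2 <- tr[tr$site == 2L, ]
  pops <- cof$labels$population[match(site2$donor, cof$labels$donor)]
  expect_true(all(site2$dosage[pops == "A"] == 2L))
  expect_true(all(site2$dosage[pops == "B"] == 0L))
})

test_that("realized cohort frequencies fall within binomial 99% bounds", {
  ref <- tiny_ref()
  db <- tiny_db()
  n_sites <- 10L
  sites <- pick_sites(ref, n_sites)
  freq <- matrix(c(rep(0.8, n_sites), rep(0.2, n_sites)), ncol = 2)
  ps <- population_spec(c("P1", "P2"), 50L, sites, freq)
  co <- simulate_cohort(ref, db, ps, seed = 9L)
  tr <- co$truth$snv
  tr$pop <- co$labels$population[match(tr$donor, co$labels$donor)]
  for (p in c("P1", "P2")) {
    target <- if (p == "P1") 0.8 else 0.2
    for (s in seq_len(n_sites)) {
      x <- tr$dosage[tr$pop == p & tr$site == s]
      n_chrom <- 2L * length(x)
      ci <- stats::qbinom(c(0.005, 0.995), n_chrom, target) / n_chrom
      f <- sum(x) / n_chrom
      expect_gte(f, ci[1]); expect_lte(f, ci[2])
    }
  }
})

test_that("read simulation hits coverage, tiles exactly, and is deterministic", {
  hap <- random_seq(50000L, seed = 42L)
  spec <- read_sim_spec(read_lengths = c(3000L), coverage_per_haplotype = 15,
                        seed = 77L)
  rd <- simulate_reads(hap, spec, label = "t")
  total <- sum(rd$end - rd$start + 1L)
  expect_lt(abs(total - 15 * 50000) / (15 * 50000), 0.05)
  expect_equal(nrow(rd), length(unique(rd$read_id)))
  # error rate 0: every read substring-matches its recorded source interval
  expect_identical(rd$seq, substring(hap, rd$start, rd$end))
  rd2 <- simulate_reads(hap, spec, label = "t")
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(stats::setNames(rd$seq, rd$read_id), f1)
  write_fastq(stats::setNames(rd2$seq, rd2$read_id), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads(substr(hap, 1, 1000), read_sim_spec(read_lengths = 3000L)),
               "smaller")
})

test_that("expected read count matches coverage arithmetic", {
  hap <- random_seq(100000L, seed = 43L)
  rd <- simulate_reads(hap, read_sim_spec(read_lengths = 6000L,
                                          coverage_per_haplotype = 15, seed = 1L))
  expected <- 100000 * 15 / 6000
  expect_lt(abs(nrow(rd) - expected) / expected, 0.06)
  err <- simulate_reads(hap, read_sim_spec(read_lengths = 6000L,
                                           coverage_per_haplotype = 5,
                                           substitution_error_rate = 0.01, seed = 2L))
  mm <- sum(mapply(function(s, a, b) sum(utf8ToInt(s) != utf8ToInt(substr(hap, a, b))),
                   err$seq, err$start, err$end))
  rate <- mm / sum(err$end - err$start + 1L)
  expect_gt(rate, 0.008); expect_lt(rate, 0.012)
})

test_that("truth bundle round-trips and replays to the haplotypes", {
  ref <- tiny_ref()
  db <- tiny_db()
  sites <- pick_sites(ref, 3L)
  ps <- population_spec(c("A", "B"), 2L, sites, matrix(c(1, 0, 0.5, 0.5, 0, 1), 3, 2,
                                                       byrow = TRUE))
  co <- simulate_cohort(ref, db, ps, seed = 5L)
  out <- tempfile("truth_")
  paths <- emit_truth(co, out)
  expect_true(all(file.exists(paths)))
  back <- read_truth(out)
  expect_identical(back$reference[[ref$id]], ref$seq)
  expect_identical(unname(back$haplotypes[["A_01_h1"]]),
                   co$donors[["A_01"]]$haplotypes[[1]]$seq)
  # VCF round trip reproduces the dosage table
  vr <- back$snv
  for (d in names(co$donors)) {
    tr <- co$truth$snv[co$truth$snv$donor == d, ]
    gt <- vr[[paste0("gt.", d)]][match(tr$pos, vr$pos)]
    expect_identical(gt, c("0/0", "0/1", "1/1")[tr$dosage + 1L])
  }
  # applying the recorded events to the reference reconstructs each haplotype
  for (d in co$donors) for (h in d$haplotypes)
    expect_identical(replay_haplotype(ref, h$event_log), h$seq)
  # a donor with no variants is all hom-ref in the truth VCF
  ps0 <- population_spec("Z", 1L, sites, matrix(0, 3, 1))
  co0 <- simulate_cohort(ref, db, ps0, seed = 6L)
  out0 <- tempfile("truth0_")
  emit_truth(co0, out0)
  v0 <- read_vcf(file.path(out0, "truth_snv.vcf"))
  expect_true(all(v0$gt.Z_01 == "0/0"))
})
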