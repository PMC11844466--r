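# Shared fixtures, built once per test run and cached. Most tests use a
# 60 kb locus (same architecture as the full-size default, scaled down).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_spec <- function(len = 60000L, seed = 7L) {
  locus_spec(locus_length = len, gene_models = default_gene_models(len),
             paralog_blocks = default_paralog_blocks(len), seed = seed)
}

tiny_ref <- function() fixture("tiny_ref", function() build_locus(tiny_spec()))

tiny_db <- function() fixture("tiny_db", function()
  spawn_allele_database(tiny_ref(), n_alleles_per_gene = 3L, seed = 2L))

tiny_idx <- function() fixture("tiny_idx", function() kmer_index(tiny_ref()))

# mid-size reference (120 kb) for SV-event tests needing the default events
mid_ref <- function() fixture("mid_ref", function()
  build_locus(tiny_spec(len = 120000L, seed = 11L)))

mid_db <- function() fixture("mid_db", function()
  spawn_allele_database(mid_ref(), n_alleles_per_gene = 3L, seed = 12L))

mid_idx <- function() fixture("mid_idx", function() kmer_index(mid_ref()))

# n non-exonic sites, evenly spread over the locus, with a fixed alt base
pick_sites <- function(ref, n, avoid = NULL) {
  ex <- ref$genes
  bad <- logical(ref$length)
  for (i in seq_len(nrow(ex))) bad[ex$start[i]:ex$end[i]] <- TRUE
  if (!is.null(avoid))
    for (i in seq_len(nrow(avoid))) bad[avoid$start[i]:avoid$end[i]] <- TRUE
  elig <- which(!bad)
  pos <- elig[as.integer(round(seq(1L, length(elig), length.out = n + 2L)))][2:(n + 1L)]
  pos <- sort(unique(pos))
  data.frame(pos = pos,
             alt = ifelse(substring(ref$seq, pos, pos) == "A", "C", "A"))
}

random_seq <- function(n, seed = 1L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}
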