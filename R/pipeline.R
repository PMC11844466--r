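# End-to-end orchestration: simulate (or load) a cohort, align haplotype
# assemblies to the reference, call and genotype SNVs/SVs, cluster the CNV
# region, curate alleles, compute population statistics, and write a report
# bundle with a checksummed manifest.

#' Pipeline configuration with the study's default thresholds
#'
#' All numeric defaults are the workflow's published operating points: contig
#' merging at 2 kb overlap / 5 mismatches, read support at 10 reads / 80%
#' agreement over >9x positions, genotype concordance at 4 reads, read
#' candidate rescue at minrel 0.05, CNV clustering with 5 kb flanks at
#' cutoff 0.1, 10 kb error windows, MAF filter 5%, read lengths
#' 350/3000/6000/10000 at 15x per haplotype.
#'
#' @param out_dir output directory.
#' @param seed master seed for all stages.
#' @param locus a [locus_spec()] (used when simulating).
#' @param populations,donors_per_population,n_snv_sites cohort design.
#' @param n_alleles_per_gene allele database size per gene.
#' @param simulate_svs include the default SV classes in the cohort.
#' @param read_lengths,coverage,error_rate read simulation settings.
#' @param merge_min_overlap,merge_max_mismatch contig merge rule.
#' @param support_min_depth,support_min_fraction read-support rule.
#' @param concordance_min_reads genotype concordance depth rule.
#' @param minrel read-candidate rescue threshold.
#' @param cluster_flank,cluster_cutoff CNV-region clustering settings.
#' @param window error-rate window size.
#' @param maf MAF filter for population statistics.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("haplokit_run_"),
                            seed = 1L,
                            locus = locus_spec(seed = seed),
                            populations = c("AFR", "EAS", "EUR"),
                            donors_per_population = 4L,
                            n_snv_sites = 120L,
                            n_alleles_per_gene = 3L,
                            simulate_svs = TRUE,
                            read_lengths = c(350L, 3000L, 6000L, 10000L),
                            coverage = 15,
                            error_rate = 0,
                            merge_min_overlap = 2000L,
                            merge_max_mismatch = 5L,
                            support_min_depth = 10L,
                            support_min_fraction = 0.8,
                            concordance_min_reads = 4L,
                            minrel = 0.05,
                            cluster_flank = 5000L,
                            cluster_cutoff = 0.1,
                            window = 10000L,
                            maf = 0.05) {
  cfg <- as.list(environment())
  thresholds <- c(merge_min_overlap = merge_min_overlap,
                  merge_max_mismatch = merge_max_mismatch,
                  support_min_depth = support_min_depth,
                  support_min_fraction = support_min_fraction,
                  concordance_min_reads = concordance_min_reads,
                  minrel = minrel, cluster_flank = cluster_flank,
                  cluster_cutoff = cluster_cutoff, window = window, maf = maf,
                  coverage = coverage)
  if (any(thresholds <= 0))
    stop("every threshold must be positive; offending: ",
         paste(names(thresholds)[thresholds <= 0], collapse = ", "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[haplokit:%s] %s", stage, sprintf(...)))
}

#' Run the pipeline end to end on a simulated cohort
#'
#' Stages: simulate -> emit truth -> align -> call SNVs/SVs -> cluster the
#' CNV region -> curate alleles -> population statistics. Every output file
#' is listed in a manifest with MD5 checksums; reruns with the same
#' configuration and seed produce byte-identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the cohort, callsets, SV genotypes, cluster
#'   genotypes, allele calls, F_ST/PCA results, and the manifest path.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_log("simulate", "building locus (%d bp) and cohort", config$locus$locus_length)
  ref <- build_locus(config$locus)
  db <- spawn_allele_database(ref, config$n_alleles_per_gene, seed = config$seed + 1L)
  svs <- if (config$simulate_svs) default_sv_events(ref) else list()
  ps <- random_population_spec(ref, db, populations = config$populations,
                               donors_per_population = config$donors_per_population,
                               n_snv_sites = config$n_snv_sites,
                               sv_events = svs, seed = config$seed + 2L)
  cohort <- simulate_cohort(ref, db, ps, seed = config$seed + 3L)
  paths <- emit_truth(cohort, config$out_dir)
  write_allele_db(db, file.path(config$out_dir, "allele_db.fasta"))
  stage_log("simulate", "%d donors, %d SNV sites, %d SV classes",
            length(cohort$donors), nrow(ps$snv_sites), length(svs))

  stage_log("align", "aligning %d haplotypes", 2L * length(cohort$donors))
  idx <- kmer_index(ref)
  chains <- lapply(cohort$donors, function(d)
    lapply(1:2, function(h)
      align_contig(d$haplotypes[[h]]$seq, idx,
                   query_id = sprintf("%s_h%d", d$donor_id, h))))

  mask <- if (length(svs))
    data.frame(start = vapply(svs, function(e) e$start, 0L) - 50L,
               end = vapply(svs, function(e) e$end, 0L) + 50L)
  else NULL
  stage_log("call", "SNV + SV calling (mask: %d regions)",
            if (is.null(mask)) 0L else nrow(mask))
  callsets <- lapply(cohort$donors, function(d)
    call_from_assembly(chains[[d$donor_id]], ref, mask = mask))
  sv_genotypes <- lapply(cohort$donors, function(d)
    detect_svs(chains[[d$donor_id]])$genotypes)
  vcf_rec <- do.call(rbind, lapply(names(callsets), function(d) {
    r <- callsets[[d]]$records
    if (nrow(r) == 0L) return(NULL)
    data.frame(chrom = ref$id, pos = r$pos, ref = r$ref, alt = r$alt,
               source = r$source, masked = r$masked, donor = d, gt = r$gt,
               stringsAsFactors = FALSE)
  }))
  write_tsv(vcf_rec %||% data.frame(), file.path(config$out_dir, "snv_calls.tsv"))
  write_tsv(do.call(rbind, lapply(names(sv_genotypes), function(d) {
    g <- sv_genotypes[[d]]
    if (nrow(g) == 0L) return(NULL)
    cbind(donor = d, g)
  })) %||% data.frame(), file.path(config$out_dir, "sv_genotypes.tsv"))

  stage_log("cluster-sv", "CNV region haplotype clustering")
  pb <- ref$paralog_blocks[1, ]
  region <- c(pb$src_start, pb$copy_end)
  unit <- pb$src_end - pb$src_start + 1L
  rhaps <- list()
  for (d in cohort$donors) for (h in 1:2) {
    rh <- extract_sv_region(d$haplotypes[[h]]$seq, chains[[d$donor_id]][[h]],
                            region, flank = config$cluster_flank, unit = unit,
                            donor_id = d$donor_id, haplotype_index = h)
    if (!is.null(rh)) rhaps[[length(rhaps) + 1L]] <- rh
  }
  cluster_res <- NULL
  if (length(rhaps) >= 2L) {
    dm <- region_distances(rhaps)
    ca <- cluster_region_haplotypes(dm, cutoff = config$cluster_cutoff)
    cluster_res <- genotype_clusters(ca, cohort$labels)
    write_tsv(ca$assignments, file.path(config$out_dir, "cluster_assignments.tsv"))
    write_tsv(cluster_res$diplotypes, file.path(config$out_dir, "cluster_diplotypes.tsv"))
    stage_log("cluster-sv", "%d haplotypes -> %d clusters", length(rhaps), ca$n_clusters)
  }

  stage_log("alleles", "allele curation over %d genes", length(unique(ref$genes$gene)))
  allele_calls <- do.call(rbind, lapply(cohort$donors, function(d)
    do.call(rbind, lapply(1:2, function(h)
      curate_alleles(d$haplotypes[[h]]$seq, ref, db,
                     chains = chains[[d$donor_id]][[h]],
                     donor_id = d$donor_id, haplotype_index = h)))))
  write_tsv(allele_calls, file.path(config$out_dir, "allele_calls.tsv"))
  allele_summary <- summarize_allele_genotypes(
    allele_calls[allele_calls$called, ], cohort$labels,
    paralog_groups = list(IGHG4 = c("IGHG4", "IGHG4B")))

  stage_log("popstats", "genotype matrix, F_ST, PCA")
  gm <- build_genotype_matrix(callsets, maf_filter = config$maf)
  fst <- list(); pca <- NULL
  if (ncol(gm$G) > 0L) {
    for (pop in config$populations)
      fst[[pop]] <- wc_fst(gm, cohort$labels, focal = pop)
    pca <- pca_genotypes(gm)
    write_tsv(do.call(rbind, lapply(names(fst), function(p)
      cbind(population = p, fst[[p]]$per_site))),
      file.path(config$out_dir, "fst_per_site.tsv"))
    write_tsv(data.frame(donor = rownames(pca$scores), pca$scores),
              file.path(config$out_dir, "pca_scores.tsv"))
  }

  files <- sort(list.files(config$out_dir, full.names = TRUE, recursive = TRUE))
  files <- files[!grepl("manifest\\.tsv$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write_tsv(manifest, manifest_path)
  stage_log("done", "%d output files; manifest at %s", nrow(manifest), manifest_path)
  invisible(list(cohort = cohort, reference = ref, allele_db = db,
                 chains = chains, callsets = callsets,
                 sv_genotypes = sv_genotypes, cluster = cluster_res,
                 allele_calls = allele_calls, allele_summary = allele_summary,
                 genotype_matrix = gm, fst = fst, pca = pca,
                 manifest = manifest, manifest_path = manifest_path))
}
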