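#' @title End-to-end pipeline
#' @name pipeline
#' @description
#' Orchestrates the positional CLIP analysis: cross-link sites -> peaks ->
#' binding regions -> enrichment -> five-region occupancy -> consensus
#' clustering -> metagene / stem-loop profiles -> motif export and k-mer
#' scoring -> interval-overlap test. Stages whose inputs are supplied
#' pre-computed are skipped; a manifest records configuration and input
#' hashes plus per-stage record counts so a run is reproducible.
NULL

#' Build a pipeline run configuration
#'
#' Defaults follow the analysis this pipeline reimplements: 50-nt codon
#' windows, region read filter > 20, enrichment thresholds fold > 2 /
#' adjusted p < 0.05, non-binder |log2fc| < 0.2 & p > 0.1, five clusters x
#' 200 rounds at 70% occurrence, 20-nt motif flank, k-mer sizes 4/6/8/10.
#'
#' @param gtf annotation path (GTF).
#' @param reads_bed optional BED6 of read alignments (cross-link stage).
#' @param sites_bed optional BED6 of pre-computed cross-link sites
#'   (skips the cross-link stage).
#' @param rna_counts_tsv per-gene total RNA counts (`gene_id`, `count`).
#' @param sequences_fasta optional transcript sequences (enables the motif
#'   stage).
#' @param stemloop_bed optional stem-loop annotation (enables the
#'   stem-loop profile).
#' @param reference_bed optional reference RBP binding regions (enables
#'   the overlap test).
#' @param seed global seed; each stochastic stage derives its own seed
#'   from it.
#' @param half_window,n_perm,fdr_threshold peak-calling parameters.
#' @param max_gap,min_region_reads region merging parameters.
#' @param k,rounds,occurrence_min clustering parameters.
#' @param flank metagene flank (nt).
#' @param motif_flank nt each side of the motif region centre.
#' @param kmer_sizes motif sizes scanned.
#' @param n_overlap_samples randomization samples for the overlap test.
#' @return list of class `run_config`.
#' @export
run_config <- function(gtf, reads_bed = NULL, sites_bed = NULL,
                       rna_counts_tsv, sequences_fasta = NULL,
                       stemloop_bed = NULL, reference_bed = NULL,
                       seed = 1L, half_window = 3L, n_perm = 100L,
                       fdr_threshold = 0.05, max_gap = 20L,
                       min_region_reads = 20L, k = 5L, rounds = 200L,
                       occurrence_min = 0.70, flank = 500L,
                       motif_flank = 20L, kmer_sizes = c(4L, 6L, 8L, 10L),
                       n_overlap_samples = 1000L) {
  cfg <- as.list(environment())
  if (is.null(cfg$reads_bed) && is.null(cfg$sites_bed))
    stop("supply reads_bed or sites_bed")
  structure(cfg, class = "run_config")
}

.file_hash <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed); all stage outputs
#'   and `manifest.tsv` are written there.
#' @return invisible list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name) message("[posclip] stage: ", name)

  stage("annotate")
  models <- load_annotation(config$gtf, "gtf")
  counts$models <- length(models)
  gene_lengths <- vapply(models, `[[`, 1L, "tx_len")

  if (is.null(config$sites_bed)) {
    stage("crosslink")
    sites_gen <- call_crosslinks(config$reads_bed)
    sites_df <- data.frame(chrom = sites_gen$chrom, start = sites_gen$pos,
                           end = sites_gen$pos + 1L, name = ".",
                           score = sites_gen$count, strand = sites_gen$strand)
    write_bed6(sites_df, file.path(outdir, "sites.bed"))
  } else {
    stage("crosslink (skipped: pre-computed sites supplied)")
    sites_df <- read_bed6(config$sites_bed)
  }
  counts$sites <- nrow(sites_df)

  stage("map")
  sites_tx <- map_sites_to_transcripts(sites_df, models)
  write_tsv(sites_tx, file.path(outdir, "sites_tx.tsv"))
  counts$sites_tx <- nrow(sites_tx)

  stage("peaks")
  peaks <- call_peaks(sites_tx, gene_lengths,
                      half_window = config$half_window,
                      n_perm = config$n_perm,
                      fdr_threshold = config$fdr_threshold,
                      seed = derive_seed(config$seed, "peaks"))
  write_tsv(peaks, file.path(outdir, "peaks.tsv"))
  counts$peaks <- nrow(peaks)

  stage("regions")
  regions <- merge_peaks_to_regions(peaks, max_gap = config$max_gap,
                                    min_reads = config$min_region_reads)
  write_tsv(regions, file.path(outdir, "regions.tsv"))
  counts$regions <- nrow(regions)

  stage("enrichment")
  rna <- read_tsv(config$rna_counts_tsv)
  universe <- intersect(names(models), rna$gene_id)
  # iCLIP side: total per-gene cross-link reads. Reads-in-peaks (written
  # above) are structurally zero for background genes, which would starve
  # the ratio-based size factor of null genes; gene totals keep the
  # normalization anchored while peaks still gate the downstream motif
  # and region analyses.
  gene_reads <- tapply(sites_tx$count, sites_tx$gene_id, sum)
  clip_counts <- data.frame(
    gene_id = universe,
    count = as.integer(ifelse(is.na(gene_reads[universe]), 0L,
                              gene_reads[universe])))
  rna_counts <- data.frame(gene_id = universe,
                           count = rna$count[match(universe, rna$gene_id)])
  enrichment <- enrichment_test(clip_counts, rna_counts)
  write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
  counts$enriched <- sum(enrichment$status == "enriched")

  stage("occupancy")
  enriched_genes <- enrichment$gene_id[enrichment$status == "enriched"]
  occupancy <- compute_occupancy(sites_tx, models, enriched_genes,
                                 min_reads = config$min_region_reads)
  write_tsv(occupancy, file.path(outdir, "occupancy.tsv"))
  counts$occupancy <- nrow(occupancy)

  clustering <- NULL
  if (nrow(occupancy) >= config$k) {
    stage("clustering")
    clustering <- consensus_cluster(occupancy_matrix(occupancy),
                                    k = config$k, rounds = config$rounds,
                                    occurrence_min = config$occurrence_min,
                                    seed = derive_seed(config$seed, "cluster"))
    write_tsv(clustering$assignments, file.path(outdir, "clusters.tsv"))
    counts$assigned <- sum(clustering$assignments$label != "unassigned")
  } else {
    stage("clustering (skipped: fewer occupancy genes than k)")
  }

  stage("profiles")
  prof_start <- metagene_profile(sites_tx, models, "start", config$flank)
  prof_stop <- metagene_profile(sites_tx, models, "stop", config$flank)
  write_tsv(prof_start, file.path(outdir, "metagene_start.tsv"))
  write_tsv(prof_stop, file.path(outdir, "metagene_stop.tsv"))

  slp <- NULL
  if (!is.null(config$stemloop_bed)) {
    sl <- read_bed6(config$stemloop_bed)
    slp <- stemloop_profile(sites_tx, models, sl)
    write_tsv(slp$profile, file.path(outdir, "stemloop_profile.tsv"))
  }

  motifs <- NULL
  if (!is.null(config$sequences_fasta)) {
    stage("motifs")
    seqs <- read_fasta(config$sequences_fasta)
    sel <- select_motif_regions(regions, enrichment, seqs,
                                flank = config$motif_flank, dir = outdir)
    if (length(sel$targets) > 0L && length(sel$background) > 0L) {
      motifs <- kmer_enrichment(sel$targets, sel$background,
                                sizes = config$kmer_sizes)
      write_tsv(motifs, file.path(outdir, "kmer_enrichment.tsv"))
      counts$kmers <- nrow(motifs)
    }
  }

  overlap <- NULL
  if (!is.null(config$reference_bed) && nrow(regions) > 0L) {
    stage("overlap")
    ref <- read_bed6(config$reference_bed)
    # regions live in transcript coordinates; lift to genomic per gene
    qry <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      m <- models[[regions$gene_id[i]]]
      g <- transcript_to_genomic(m, c(regions$start[i], regions$end[i] - 1L))
      data.frame(chrom = m$chrom, start = min(g), end = max(g) + 1L)
    }))
    wsp <- do.call(rbind, lapply(unname(models), function(m)
      data.frame(chrom = m$chrom, start = min(m$exons[, 1L]),
                 end = max(m$exons[, 2L]))))
    overlap <- overlap_randomization(qry, ref[, c("chrom", "start", "end")],
                                     wsp, n_samples = config$n_overlap_samples,
                                     seed = derive_seed(config$seed, "overlap"))
    write_tsv(data.frame(observed = overlap$observed_overlap,
                         expected = overlap$expected_overlap,
                         fold = overlap$fold, p = overlap$p_empirical),
              file.path(outdir, "overlap_test.tsv"))
  }

  stage("manifest")
  inputs <- Filter(Negate(is.null),
                   config[c("gtf", "reads_bed", "sites_bed", "rna_counts_tsv",
                            "sequences_fasta", "stemloop_bed", "reference_bed")])
  cfg_txt <- tempfile()
  dput(config[order(names(config))], file = cfg_txt)
  manifest <- rbind(
    data.frame(key = "config_hash", value = .file_hash(cfg_txt)),
    data.frame(key = paste0("input_hash.", names(inputs)),
               value = vapply(unlist(inputs), .file_hash, "")),
    data.frame(key = paste0("n.", names(counts)),
               value = as.character(unlist(counts))))
  unlink(cfg_txt)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  invisible(list(models = models, sites_tx = sites_tx, peaks = peaks,
                 regions = regions, enrichment = enrichment,
                 occupancy = occupancy, clustering = clustering,
                 metagene_start = prof_start, metagene_stop = prof_stop,
                 stemloop = slp, motifs = motifs, overlap = overlap,
                 manifest = manifest))
}
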