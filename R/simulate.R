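#' @title Synthetic data with planted ground truth
#' @name synthetic_data
#' @description
#' Generators for every input the pipeline consumes: a spliced, stranded
#' coding transcriptome (GTF), position-biased cross-link sites (BED6) with
#' paired total-RNA counts (TSV), one-site binding curves, one-phase decay
#' series, unwinding progress curves and G1/S/G2-M DNA-content histograms.
#' Every generator records the planted truth so downstream recovery can be
#' scored, and is byte-deterministic under a fixed seed.
NULL

#' Simulation configuration
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_genes number of genes.
#' @param archetype_mix named proportions over the five positional
#'   archetypes plus `none` (no binding); must sum to 1. The bound part
#'   defaults to the relative sizes of the five positional clusters
#'   reported for the lymphoma cell line (164/199/56/125/124); 75% of
#'   genes are unbound (roughly the share of expressed genes without
#'   binding in that study) so that library normalization of the
#'   enrichment test stays anchored on the null majority.
#' @param enrichment_fold linear iCLIP/total-RNA enrichment planted on
#'   bound genes.
#' @param library_size_clip,library_size_rna target read totals.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param n_histone_like number of histone-like genes (short 3'UTR ending
#'   in a 16-nt stem-loop; binding planted in the 30 nt upstream of it).
#' @param gene_mean mean per-gene expression before library scaling.
#' @param site_sd Gaussian sd (nt) of cross-link placement around the
#'   archetype centre.
#' @param fp_sd,ct_sd,progress_sd,hist_cv default noise levels for the
#'   assay generators (mP, Ct cycles, signal units, coefficient of
#'   variation).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       archetype_mix = c(five_prime_utr = 0.061,
                                         start = 0.075, cds = 0.021,
                                         stop = 0.047, three_prime_utr = 0.046,
                                         none = 0.750),
                       enrichment_fold = 4,
                       library_size_clip = 2e5,
                       library_size_rna = 2e5,
                       nb_dispersion = 0.05,
                       n_histone_like = 20L,
                       gene_mean = 100,
                       site_sd = 15,
                       fp_sd = 5, ct_sd = 0.1, progress_sd = 1,
                       hist_cv = 0.05) {
  if (!setequal(names(archetype_mix), ARCHETYPES))
    stop("archetype_mix must be named over: ", paste(ARCHETYPES, collapse = ", "))
  archetype_mix <- archetype_mix[ARCHETYPES]
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-6)
    stop("archetype_mix proportions must be non-negative and sum to 1")
  if (n_genes < 1L || n_histone_like < 0L || n_histone_like > n_genes)
    stop("need n_genes >= 1 and 0 <= n_histone_like <= n_genes")
  if (enrichment_fold <= 0 || nb_dispersion <= 0)
    stop("enrichment_fold and nb_dispersion must be positive")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    archetype_mix = archetype_mix, enrichment_fold = enrichment_fold,
    library_size_clip = library_size_clip,
    library_size_rna = library_size_rna,
    nb_dispersion = nb_dispersion,
    n_histone_like = as.integer(n_histone_like),
    gene_mean = gene_mean, site_sd = site_sd,
    fp_sd = fp_sd, ct_sd = ct_sd, progress_sd = progress_sd,
    hist_cv = hist_cv
  ), class = "sim_config")
}

# rnbinom parameterized by mean and dispersion alpha: var = mu + alpha mu^2
rnbinom_alpha <- function(n, mu, alpha) {
  stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a coding transcriptome
#'
#' Draws spliced, stranded coding transcripts with log-normal UTR/CDS
#' lengths (CDS always >= 150 nt so the start/stop 50-nt windows cannot
#' overlap). A configured number of genes are histone-like: short 3'UTR
#' whose last bases carry a 16-nt stem-loop segment (6-base stem +
#' 4-nt loop + 6-base stem) at a recorded position.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; if given, writes
#'   `annotation.gtf`, `transcriptome_truth.tsv` and `stemloops.bed`.
#' @return list with `models` (a `transcript_model_set`), `truth` (data
#'   frame incl. stem-loop transcript coordinates), `sequences` (random
#'   RNA sequence per transcript) and any file paths written.
#' @export
simulate_transcriptome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "transcriptome"))
  n <- config$n_genes
  ids <- sprintf("G%04d", seq_len(n))
  histone <- rep(FALSE, n)
  histone[sample.int(n, config$n_histone_like)] <- TRUE

  utr5 <- pmax(2L, round(stats::rlnorm(n, log(200), 0.6)))
  cds <- pmax(150L, round(stats::rlnorm(n, log(1200), 0.5) / 3) * 3)
  utr3 <- pmax(2L, round(stats::rlnorm(n, log(400), 0.6)))
  # histone-like: compact genes, short 3'UTR ending in the stem-loop segment
  utr5[histone] <- pmax(10L, round(stats::rlnorm(sum(histone), log(50), 0.3)))
  cds[histone] <- pmax(150L, round(stats::rlnorm(sum(histone), log(400), 0.2) / 3) * 3)
  spacer <- round(stats::runif(sum(histone), 35, 60))
  utr3[histone] <- as.integer(spacer + 16L + 5L)

  chroms <- paste0("chr", 1:5)
  cursor <- stats::setNames(rep(10000L, length(chroms)), chroms)
  models <- list()
  sl_start <- rep(NA_integer_, n)
  sl_end <- rep(NA_integer_, n)
  sequences <- character(n)
  for (i in seq_len(n)) {
    L <- utr5[i] + cds[i] + utr3[i]
    chrom <- sample(chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample.int(4L, 1L)
    brk <- sort(sample.int(L - 1L, n_ex - 1L))
    chunk <- diff(c(0L, brk, L))        # exon lengths in tx order
    introns <- round(stats::runif(n_ex - 1L, 50, 500))
    glen_chunks <- if (strand == "+") chunk else rev(chunk)
    gstart <- cursor[[chrom]]
    starts <- gstart + cumsum(c(0L, glen_chunks[-n_ex] +
                                  if (n_ex > 1L) introns else integer(0)))
    exons <- cbind(starts, starts + glen_chunks)
    cursor[[chrom]] <- as.integer(max(exons[, 2L]) + 1000L)
    models[[ids[i]]] <- transcript_model(
      gene_id = ids[i], transcript_id = paste0(ids[i], ".t1"),
      chrom = chrom, strand = strand, exons = exons,
      cds_start_tx = utr5[i], cds_end_tx = utr5[i] + cds[i])
    if (histone[i]) {
      sl_end[i] <- L - 5L
      sl_start[i] <- sl_end[i] - 16L
    }
    sequences[i] <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                          collapse = "")
  }
  names(sequences) <- ids
  class(models) <- "transcript_model_set"
  truth <- cbind(models_table(models),
                 data.frame(histone_like = histone,
                            sl_start_tx = sl_start, sl_end_tx = sl_end))
  out <- list(models = models, truth = truth, sequences = sequences)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$gtf <- file.path(dir, "annotation.gtf")
    write_gtf(models, out$gtf)
    out$truth_path <- write_tsv(truth, file.path(dir, "transcriptome_truth.tsv"))
    sl <- truth[truth$histone_like, ]
    if (nrow(sl) > 0L) {
      bed <- do.call(rbind, lapply(seq_len(nrow(sl)), function(j) {
        m <- models[[sl$gene_id[j]]]
        g <- transcript_to_genomic(m, c(sl$sl_start_tx[j], sl$sl_end_tx[j] - 1L))
        data.frame(chrom = m$chrom, start = min(g), end = max(g) + 1L,
                   name = m$gene_id, score = 0L, strand = m$strand)
      }))
      out$stemloop_bed <- write_bed6(bed, file.path(dir, "stemloops.bed"))
    }
  }
  out
}

#' Write transcript models as GTF
#'
#' @param models a `transcript_model_set`.
#' @param path output file.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    ex <- m$exons
    lines <- c(lines, sprintf("%s\tposclip\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, ex[, 1L] + 1L, ex[, 2L], m$strand, attrs))
    # CDS genomic segments: intersect the CDS transcript span with each exon
    cds_tx <- c(m$cds_start_tx, m$cds_end_tx - 1L)
    g <- transcript_to_genomic(m, cds_tx[1L]:cds_tx[2L])
    runs <- split(sort(g), cumsum(c(1L, diff(sort(g)) != 1L)))
    for (r in runs)
      lines <- c(lines, sprintf("%s\tposclip\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                m$chrom, min(r) + 1L, max(r) + 1L, m$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate iCLIP cross-link sites and paired total-RNA counts
#'
#' Per gene the total-RNA count is negative binomial; the iCLIP count is an
#' RNA-proportional baseline multiplied by `enrichment_fold` for bound
#' genes. Cross-link positions follow the gene's archetype: Gaussian
#' (sd = `site_sd`) around the centre of one of the five regions for bound
#' genes, uniform for unbound genes, and uniform within the 30 nt upstream
#' of the stem-loop for histone-like genes.
#'
#' @param config a [sim_config()].
#' @param transcriptome result of [simulate_transcriptome()].
#' @param planted_motif optional RNA k-mer spliced into each bound gene's
#'   sequence at its binding centre (for motif-recovery benchmarks).
#' @param dir optional output directory (`sites.bed`, `rna_counts.tsv`,
#'   `clip_truth.tsv`).
#' @return list with `sites` (genomic BED6 data frame, score = read
#'   count), `sites_tx` (gene_id/tx_pos/count), `rna_counts`, `truth` and
#'   possibly modified `sequences`.
#' @export
simulate_clip <- function(config, transcriptome, planted_motif = NULL,
                          dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "clip"))
  models <- transcriptome$models
  truth <- transcriptome$truth
  n <- nrow(truth)

  arche <- rep("histone", n)
  free <- !truth$histone_like
  arche[free] <- sample(ARCHETYPES, sum(free), replace = TRUE,
                        prob = config$archetype_mix)
  bound <- arche != "none"
  enriched <- bound & config$enrichment_fold > 1

  mu <- stats::rlnorm(n, log(config$gene_mean), 1)
  rna_mu <- mu * config$library_size_rna / sum(mu)
  clip_base <- mu * ifelse(bound, config$enrichment_fold, 1)
  clip_mu <- clip_base * config$library_size_clip / sum(clip_base)
  rna_count <- rnbinom_alpha(n, rna_mu, config$nb_dispersion)
  clip_count <- rnbinom_alpha(n, clip_mu, config$nb_dispersion)

  centre <- rep(NA_integer_, n)
  sites_tx <- vector("list", n)
  sequences <- transcriptome$sequences
  for (i in seq_len(n)) {
    m <- models[[truth$gene_id[i]]]
    L <- m$tx_len
    nr <- clip_count[i]
    if (nr == 0L) next
    if (arche[i] == "histone") {
      lo <- max(0L, truth$sl_start_tx[i] - 30L)
      hi <- truth$sl_start_tx[i] - 1L
      pos <- lo + floor(stats::runif(nr) * (hi - lo + 1L))
      centre[i] <- as.integer(round((lo + hi) / 2))
    } else if (arche[i] == "none") {
      pos <- floor(stats::runif(nr) * L)
    } else {
      b <- region_breaks(m)
      j <- match(arche[i], REGION_LABELS)
      ctr <- switch(arche[i],
                    start = m$cds_start_tx,
                    stop = m$cds_end_tx,
                    as.integer(round((b[j] + b[j + 1L]) / 2)))
      pos <- pmin(L - 1L, pmax(0L, round(stats::rnorm(nr, ctr, config$site_sd))))
      centre[i] <- ctr
    }
    tab <- table(pos)
    sites_tx[[i]] <- data.frame(gene_id = truth$gene_id[i],
                                tx_pos = as.integer(names(tab)),
                                count = as.integer(tab),
                                stringsAsFactors = FALSE)
    if (!is.null(planted_motif) && bound[i] && !is.na(centre[i])) {
      at <- min(max(1L, centre[i] + 1L), nchar(sequences[i]) - nchar(planted_motif) + 1L)
      substr(sequences[i], at, at + nchar(planted_motif) - 1L) <- planted_motif
    }
  }
  sites_tx <- do.call(rbind, sites_tx[!vapply(sites_tx, is.null, TRUE)])
  if (is.null(sites_tx))
    sites_tx <- data.frame(gene_id = character(0), tx_pos = integer(0),
                           count = integer(0))

  sites_bed <- if (nrow(sites_tx) > 0L) {
    do.call(rbind, lapply(split(sites_tx, sites_tx$gene_id), function(s) {
      m <- models[[s$gene_id[1L]]]
      data.frame(chrom = m$chrom,
                 start = transcript_to_genomic(m, s$tx_pos),
                 name = s$gene_id, score = s$count, strand = m$strand,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(chrom = character(0), start = integer(0),
                    name = character(0), score = integer(0),
                    strand = character(0))
  sites_bed$end <- sites_bed$start + 1L
  sites_bed <- sites_bed[order(sites_bed$chrom, sites_bed$start),
                         c("chrom", "start", "end", "name", "score", "strand")]
  rownames(sites_bed) <- NULL

  clip_truth <- data.frame(gene_id = truth$gene_id, archetype = arche,
                           enriched = enriched, centre_tx = centre,
                           clip_count = clip_count, rna_count = rna_count,
                           stringsAsFactors = FALSE)
  rna <- data.frame(gene_id = truth$gene_id, count = rna_count,
                    stringsAsFactors = FALSE)
  out <- list(sites = sites_bed, sites_tx = sites_tx, rna_counts = rna,
              truth = clip_truth, sequences = sequences)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$sites_path <- write_bed6(sites_bed, file.path(dir, "sites.bed"))
    out$rna_path <- write_tsv(rna, file.path(dir, "rna_counts.tsv"))
    out$truth_path <- write_tsv(clip_truth, file.path(dir, "clip_truth.tsv"))
  }
  out
}

#' Simulate a fluorescence-polarization binding curve
#'
#' One-site model: `FP(c) = fp_free + (fp_bound - fp_free) c / (kd + c)`
#' plus Gaussian noise.
#'
#' @param kd dissociation constant (nM), positive.
#' @param fp_free,fp_bound polarization of free and bound probe (mP).
#' @param concentrations protein concentrations (nM), non-negative.
#' @param sd Gaussian noise sd (mP).
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return data frame `concentration_nM`, `polarization_mP`, `replicate`.
#' @export
simulate_binding_curve <- function(kd, fp_free, fp_bound, concentrations,
                                   sd = 0, n_reps = 1L, seed = 1L) {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  set.seed(derive_seed(seed, "binding_curve"))
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    fp <- fp_free + (fp_bound - fp_free) * concentrations / (kd + concentrations)
    data.frame(concentration_nM = concentrations,
               polarization_mP = fp + stats::rnorm(length(fp), 0, sd),
               replicate = r)
  }))
}

#' Simulate a one-phase decay series
#'
#' `abundance(t) = (1 - plateau) exp(-ln2 t / t_half) + plateau` plus
#' Gaussian noise; the noise-free value at t = 0 is 1.
#'
#' @param t_half half-life (hours), positive.
#' @param plateau asymptotic fraction in `[0, 1)`.
#' @param timepoints hours.
#' @param sd Gaussian noise sd.
#' @param n_reps replicates (independent noise).
#' @param seed integer seed.
#' @return data frame `time_h`, `relative_abundance`, `replicate`.
#' @export
simulate_decay <- function(t_half, plateau = 0, timepoints = c(0, 1, 2, 4, 8),
                           sd = 0, n_reps = 1L, seed = 1L) {
  if (t_half <= 0) stop("t_half must be positive")
  if (plateau < 0 || plateau >= 1) stop("plateau must be in [0, 1)")
  set.seed(derive_seed(seed, "decay"))
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    y <- (1 - plateau) * exp(-log(2) * timepoints / t_half) + plateau
    data.frame(time_h = timepoints,
               relative_abundance = y + stats::rnorm(length(y), 0, sd),
               replicate = r)
  }))
}

#' Simulate a DNA-content histogram
#'
#' G1 events are Normal(`g1_mean`, cv * g1_mean), G2/M events
#' Normal(2 g1_mean, cv * 2 g1_mean) and S-phase events uniform between the
#' two means before blurring with the same CV. Events are binned over
#' `[0, 3 g1_mean]`.
#'
#' @param fractions_g1_s_g2 proportions (G1, S, G2/M) summing to 1.
#' @param g1_mean G1 peak channel.
#' @param cv coefficient of variation in `(0, 0.2]`.
#' @param n_events total events.
#' @param n_bins histogram bins (>= 50; default matches common
#'   cytometer channel resolution).
#' @param seed integer seed.
#' @return list of class `dna_histogram`: `bin_centers`, `counts`,
#'   `n_events`, `truth`.
#' @export
simulate_dna_histogram <- function(fractions_g1_s_g2, g1_mean = 200, cv = 0.05,
                                   n_events = 10000L, n_bins = 256L, seed = 1L) {
  f <- fractions_g1_s_g2
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-6)
    stop("fractions must be three non-negative proportions summing to 1")
  if (cv <= 0 || cv > 0.2) stop("cv must be in (0, 0.2]")
  set.seed(derive_seed(seed, "dna_histogram"))
  counts <- as.integer(stats::rmultinom(1L, n_events, f))
  x <- c(stats::rnorm(counts[1L], g1_mean, cv * g1_mean),
         {
           u <- stats::runif(counts[2L], g1_mean, 2 * g1_mean)
           stats::rnorm(counts[2L], u, cv * u)
         },
         stats::rnorm(counts[3L], 2 * g1_mean, cv * 2 * g1_mean))
  breaks <- seq(0, 3 * g1_mean, length.out = n_bins + 1L)
  x <- pmin(pmax(x, 0), 3 * g1_mean)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(bin_centers = h$mids, counts = h$counts,
                 n_events = as.integer(n_events),
                 truth = stats::setNames(f, c("g1", "s", "g2m"))),
            class = "dna_histogram")
}

#' Simulate an unwinding progress curve
#'
#' Flat baseline during the lag, linear rise at the stated velocity, capped
#' at the plateau; Gaussian noise added.
#'
#' @param velocity signal units per minute, non-negative.
#' @param lag lag time (min).
#' @param plateau signal cap.
#' @param timepoints minutes.
#' @param sd noise sd.
#' @param baseline starting signal.
#' @param seed integer seed.
#' @return data frame `time_min`, `signal`.
#' @export
simulate_unwinding <- function(velocity, lag = 0, plateau = Inf,
                               timepoints = 0:30, sd = 0, baseline = 0,
                               seed = 1L) {
  if (velocity < 0) stop("velocity must be non-negative")
  set.seed(derive_seed(seed, "unwinding"))
  y <- baseline + pmin(pmax(timepoints - lag, 0) * velocity,
                       max(plateau - baseline, 0))
  data.frame(time_min = timepoints,
             signal = y + stats::rnorm(length(y), 0, sd))
}
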