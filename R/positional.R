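#' @title Positional occupancy, profiles, motifs and overlap statistics
#' @name positional_analysis
NULL

#' Five-region occupancy per gene
#'
#' For each enriched gene with more than `min_reads` site reads, counts
#' cross-link reads per positional region and converts them to RPKM
#' (reads per kilobase of region per million mapped reads, library size =
#' total site reads over the considered genes).
#'
#' @param sites_tx data frame `gene_id`, `tx_pos`, `count`.
#' @param models named list of `transcript_model` objects.
#' @param enriched_genes character vector of gene ids to consider.
#' @param min_reads genes must exceed this read total (strict).
#' @return data frame with one row per retained gene: `gene_id`,
#'   `total_reads`, `raw.<region>` and `rpkm.<region>` columns; attribute
#'   `n_excluded` counts genes failing the read filter.
#' @export
compute_occupancy <- function(sites_tx, models, enriched_genes,
                              min_reads = 20L) {
  missing_models <- setdiff(enriched_genes, names(models))
  if (length(missing_models) > 0L)
    stop("no transcript model for: ",
         paste(utils::head(missing_models, 10L), collapse = ", "))
  s <- sites_tx[sites_tx$gene_id %in% enriched_genes, , drop = FALSE]
  totals <- tapply(s$count, s$gene_id, sum)
  keep <- names(totals)[totals > min_reads]
  n_excluded <- length(enriched_genes) - length(keep)
  if (n_excluded > 0L)
    message(n_excluded, " gene(s) excluded (<= ", min_reads, " reads)")
  if (length(keep) == 0L) {
    out <- data.frame(gene_id = character(0))
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  lib <- sum(totals[keep])
  by_gene <- split(s, s$gene_id)
  rows <- lapply(keep, function(g) {
    m <- models[[g]]
    sg <- by_gene[[g]]
    reg <- classify_position(m, sg$tx_pos)
    raw <- tapply(sg$count, reg, sum)
    raw[is.na(raw)] <- 0
    lens <- region_lengths(m)
    rpkm <- ifelse(lens > 0, raw / (lens / 1000) / (lib / 1e6), 0)
    cbind(data.frame(gene_id = g, total_reads = sum(sg$count)),
          stats::setNames(as.data.frame(as.list(raw)),
                          paste0("raw.", REGION_LABELS)),
          stats::setNames(as.data.frame(as.list(rpkm)),
                          paste0("rpkm.", REGION_LABELS)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "library_reads") <- lib
  out
}

#' Extract the genes x regions RPKM matrix from an occupancy table
#'
#' @param occupancy result of [compute_occupancy()].
#' @return numeric matrix (genes x 5) with gene ids as row names.
#' @export
occupancy_matrix <- function(occupancy) {
  m <- as.matrix(occupancy[, paste0("rpkm.", REGION_LABELS)])
  dimnames(m) <- list(occupancy$gene_id, REGION_LABELS)
  m
}

#' Metagene profile anchored at the start or stop codon
#'
#' Each gene's per-position counts are normalized to sum 1 over its
#' transcript; the profile is the per-offset mean of those densities
#' across the genes whose transcripts cover the offset.
#'
#' @param sites_tx data frame `gene_id`, `tx_pos`, `count`.
#' @param models named list of `transcript_model` objects.
#' @param anchor `"start"` (first base of the start codon) or `"stop"`
#'   (CDS/3'UTR junction).
#' @param flank offsets `-flank..flank` are reported.
#' @return data frame `offset`, `density`, `n` (contributing genes).
#' @export
metagene_profile <- function(sites_tx, models, anchor = c("start", "stop"),
                             flank = 500L) {
  anchor <- match.arg(anchor)
  genes <- intersect(unique(sites_tx$gene_id), names(models))
  if (length(genes) == 0L) stop("no genes shared between sites and models")
  offsets <- seq(-flank, flank)
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  by_gene <- split(sites_tx, sites_tx$gene_id)
  for (g in genes) {
    m <- models[[g]]
    a <- if (anchor == "start") m$cds_start_tx else m$cds_end_tx
    sg <- by_gene[[g]]
    tot <- sum(sg$count)
    if (tot == 0) next
    o_lo <- max(-flank, -a)
    o_hi <- min(flank, m$tx_len - 1L - a)
    if (o_lo > o_hi) next
    n[(o_lo + flank + 1L):(o_hi + flank + 1L)] <-
      n[(o_lo + flank + 1L):(o_hi + flank + 1L)] + 1L
    so <- sg$tx_pos - a
    in_rng <- so >= -flank & so <= flank
    acc[so[in_rng] + flank + 1L] <- acc[so[in_rng] + flank + 1L] +
      sg$count[in_rng] / tot
  }
  data.frame(offset = offsets,
             density = ifelse(n > 0, acc / pmax(n, 1L), NA_real_),
             n = n)
}

#' Site density around the histone stem-loop
#'
#' Per-gene site densities (normalized to sum 1 within the window) at
#' offsets relative to the stem-loop's first base, averaged across the
#' annotated genes; genes without sites contribute zeros.
#'
#' @param sites_tx data frame `gene_id`, `tx_pos`, `count`.
#' @param models named list of `transcript_model` objects.
#' @param stemloops data frame with `gene_id` and `sl_start_tx`
#'   (transcript coordinate of the stem-loop's first base), or a BED6 data
#'   frame of genomic stem-loop intervals named by gene.
#' @param window offsets `-window..window` are profiled.
#' @return list with `profile` (data frame `offset`, `density`),
#'   `upstream_fraction` (mass at offsets < 0) and `n_genes`.
#' @export
stemloop_profile <- function(sites_tx, models, stemloops, window = 100L) {
  if (!"sl_start_tx" %in% names(stemloops)) {
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(stemloops)))
    stemloops <- do.call(rbind, lapply(seq_len(nrow(stemloops)), function(i) {
      m <- models[[stemloops$name[i]]]
      if (is.null(m)) stop("no model for stem-loop gene ", stemloops$name[i])
      tx <- genomic_to_transcript(m, c(stemloops$start[i], stemloops$end[i] - 1L))
      data.frame(gene_id = m$gene_id, sl_start_tx = min(tx))
    }))
  }
  offsets <- seq(-window, window)
  acc <- numeric(length(offsets))
  for (i in seq_len(nrow(stemloops))) {
    g <- stemloops$gene_id[i]
    m <- models[[g]]
    if (is.null(m)) stop("no model for stem-loop gene ", g)
    sl <- stemloops$sl_start_tx[i]
    if (sl < 0L || sl >= m$tx_len)
      stop("stem-loop of ", g, " outside its transcript")
    sg <- sites_tx[sites_tx$gene_id == g, , drop = FALSE]
    so <- sg$tx_pos - sl
    in_rng <- so >= -window & so <= window
    tot <- sum(sg$count[in_rng])
    if (tot == 0) next
    acc[so[in_rng] + window + 1L] <- acc[so[in_rng] + window + 1L] +
      sg$count[in_rng] / tot
  }
  n_genes <- nrow(stemloops)
  dens <- acc / max(n_genes, 1L)
  mass <- sum(dens)
  upstream <- if (mass > 0) sum(dens[offsets < 0]) / mass else NA_real_
  list(profile = data.frame(offset = offsets, density = dens),
       upstream_fraction = upstream, n_genes = n_genes)
}

#' Select motif target and background regions
#'
#' Targets: for each enriched gene, the single binding region with the
#' most peaks (ties: most reads, then 5'-most), trimmed to `flank` nt on
#' each side of the region centre. Background: every region (already read
#' filtered) of a non-binder gene, trimmed the same way.
#'
#' @param regions data frame from [merge_peaks_to_regions()] (transcript
#'   coordinates).
#' @param enrichment_results data frame from [enrichment_test()].
#' @param sequences named character vector of transcript sequences (RNA or
#'   DNA alphabet) keyed by gene id.
#' @param flank nt kept on each side of the region centre.
#' @param dir optional directory to write `motif_targets.fasta` and
#'   `motif_background.fasta`.
#' @return list with `targets` and `background` (named character vectors;
#'   names carry `gene:start-end` coordinates) plus the underlying tables.
#' @export
select_motif_regions <- function(regions, enrichment_results, sequences,
                                 flank = 20L, dir = NULL) {
  pick <- function(genes, best_only) {
    rows <- list()
    for (g in genes) {
      rg <- regions[regions$gene_id == g, , drop = FALSE]
      if (nrow(rg) == 0L) next
      if (best_only) {
        ord <- order(-rg$n_peaks, -rg$read_count, rg$start)
        rg <- rg[ord[1L], , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- rg
    }
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
  }
  extract <- function(tab) {
    if (is.null(tab)) return(character(0))
    out <- character(nrow(tab))
    nms <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      g <- tab$gene_id[i]
      seq <- sequences[[g]]
      if (is.null(seq) || is.na(seq)) stop("no sequence for gene ", g)
      ctr <- (tab$start[i] + tab$end[i]) %/% 2L
      lo <- max(0L, ctr - flank)
      hi <- min(nchar(seq), ctr + flank)
      out[i] <- substr(seq, lo + 1L, hi)
      nms[i] <- sprintf("%s:%d-%d", g, lo, hi)
    }
    stats::setNames(out, nms)
  }
  enriched <- enrichment_results$gene_id[enrichment_results$status == "enriched"]
  nonbind <- enrichment_results$gene_id[enrichment_results$status == "non_binder"]
  ttab <- pick(enriched, best_only = TRUE)
  skipped <- setdiff(enriched, ttab$gene_id)
  if (length(skipped) > 0L)
    message(length(skipped), " enriched gene(s) without a surviving region skipped")
  btab <- pick(nonbind, best_only = FALSE)
  out <- list(targets = extract(ttab), background = extract(btab),
              target_table = ttab, background_table = btab)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$target_path <- write_fasta(out$targets,
                                   file.path(dir, "motif_targets.fasta"))
    out$background_path <- write_fasta(out$background,
                                       file.path(dir, "motif_background.fasta"))
  }
  out
}

kmers_present <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' K-mer enrichment of target over background sequences
#'
#' Presence/absence per sequence; one-sided hypergeometric p for
#' over-representation among targets, Benjamini-Hochberg adjusted within
#' each motif size. Sequences shorter than k are skipped for that size.
#'
#' @param targets,background character vectors of sequences.
#' @param sizes k-mer sizes to scan.
#' @return data frame `kmer`, `size`, `target_frac`, `background_frac`,
#'   `p_value`, `p_adj`, ranked by p within the full table.
#' @export
kmer_enrichment <- function(targets, background, sizes = c(4L, 6L, 8L, 10L)) {
  if (length(targets) == 0L || length(background) == 0L)
    stop("both target and background sets must be non-empty")
  res <- list()
  for (k in sizes) {
    tk <- lapply(targets, kmers_present, k = k)
    bk <- lapply(background, kmers_present, k = k)
    n_t <- sum(vapply(targets, nchar, 1L) >= k)
    n_b <- sum(vapply(background, nchar, 1L) >= k)
    if (n_t == 0L || n_b == 0L) next
    x_t <- table(unlist(lapply(tk, unique)))
    x_b <- table(unlist(lapply(bk, unique)))
    univ <- union(names(x_t), names(x_b))
    xt <- as.integer(x_t[univ]); xt[is.na(xt)] <- 0L
    xb <- as.integer(x_b[univ]); xb[is.na(xb)] <- 0L
    p <- stats::phyper(xt - 1L, n_t, n_b, xt + xb, lower.tail = FALSE)
    res[[length(res) + 1L]] <- data.frame(
      kmer = univ, size = k, target_frac = xt / n_t,
      background_frac = xb / n_b, p_value = p,
      p_adj = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_interval_df <- function(x) {
  if (inherits(x, "GRanges"))
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x) - 1L,
                    end = GenomicRanges::end(x))
  x <- as.data.frame(x)
  if (!"chrom" %in% names(x))
    x$chrom <- rep("*", nrow(x))
  x[, c("chrom", "start", "end")]
}

.overlap_nt <- function(a, b) {
  tot <- 0L
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == ch] + 1L,
                                           a$end[a$chrom == ch]))
    ib <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == ch] + 1L,
                                           b$end[b$chrom == ch]))
    tot <- tot + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  tot
}

#' Interval-overlap randomization test
#'
#' Tests whether the nucleotide overlap between query and reference
#' intervals exceeds random expectation: each sample re-places the query
#' segments (lengths preserved, segments kept non-overlapping, rejection
#' sampling) uniformly within the workspace and the empirical p is
#' `(#samples with overlap >= observed + 1) / (n_samples + 1)`.
#'
#' @param query,reference,workspace interval data frames with `start`,
#'   `end` (0-based half-open; optional `chrom`) or `GRanges`.
#' @param n_samples randomization samples.
#' @param seed integer seed.
#' @return list of class `overlap_test`: `observed_overlap`,
#'   `expected_overlap`, `fold`, `p_empirical`, `n_samples`.
#' @export
overlap_randomization <- function(query, reference, workspace,
                                  n_samples = 1000L, seed = 1L) {
  q <- .as_interval_df(query)
  r <- .as_interval_df(reference)
  w <- .as_interval_df(workspace)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  lens <- sort(q$end - q$start, decreasing = TRUE)
  wlen <- w$end - w$start
  if (sum(lens) > sum(wlen))
    stop("workspace too small to place query segments")
  observed <- .overlap_nt(q, r)

  # map workspace segments onto one concatenated axis so a single uniform
  # draw places a segment in a workspace-proportional interval; reference
  # overlap is evaluated with prefix-sum coverage on the same axis
  w$offset <- cumsum(c(0, utils::head(wlen, -1L)))
  to_axis <- function(d) {
    out <- NULL
    for (i in seq_len(nrow(w))) {
      sel <- d$chrom == w$chrom[i] & d$start < w$end[i] & d$end > w$start[i]
      if (!any(sel)) next
      out <- rbind(out, data.frame(
        start = pmax(d$start[sel], w$start[i]) - w$start[i] + w$offset[i],
        end = pmin(d$end[sel], w$end[i]) - w$start[i] + w$offset[i]))
    }
    out
  }
  ra <- to_axis(r)
  if (is.null(ra)) ra <- data.frame(start = numeric(0), end = numeric(0))
  ra <- ra[order(ra$start), , drop = FALSE]
  # merge overlapping reference pieces
  if (nrow(ra) > 1L) {
    keep_grp <- cumsum(c(1, as.integer(ra$start[-1L] >
                                         cummax(ra$end[-nrow(ra)]))))
    ra <- data.frame(start = tapply(ra$start, keep_grp, min),
                     end = tapply(ra$end, keep_grp, max))
  }
  cum_cov <- cumsum(c(0, ra$end - ra$start))
  covered <- function(p) {
    i <- findInterval(p, ra$start)
    ifelse(i == 0L, 0,
           cum_cov[pmax(i, 1L)] +
             pmin(pmax(p - ra$start[pmax(i, 1L)], 0),
                  ra$end[pmax(i, 1L)] - ra$start[pmax(i, 1L)]))
  }
  # valid start positions per segment length: segment must fit inside one
  # workspace segment; cumulative valid-start counts drive uniform draws
  total_axis <- sum(wlen)
  set.seed(derive_seed(seed, "overlap"))
  nulls <- numeric(n_samples)
  k <- length(lens)
  # per-length valid-start bookkeeping on the concatenated axis: a start
  # drawn in [cum[i], cum[i+1]) lands in workspace segment i
  start_tab <- lapply(unique(lens), function(l) {
    ns <- pmax(0, wlen - l + 1)
    if (sum(ns) == 0) stop("workspace too small to place query segments")
    list(ns = ns, cum = cumsum(c(0, ns)))
  })
  names(start_tab) <- as.character(unique(lens))
  for (si in seq_len(n_samples)) {
    starts <- numeric(k)
    for (j in seq_len(k)) {
      tab <- start_tab[[as.character(lens[j])]]
      placed <- FALSE
      for (attempt in 1:1000) {
        u <- floor(stats::runif(1) * tab$cum[length(tab$cum)])
        wi <- min(findInterval(u, tab$cum, left.open = FALSE), nrow(w))
        st <- w$offset[wi] + (u - tab$cum[wi])
        if (j > 1L) {
          prev <- seq_len(j - 1L)
          if (any(starts[prev] < st + lens[j] &
                    starts[prev] + lens[prev] > st)) next
        }
        starts[j] <- st
        placed <- TRUE
        break
      }
      if (!placed)
        stop("workspace too small to place query segments without overlap")
    }
    nulls[si] <- sum(covered(starts + lens) - covered(starts))
  }
  expected <- mean(nulls)
  fold <- if (expected > 0) observed / expected else if (observed > 0) Inf else 0
  structure(list(observed_overlap = observed, expected_overlap = expected,
                 fold = fold,
                 p_empirical = (sum(nulls >= observed) + 1) / (n_samples + 1),
                 n_samples = n_samples, null_overlaps = nulls),
            class = "overlap_test")
}
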