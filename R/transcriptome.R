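#' @title Transcript models and five-region positional classification
#' @name transcriptome
#' @description
#' A `transcript_model` describes one spliced, stranded coding transcript:
#' its exons in genomic coordinates (0-based, half-open) and the position of
#' the CDS in transcript coordinates. Transcript coordinates run 5' to 3'
#' along the spliced mRNA, starting at 0. Every transcript position belongs
#' to exactly one of five positional regions: 5'UTR, start (50 nt on each
#' side of the start codon), CDS interior, stop (50 nt on each side of the
#' CDS/3'UTR junction) and 3'UTR.
NULL

#' Construct a transcript model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of genomic exon intervals (0-based,
#'   half-open), non-overlapping; rows may be in any order.
#' @param cds_start_tx transcript coordinate of the first base of the start
#'   codon (equals the 5'UTR length).
#' @param cds_end_tx transcript coordinate one past the last CDS base
#'   (the first 3'UTR base; equals 5'UTR length + CDS length).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds_start_tx, cds_end_tx) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon intervals must be non-empty half-open [start, end)")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons overlap")
  tx_len <- sum(exons[, 2L] - exons[, 1L])
  cds_start_tx <- as.integer(cds_start_tx)
  cds_end_tx <- as.integer(cds_end_tx)
  if (cds_start_tx < 0L || cds_end_tx > tx_len || cds_end_tx - cds_start_tx < 3L)
    stop("CDS must lie within the transcript and span at least 3 nt")
  structure(list(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons,
    tx_len = as.integer(tx_len),
    cds_start_tx = cds_start_tx,
    cds_end_tx = cds_end_tx,
    utr5_len = cds_start_tx,
    cds_len = cds_end_tx - cds_start_tx,
    utr3_len = as.integer(tx_len) - cds_end_tx
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d nt [UTR5 %d | CDS %d | UTR3 %d]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$tx_len, x$utr5_len, x$cds_len, x$utr3_len))
  invisible(x)
}

#' Map genomic positions onto the spliced transcript
#'
#' Exonic positions map to their cumulative spliced offset from the
#' transcript 5' end (strand-aware); intronic or out-of-range positions
#' map to `NA`.
#'
#' @param model a `transcript_model`.
#' @param genomic_pos integer vector of 0-based genomic positions.
#' @return integer vector of transcript coordinates, `NA` where non-exonic.
#' @export
genomic_to_transcript <- function(model, genomic_pos) {
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  cum_before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  idx <- findInterval(genomic_pos, ex[, 1L])
  ok <- idx >= 1L & genomic_pos < ex[pmax(idx, 1L), 2L]
  plus_off <- rep(NA_integer_, length(genomic_pos))
  plus_off[ok] <- cum_before[idx[ok]] + as.integer(genomic_pos[ok]) - ex[idx[ok], 1L]
  unname(if (model$strand == "+") plus_off else model$tx_len - 1L - plus_off)
}

#' Map transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_transcript()]; round-trips exactly for every
#' exonic base.
#'
#' @param model a `transcript_model`.
#' @param tx_pos integer vector of transcript coordinates in
#'   `[0, tx_len)`.
#' @return integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(model, tx_pos) {
  if (any(tx_pos < 0L | tx_pos >= model$tx_len))
    stop("transcript coordinate out of range")
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  cum <- c(0L, cumsum(widths))
  plus_off <- if (model$strand == "+") as.integer(tx_pos) else
    model$tx_len - 1L - as.integer(tx_pos)
  idx <- findInterval(plus_off, cum, left.open = FALSE)
  idx <- pmin(idx, nrow(ex))
  unname(ex[idx, 1L] + (plus_off - cum[idx]))
}

# Region boundaries as a cumulative breaks vector b of length 6:
# region i (in REGION_LABELS order) is the half-open interval [b[i], b[i+1]).
# Start window anchored at the first base of the start codon, stop window at
# the CDS/3'UTR junction; windows truncated at transcript ends. When the CDS
# is shorter than 100 nt the two windows overlap and the overlap is divided
# at the midpoint between the anchors (ties to stop), leaving a zero-length
# CDS region.
region_breaks <- function(model) {
  sa <- model$cds_start_tx
  so <- model$cds_end_tx
  L <- model$tx_len
  w <- REGION_WINDOW
  lo_start <- max(0L, sa - w)
  hi_stop <- min(L, so + w)
  if (model$cds_len >= 2L * w) {
    b <- c(0L, lo_start, sa + w, so - w, hi_stop, L)
  } else {
    split <- (sa + so + 1L) %/% 2L
    b <- c(0L, lo_start, split, split, hi_stop, L)
  }
  b
}

#' Classify transcript positions into the five positional regions
#'
#' Regions per transcript: 5'UTR (>50 nt upstream of the start codon),
#' start (50 nt on each side of the start codon), CDS (from 50 nt after the
#' start codon to 50 nt before the stop), stop (50 nt on each side of the
#' CDS/3'UTR junction) and 3'UTR (>50 nt downstream). Windows are half-open
#' `[anchor - 50, anchor + 50)` and truncated at transcript ends; for CDSs
#' shorter than 100 nt, overlapping window positions go to whichever anchor
#' is strictly closer (ties to stop).
#'
#' @param model a `transcript_model`.
#' @param tx_pos integer vector of transcript coordinates.
#' @return factor with levels `five_prime_utr`, `start`, `cds`, `stop`,
#'   `three_prime_utr`.
#' @export
classify_position <- function(model, tx_pos) {
  if (any(tx_pos < 0L | tx_pos >= model$tx_len))
    stop("position out of transcript range")
  b <- region_breaks(model)
  idx <- findInterval(tx_pos, b[-1L]) + 1L
  factor(REGION_LABELS[pmin(idx, 5L)], levels = REGION_LABELS)
}

#' Lengths of the five positional regions
#'
#' @param model a `transcript_model`.
#' @return named integer vector of five region lengths summing to the
#'   transcript length. Depends only on the UTR/CDS lengths, never on exon
#'   structure.
#' @export
region_lengths <- function(model) {
  b <- region_breaks(model)
  stats::setNames(diff(b), REGION_LABELS)
}

#' Load transcript models from an annotation file
#'
#' Keeps exactly one model per gene: the coding transcript with the longest
#' spliced length (ties broken by longest CDS, then lexicographically
#' smallest transcript id). Non-coding transcripts and genes without any
#' coding transcript are dropped; transcripts whose CDS falls outside their
#' exons are rejected with a message.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` (requires `gene_id`/`transcript_id` attributes and
#'   CDS features) or `"bed12"` (thickStart/thickEnd as the CDS; the name
#'   field serves as both gene and transcript id).
#' @return named list of `transcript_model` objects (by gene id), with
#'   attributes `n_excluded_genes` (genes with no usable coding transcript)
#'   and `n_rejected` (transcripts with inconsistent CDS).
#' @export
load_annotation <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") .load_gtf(path) else .load_bed12(path)
}

.load_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("cannot parse GTF '", path, "': ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "transcript_id") %in% colnames(md)))
    stop("GTF must carry gene_id and transcript_id attributes")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF is 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    stringsAsFactors = FALSE
  )
  .assemble_models(df)
}

.load_bed12 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("cannot parse BED12 '", path, "': ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks))
    stop("BED input lacks block structure; 12-column BED required")
  rows <- list()
  for (i in seq_along(gr)) {
    blocks <- md$blocks[[i]]
    tx_start <- GenomicRanges::start(gr)[i] - 1L
    ex_start <- tx_start + IRanges::start(blocks) - 1L
    ex_end <- ex_start + IRanges::width(blocks)
    thick <- md$thick[i]
    name <- if (!is.null(md$name)) md$name[i] else paste0("tx", i)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = ex_start, end = ex_end,
      strand = as.character(GenomicRanges::strand(gr))[i],
      type = "exon", gene_id = name, transcript_id = name,
      stringsAsFactors = FALSE)
    if (IRanges::width(thick) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        start = IRanges::start(thick) - 1L, end = IRanges::end(thick),
        strand = as.character(GenomicRanges::strand(gr))[i],
        type = "CDS", gene_id = name, transcript_id = name,
        stringsAsFactors = FALSE)
  }
  .assemble_models(do.call(rbind, rows))
}

# Build one transcript_model per gene from a long feature table with
# columns chrom/start/end/strand/type/gene_id/transcript_id.
.assemble_models <- function(df) {
  n_rejected <- 0L
  by_tx <- split(df, df$transcript_id)
  candidates <- list()
  for (tx in names(by_tx)) {
    feats <- by_tx[[tx]]
    exons <- feats[feats$type == "exon", , drop = FALSE]
    cds <- feats[feats$type == "CDS", , drop = FALSE]
    if (nrow(exons) == 0L || nrow(cds) == 0L) next  # non-coding or malformed
    strand <- exons$strand[1L]
    if (!strand %in% c("+", "-")) next
    ex <- as.matrix(exons[order(exons$start), c("start", "end")])
    m <- try(transcript_model(
      gene_id = exons$gene_id[1L], transcript_id = tx,
      chrom = exons$chrom[1L], strand = strand,
      exons = ex, cds_start_tx = 0L, cds_end_tx = 3L), silent = TRUE)
    if (inherits(m, "try-error")) { n_rejected <- n_rejected + 1L; next }
    gmin <- min(cds$start); gmax <- max(cds$end)
    t1 <- genomic_to_transcript(m, gmin)
    t2 <- genomic_to_transcript(m, gmax - 1L)
    if (is.na(t1) || is.na(t2)) {
      message("transcript ", tx, " rejected: CDS outside exons")
      n_rejected <- n_rejected + 1L
      next
    }
    sa <- min(t1, t2); so <- max(t1, t2) + 1L
    m$cds_start_tx <- sa; m$cds_end_tx <- so
    m$utr5_len <- sa; m$cds_len <- so - sa; m$utr3_len <- m$tx_len - so
    candidates[[length(candidates) + 1L]] <- m
  }
  all_genes <- unique(df$gene_id)
  if (length(candidates) == 0L) {
    out <- structure(list(), class = "transcript_model_set")
    attr(out, "n_excluded_genes") <- length(all_genes)
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  genes <- vapply(candidates, `[[`, "", "gene_id")
  models <- list()
  for (g in sort(unique(genes))) {
    cand <- candidates[genes == g]
    len <- vapply(cand, `[[`, 1L, "tx_len")
    clen <- vapply(cand, `[[`, 1L, "cds_len")
    tid <- vapply(cand, `[[`, "", "transcript_id")
    ord <- order(-len, -clen, tid)
    models[[g]] <- cand[[ord[1L]]]
  }
  structure(models, class = "transcript_model_set",
            n_excluded_genes = length(setdiff(all_genes, names(models))),
            n_rejected = n_rejected)
}

#' Summarize transcript models as a data frame
#'
#' @param models list of `transcript_model` objects.
#' @return data frame with one row per model.
#' @export
models_table <- function(models) {
  do.call(rbind, lapply(unname(models), function(m) data.frame(
    gene_id = m$gene_id, transcript_id = m$transcript_id, chrom = m$chrom,
    strand = m$strand, tx_len = m$tx_len, utr5_len = m$utr5_len,
    cds_len = m$cds_len, utr3_len = m$utr3_len,
    cds_start_tx = m$cds_start_tx, cds_end_tx = m$cds_end_tx,
    stringsAsFactors = FALSE)))
}

#' Per-cluster UTR length distributions
#'
#' Summarizes 5'UTR and 3'UTR lengths of the genes in each positional
#' binding cluster (median and quartiles).
#'
#' @param models list of `transcript_model` objects keyed by gene id.
#' @param cluster_assignments data frame with columns `gene_id` and `label`.
#' @return data frame with one row per cluster label.
#' @export
utr_length_stats <- function(models, cluster_assignments) {
  unknown <- setdiff(cluster_assignments$gene_id, names(models))
  if (length(unknown) > 0L)
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  labs <- unique(as.character(cluster_assignments$label))
  out <- lapply(labs, function(lb) {
    g <- cluster_assignments$gene_id[cluster_assignments$label == lb]
    u5 <- vapply(models[g], `[[`, 1L, "utr5_len")
    u3 <- vapply(models[g], `[[`, 1L, "utr3_len")
    q5 <- stats::quantile(u5, c(0.25, 0.5, 0.75), names = FALSE)
    q3 <- stats::quantile(u3, c(0.25, 0.5, 0.75), names = FALSE)
    if (length(g) == 0L) q5 <- q3 <- rep(NA_real_, 3L)
    data.frame(label = lb, n = length(g),
               utr5_q1 = q5[1L], utr5_median = q5[2L], utr5_q3 = q5[3L],
               utr3_q1 = q3[1L], utr3_median = q3[2L], utr3_q3 = q3[3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
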