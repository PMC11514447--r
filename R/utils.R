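# Shared small helpers: per-stage seed derivation and plain-text I/O for
# the interval/count formats the pipeline exchanges.

#' Derive a per-stage seed from a global seed
#'
#' Hashes the stage name into a 31-bit offset so that inserting a stage in
#' the pipeline does not shift the randomness of the others.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Write intervals as BED6
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path output file.
#' @export
write_bed6 <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in%
                  names(df)))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  utils::write.table(
    df[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file with at least 6 columns.
#' @return data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("'", path, "' has fewer than 6 BED columns")
  df <- df[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  nms <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 paste, "", collapse = "")
  stats::setNames(unname(seqs), nms)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs))
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  invisible(path)
}
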