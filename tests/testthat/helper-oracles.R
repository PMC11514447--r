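# Shared fixtures and independent oracles used across the suite.

# random multi-exon transcript model (both strands, 1-5 exons)
random_model <- function(seed, min_cds = 150L) {
  set.seed(seed)
  utr5 <- sample(0:300, 1L)
  cds <- max(min_cds, 3L * sample(1:400, 1L))
  utr3 <- sample(0:400, 1L)
  L <- utr5 + cds + utr3
  n_ex <- sample(1:5, 1L)
  brk <- if (n_ex > 1L) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0)
  chunks <- diff(c(0L, brk, L))
  introns <- if (n_ex > 1L) sample(20:300, n_ex - 1L, replace = TRUE) else integer(0)
  strand <- sample(c("+", "-"), 1L)
  gchunks <- if (strand == "+") chunks else rev(chunks)
  starts <- 1000L + cumsum(c(0L, head(gchunks, -1L) + introns))
  transcript_model("g", "t", "chrX", strand,
                   cbind(starts, starts + gchunks),
                   cds_start_tx = utr5, cds_end_tx = utr5 + cds)
}

# brute-force spliced-sequence oracle: the list of genomic positions of the
# transcript, base by base, 5' to 3'
spliced_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    model$exons[i, 1L]:(model$exons[i, 2L] - 1L)))
  if (model$strand == "-") rev(pos) else pos
}

# literal interval-membership oracle for the five-region classification,
# built directly from the quoted window definitions plus the stated
# truncation and nearest-anchor rules
region_oracle <- function(model, tx_pos) {
  sa <- model$cds_start_tx
  so <- model$cds_end_tx
  w <- 50L
  vapply(tx_pos, function(p) {
    in_start <- p >= sa - w && p < sa + w
    in_stop <- p >= so - w && p < so + w
    if (in_start && in_stop) {
      if (abs(p - sa) < abs(p - so)) "start" else "stop"
    } else if (in_start) "start"
    else if (in_stop) "stop"
    else if (p < sa - w) "five_prime_utr"
    else if (p >= so + w) "three_prime_utr"
    else "cds"
  }, "")
}

# sequential-rejection placement of n non-overlapping segments of a given
# length on [0, ws_len); mirrors the randomization scheme of the overlap
# test so calibration can be checked under its own null
place_segments <- function(n, len, ws_len) {
  starts <- numeric(n)
  for (j in seq_len(n)) {
    repeat {
      st <- floor(runif(1) * (ws_len - len + 1))
      if (j == 1L ||
            all(starts[1:(j - 1)] >= st + len | starts[1:(j - 1)] + len <= st))
        break
    }
    starts[j] <- st
  }
  data.frame(start = starts, end = starts + len)
}

# random RNA sequence of length n
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
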