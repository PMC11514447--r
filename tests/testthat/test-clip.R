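test_that("cross-link sites follow the truncation convention", {
  reads <- data.frame(chrom = "c1",
                      start = c(100, 100, 100, 150, 0),
                      end = c(130, 130, 130, 200, 30),
                      name = ".", score = 0,
                      strand = c("+", "+", "+", "-", "+"))
  sites <- suppressMessages(call_crosslinks(reads))
  # three identical plus reads at 100 -> one site at 99, count 3
  expect_equal(sites$pos[sites$strand == "+"], 99L)
  expect_equal(sites$count[sites$strand == "+"], 3L)
  # minus read covering [150,200) -> site at 200
  expect_equal(sites$pos[sites$strand == "-"], 200L)
  # read starting at 0 -> site at -1 dropped and logged
  expect_equal(attr(sites, "n_dropped_origin"), 1L)
  expect_equal(sum(sites$count), 4L)  # conservation of usable reads
})

test_that("unstranded records are skipped with a count", {
  reads <- data.frame(chrom = "c1", start = c(10, 20), end = c(15, 25),
                      name = ".", score = 0, strand = c("+", "."))
  sites <- suppressMessages(call_crosslinks(reads))
  expect_equal(attr(sites, "n_unstranded"), 1L)
  expect_equal(nrow(sites), 1L)
})

test_that("site-to-transcript mapping is strand- and splice-aware", {
  cfg <- sim_config(seed = 8, n_genes = 25, n_histone_like = 0)
  tr <- simulate_transcriptome(cfg)
  cl <- simulate_clip(cfg, tr)
  mapped <- map_sites_to_transcripts(cl$sites, tr$models)
  a <- aggregate(count ~ gene_id + tx_pos, cl$sites_tx, sum)
  b <- aggregate(count ~ gene_id + tx_pos, mapped, sum)
  expect_equal(a[order(a$gene_id, a$tx_pos), ],
               b[order(b$gene_id, b$tx_pos), ], ignore_attr = TRUE)
})

test_that("peak calling separates concentration from uniform background", {
  # maximal concentration: one position holding all reads
  pk <- call_peaks(data.frame(gene_id = "g", tx_pos = 500L, count = 100L),
                   c(g = 1000L), seed = 2)
  expect_equal(nrow(pk), 1L)
  expect_lt(pk$fdr, 0.01)
  expect_true(pk$start <= 500 && pk$end > 500)
  expect_equal(pk$read_count, 100L)
  # perfectly uniform signal: no peaks
  pk2 <- call_peaks(data.frame(gene_id = "g", tx_pos = 0:999, count = 1L),
                    c(g = 1000L), seed = 3)
  expect_equal(nrow(pk2), 0L)
  # zero-site gene is silently peak-free
  expect_equal(nrow(call_peaks(data.frame(gene_id = character(0),
                                          tx_pos = integer(0),
                                          count = integer(0)),
                               c(g = 100L), seed = 1)), 0L)
})

test_that("planted site clusters are recovered at the right place", {
  hits <- 0L
  for (i in 1:30) {
    set.seed(i)
    pos <- c(pmin(1999, pmax(0, round(rnorm(50, 1000, 15)))),
             sample.int(2000, 50, replace = TRUE) - 1L)
    tab <- table(pos)
    st <- data.frame(gene_id = "p", tx_pos = as.integer(names(tab)),
                     count = as.integer(tab))
    pk <- call_peaks(st, c(p = 2000L), seed = i)
    if (nrow(pk) > 0 && any(pk$start <= 1030 & pk$end >= 970)) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
  # peak reads never exceed site reads (conservation)
  set.seed(7)
  pos <- c(round(rnorm(80, 500, 15)), sample.int(1500, 40, TRUE) - 1L)
  pos <- pmin(1499, pmax(0, pos))
  tab <- table(pos)
  st <- data.frame(gene_id = "q", tx_pos = as.integer(names(tab)),
                   count = as.integer(tab))
  pk <- call_peaks(st, c(q = 1500L), seed = 7)
  expect_lte(sum(pk$read_count), sum(st$count))
})

test_that("region merging applies the gap and strict read rules", {
  peaks <- data.frame(gene_id = "g",
                      start = c(100L, 117L, 300L),
                      end = c(107L, 124L, 310L),
                      n_sites = 1L,
                      read_count = c(15L, 15L, 20L),
                      fdr = 0.01)
  reg <- merge_peaks_to_regions(peaks, max_gap = 20L)
  # peaks 10 nt apart merge (15 + 15 = 30 reads, kept); the 20-read
  # singleton is discarded (strictly more than 20 required)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$read_count, 30L)
  expect_equal(reg$n_peaks, 2L)
  # peaks 100 nt apart stay separate
  p2 <- data.frame(gene_id = "g", start = c(0L, 130L), end = c(10L, 140L),
                   n_sites = 1L, read_count = c(30L, 40L), fdr = 0.01)
  expect_equal(nrow(merge_peaks_to_regions(p2)), 2L)
})

test_that("enrichment test handles equality, zeroes and mismatches", {
  genes <- paste0("g", 1:200)
  set.seed(1)
  cnt <- rnbinom(200, mu = 80, size = 20) + 1L
  same <- data.frame(gene_id = genes, count = cnt)
  res <- enrichment_test(same, same)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$status != "enriched"))
  # both-zero genes are indeterminate with NA p
  z <- data.frame(gene_id = genes, count = c(0L, cnt[-1]))
  res2 <- enrichment_test(z, z)
  expect_equal(res2$status[1], "indeterminate")
  expect_true(is.na(res2$p_value[1]))
  expect_error(enrichment_test(same, data.frame(gene_id = "other", count = 1L)),
               "differ")
})

test_that("enrichment test is antisymmetric under table swap", {
  set.seed(3)
  n <- 600
  genes <- paste0("g", seq_len(n))
  mu <- rlnorm(n, log(80), 1)
  a <- data.frame(gene_id = genes,
                  count = rnbinom(n, mu = mu * c(rep(4, 60), rep(1, n - 60)),
                                  size = 20))
  b <- data.frame(gene_id = genes, count = rnbinom(n, mu = mu, size = 20))
  r1 <- enrichment_test(a, b)
  r2 <- enrichment_test(b, a)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  # enriched and non-binder sets disjoint by construction
  expect_length(intersect(which(r1$status == "enriched"),
                          which(r1$status == "non_binder")), 0)
})
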