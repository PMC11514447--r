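make_sites <- function(gene, pos, count = 1L) {
  data.frame(gene_id = gene, tx_pos = as.integer(pos),
             count = as.integer(count))
}

test_that("occupancy counts per region, converts to RPKM and filters", {
  m <- transcript_model("g1", "t", "c", "+", rbind(c(0, 2000)), 500, 1500)
  models <- list(g1 = m)
  # all reads in the 5'UTR region (positions < 450)
  occ <- compute_occupancy(make_sites("g1", c(10, 20, 30), c(40, 40, 20)),
                           models, "g1")
  expect_equal(unname(unlist(occ[paste0("raw.", c("five_prime_utr", "start",
                                                  "cds", "stop",
                                                  "three_prime_utr"))])),
               c(100, 0, 0, 0, 0))
  # worked RPKM example: 10 reads in a 500-nt region, library 1e6
  m2 <- transcript_model("g2", "t", "c", "+", rbind(c(0, 1100)), 550, 1050)
  # 5'UTR region length = 550 - 50 = 500
  s2 <- rbind(make_sites("g2", 0:9, 1L),
              make_sites("g2", 600, 999990L))  # pad library to 1e6
  occ2 <- compute_occupancy(s2, list(g2 = m2), "g2")
  expect_equal(occ2$raw.five_prime_utr, 10)
  expect_equal(occ2$rpkm.five_prime_utr, 20)
  # gene with exactly 20 reads is excluded (strict filter)
  occ3 <- suppressMessages(
    compute_occupancy(make_sites("g1", 1:20), models, "g1"))
  expect_equal(nrow(occ3), 0)
  expect_equal(attr(occ3, "n_excluded"), 1L)
  expect_error(compute_occupancy(make_sites("gX", 1), models, "gX"), "gX")
})

test_that("occupancy raw counts conserve gene read totals", {
  cfg <- sim_config(seed = 13, n_genes = 40, n_histone_like = 0)
  tr <- simulate_transcriptome(cfg)
  cl <- simulate_clip(cfg, tr)
  occ <- suppressMessages(
    compute_occupancy(cl$sites_tx, tr$models, tr$truth$gene_id))
  raw <- as.matrix(occ[, grep("^raw", names(occ))])
  expect_equal(unname(rowSums(raw)), occ$total_reads)
  totals <- tapply(cl$sites_tx$count, cl$sites_tx$gene_id, sum)
  expect_equal(occ$total_reads, as.vector(totals[occ$gene_id]))
})

test_that("metagene profile is a delta for anchored reads and flat for uniform", {
  m <- transcript_model("g", "t", "c", "+", rbind(c(0, 1200)), 300, 900)
  pr <- metagene_profile(make_sites("g", 300, 50L), list(g = m), "start",
                         flank = 100)
  expect_equal(pr$density[pr$offset == 0], 1)
  expect_true(all(pr$density[pr$offset != 0] == 0, na.rm = TRUE))
  # uniform placement over many genes: flat within Monte-Carlo noise
  set.seed(2)
  models <- list(); sites <- list()
  for (i in 1:200) {
    g <- sprintf("u%03d", i)
    models[[g]] <- transcript_model(g, "t", "c", "+", rbind(c(0, 1500)), 400, 1300)
    tab <- table(sample.int(1500, 100, replace = TRUE) - 1L)
    sites[[g]] <- make_sites(g, as.integer(names(tab)), as.integer(tab))
  }
  pr2 <- metagene_profile(do.call(rbind, sites), models, "start", flank = 300)
  p <- 1 / 1500
  mc_sd <- sqrt(p * (1 - p) / 100 / 200)  # binomial density, 100 reads, 200 genes
  expect_gte(mean(abs(pr2$density - p) <= 3 * mc_sd), 0.985)
  expect_equal(mean(pr2$density), p, tolerance = 0.02)
})

test_that("metagene profile of a union is the weighted mean of its parts", {
  m1 <- transcript_model("a", "t", "c", "+", rbind(c(0, 800)), 200, 700)
  m2 <- transcript_model("b", "t", "c", "+", rbind(c(0, 1000)), 300, 900)
  s1 <- make_sites("a", c(190, 210, 400), c(5, 3, 2))
  s2 <- make_sites("b", c(290, 330), c(1, 9))
  f <- 150
  pa <- metagene_profile(s1, list(a = m1), "start", f)
  pb <- metagene_profile(s2, list(b = m2), "start", f)
  pu <- metagene_profile(rbind(s1, s2), list(a = m1, b = m2), "start", f)
  na <- pa$n; nb <- pb$n
  expected <- ifelse(na + nb > 0,
                     (ifelse(na > 0, pa$density * na, 0) +
                        ifelse(nb > 0, pb$density * nb, 0)) / (na + nb),
                     NA_real_)
  expect_equal(pu$density, expected)
})

test_that("stem-loop profile separates upstream from downstream mass", {
  m <- transcript_model("h", "t", "c", "+", rbind(c(0, 600)), 50, 500)
  sl <- data.frame(gene_id = "h", sl_start_tx = 560L)
  pr <- stemloop_profile(make_sites("h", 530:559), list(h = m), sl, window = 100)
  expect_equal(pr$upstream_fraction, 1.0)
  # symmetric uniform input: upstream fraction = 100/201
  m2 <- transcript_model("u", "t", "c", "+", rbind(c(0, 600)), 50, 300)
  sl2 <- data.frame(gene_id = "u", sl_start_tx = 300L)
  pr2 <- stemloop_profile(make_sites("u", 200:400), list(u = m2), sl2,
                          window = 100)
  expect_equal(pr2$upstream_fraction, 100 / 201, tolerance = 1e-10)
  # gene without sites contributes zeros, not an error
  pr3 <- stemloop_profile(make_sites("h", 530:559),
                          list(h = m, u = m2),
                          rbind(sl, sl2), window = 100)
  expect_equal(pr3$n_genes, 2)
  expect_equal(sum(pr3$profile$density), 0.5)
})

test_that("motif region selection follows the peak/read/position tie-breaks", {
  regions <- data.frame(
    gene_id = c("e1", "e1", "e1", "n1", "n2"),
    start = c(100L, 300L, 500L, 40L, 60L),
    end = c(140L, 340L, 540L, 80L, 100L),
    n_peaks = c(3L, 5L, 5L, 1L, 2L),
    read_count = c(50L, 60L, 90L, 25L, 30L))
  enr <- data.frame(gene_id = c("e1", "n1", "n2", "e2"),
                    status = c("enriched", "non_binder", "non_binder",
                               "enriched"))
  seqs <- c(e1 = random_rna(700), n1 = random_rna(200), n2 = random_rna(200))
  set.seed(1)
  sel <- suppressMessages(
    select_motif_regions(regions, enr, seqs, flank = 20))
  # 5-peak tie broken by reads: region [500,540), centre 520, span 500-540
  expect_named(sel$targets, "e1:500-540")
  expect_equal(nchar(sel$targets[[1]]), 40L)
  expect_equal(sel$targets[[1]], substr(seqs[["e1"]], 501, 540))
  # background: every surviving non-binder region
  expect_length(sel$background, 2L)
  # enriched gene without region skipped, not an error
  expect_false("e2" %in% sel$target_table$gene_id)
})

test_that("k-mer scorer matches the hypergeometric closed form", {
  set.seed(5)
  tg <- vapply(1:60, function(i) random_rna(40), "")
  bg <- vapply(1:80, function(i) random_rna(40), "")
  motif <- "ACGUAC"
  tg <- vapply(tg, function(s) { substr(s, 11, 16) <- motif; s }, "",
               USE.NAMES = FALSE)
  ke <- kmer_enrichment(tg, bg)
  top <- ke[ke$size == 6, ][1, ]
  expect_equal(top$kmer, motif)
  x_b <- sum(vapply(bg, function(s) grepl(motif, s, fixed = TRUE), TRUE))
  p_exact <- phyper(60 - 1, 60, 80, 60 + x_b, lower.tail = FALSE)
  expect_equal(top$p_value, p_exact, tolerance = 1e-12)
  # identical target and background sets: nothing significant
  ke2 <- kmer_enrichment(tg, tg)
  expect_true(all(ke2$target_frac == ke2$background_frac))
  expect_gt(min(ke2$p_adj), 0.05)
  # sequences shorter than k skipped for that size
  ke3 <- kmer_enrichment(c("ACGU", tg), bg, sizes = c(6L))
  expect_true(all(ke3$target_frac <= 1))
})

test_that("overlap test matches brute force and hits the p floor", {
  set.seed(2)
  qs <- sort(sample.int(900, 5)); q <- data.frame(start = qs, end = qs + 30)
  rs <- sort(sample.int(900, 5)); r <- data.frame(start = rs, end = rs + 50)
  ws <- data.frame(start = 0, end = 1000)
  bf <- sum(vapply(0:999, function(p)
    any(q$start <= p & p < q$end) && any(r$start <= p & p < r$end), TRUE))
  res <- overlap_randomization(q, r, ws, n_samples = 49, seed = 3)
  expect_equal(res$observed_overlap, bf)
  # identical query and reference: maximal overlap, p at the floor
  set.seed(10)
  qq <- place_segments(20, 200, 2e5)
  res2 <- overlap_randomization(qq, qq, data.frame(start = 0, end = 2e5),
                                n_samples = 199, seed = 5)
  expect_equal(res2$p_empirical, 1 / 200)
  expect_gt(res2$fold, 1)
  # empty reference
  res3 <- overlap_randomization(qq, qq[0, ], data.frame(start = 0, end = 2e5),
                                n_samples = 49, seed = 5)
  expect_equal(res3$observed_overlap, 0)
  expect_equal(res3$fold, 0)
  expect_equal(res3$p_empirical, 1)
  # workspace too small
  expect_error(overlap_randomization(data.frame(start = 0, end = 500),
                                     r, data.frame(start = 0, end = 100),
                                     n_samples = 9, seed = 1),
               "workspace")
})
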