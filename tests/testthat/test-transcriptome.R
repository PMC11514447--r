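test_that("genomic/transcript mapping matches the spliced-sequence oracle", {
  for (seed in 1:40) {
    m <- random_model(seed)
    sp <- spliced_positions(m)
    tx <- genomic_to_transcript(m, sp)
    expect_equal(tx, seq_len(m$tx_len) - 1L)
    expect_equal(transcript_to_genomic(m, tx), sp)
    # intronic and flanking positions map to NA
    outside <- c(min(m$exons) - 1L, max(m$exons) + 5L)
    expect_true(all(is.na(genomic_to_transcript(m, outside))))
  }
})

test_that("worked mapping examples hold", {
  m <- transcript_model("g", "t", "c", "+", rbind(c(0, 100), c(200, 300)), 0, 3)
  expect_identical(m$tx_len, 200L)
  expect_equal(genomic_to_transcript(m, 250), 150L)
  m1 <- transcript_model("g", "t", "c", "+", rbind(c(1000, 2000)), 0, 3)
  expect_equal(genomic_to_transcript(m1, 1000), 0L)
  m2 <- transcript_model("g", "t", "c", "-", rbind(c(0, 100)), 0, 3)
  expect_equal(genomic_to_transcript(m2, 0), 99L)
})

test_that("classify_position partitions and matches the literal oracle", {
  # stated worked example
  mm <- transcript_model("g", "t", "c", "+", rbind(c(0, 900)), 200, 500)
  expect_equal(as.character(classify_position(mm, c(100, 160, 300, 470, 600))),
               c("five_prime_utr", "start", "cds", "stop", "three_prime_utr"))
  expect_equal(unname(region_lengths(mm)), c(150, 100, 200, 100, 350))
  # random models incl. short-UTR and short-CDS edge cases
  cases <- c(lapply(1:25, random_model),
             lapply(26:40, random_model, min_cds = 3L))
  for (m in cases) {
    pos <- 0:(m$tx_len - 1L)
    lab <- as.character(classify_position(m, pos))
    expect_equal(lab, region_oracle(m, pos))
    # labels partition: counts match region lengths, lengths sum to total
    rl <- region_lengths(m)
    expect_equal(as.vector(table(factor(lab, names(rl)))), unname(rl))
    expect_equal(sum(rl), m$tx_len)
  }
})

test_that("region lengths truncate at transcript ends", {
  m <- transcript_model("g", "t", "c", "+", rbind(c(0, 500)), 10, 310)
  rl <- region_lengths(m)
  expect_equal(unname(rl[c("five_prime_utr", "start")]), c(0, 60))
  expect_equal(sum(rl), 500)
  # region lengths depend only on utr/cds lengths, not exon structure
  m2 <- transcript_model("g", "t", "c", "-",
                         rbind(c(0, 200), c(300, 500), c(600, 700)), 10, 310)
  expect_equal(region_lengths(m2), rl)
})

test_that("load_annotation keeps the longest coding transcript per gene", {
  gtf <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "gA"; transcript_id "tA1";'
  attr2 <- 'gene_id "gA"; transcript_id "tA2";'
  attr3 <- 'gene_id "gB"; transcript_id "tB1";'
  writeLines(c(
    sprintf("c1\tx\texon\t1\t900\t.\t+\t.\t%s", attr1),
    sprintf("c1\tx\tCDS\t101\t700\t.\t+\t0\t%s", attr1),
    sprintf("c1\tx\texon\t1\t1400\t.\t+\t.\t%s", attr2),
    sprintf("c1\tx\tCDS\t101\t700\t.\t+\t0\t%s", attr2),
    sprintf("c2\tx\texon\t1\t500\t.\t+\t.\t%s", attr3)  # non-coding gene
  ), gtf)
  models <- load_annotation(gtf, "gtf")
  expect_named(models, "gA")
  expect_equal(models$gA$transcript_id, "tA2")
  expect_equal(models$gA$tx_len, 1400L)
  expect_equal(attr(models, "n_excluded_genes"), 1L)
})

test_that("gtf round-trips through write_gtf/load_annotation", {
  cfg <- sim_config(seed = 21, n_genes = 15, n_histone_like = 3)
  tr <- simulate_transcriptome(cfg, dir = tempfile())
  models <- load_annotation(tr$gtf, "gtf")
  expect_length(models, 15)
  for (g in names(tr$models)) {
    expect_identical(models[[g]]$exons, tr$models[[g]]$exons)
    expect_identical(models[[g]]$cds_start_tx, tr$models[[g]]$cds_start_tx)
    expect_identical(models[[g]]$cds_end_tx, tr$models[[g]]$cds_end_tx)
  }
})

test_that("bed12 dialect loads thick region as CDS", {
  bed <- tempfile(fileext = ".bed")
  # two exons [100,200) and [300,400); CDS [150,350) genomic
  writeLines(paste(c("c1", 100, 400, "tx1", 0, "+", 150, 350, "0",
                     2, "100,100", "0,200"), collapse = "\t"), bed)
  models <- load_annotation(bed, "bed12")
  m <- models$tx1
  expect_equal(m$tx_len, 200L)
  expect_equal(m$utr5_len, 50L)
  expect_equal(m$cds_len, 100L)
  expect_equal(m$utr3_len, 50L)
})

test_that("utr_length_stats summarizes per cluster and checks ids", {
  cfg <- sim_config(seed = 5, n_genes = 10, n_histone_like = 0)
  tr <- simulate_transcriptome(cfg)
  asg <- data.frame(gene_id = tr$truth$gene_id,
                    label = rep(c("a", "b"), 5))
  st <- utr_length_stats(tr$models, asg)
  expect_equal(sort(st$label), c("a", "b"))
  expect_equal(st$n, c(5L, 5L))
  one <- utr_length_stats(tr$models,
                          data.frame(gene_id = tr$truth$gene_id[1], label = "x"))
  expect_equal(one$utr5_median, tr$truth$utr5_len[1])
  expect_error(utr_length_stats(tr$models,
                                data.frame(gene_id = "nope", label = "x")),
               "nope")
})
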