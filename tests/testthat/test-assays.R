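conc12 <- round(8 * (2000 / 8)^((0:11) / 11))  # 8 nM .. 2 uM log ladder

test_that("one-site fit recovers K_D and degrades gracefully", {
  bc <- simulate_binding_curve(100, 50, 200, conc12, sd = 0, seed = 1)
  f <- fit_one_site(bc)
  expect_true(f$converged)
  expect_equal(f$kd, 100, tolerance = 0.01)
  expect_equal(f$fp_free, 50, tolerance = 1e-4)
  expect_equal(f$fp_bound, 200, tolerance = 1e-3)
  # scale equivariance: multiplying readings leaves kd unchanged
  bc2 <- bc; bc2$polarization_mP <- bc2$polarization_mP * 7
  expect_equal(fit_one_site(bc2)$kd, f$kd, tolerance = 1e-6)
  # flat readings: no signal, never an exception
  flat <- data.frame(concentration_nM = conc12, polarization_mP = 50)
  expect_false(fit_one_site(flat)$converged)
  expect_error(fit_one_site(data.frame(concentration_nM = c(1, 1, 2, 2),
                                       polarization_mP = 1:4)), "distinct")
})

test_that("K_D fit flags weak binding beyond the concentration range", {
  bc <- simulate_binding_curve(1e6, 50, 200, conc12, sd = 0, seed = 1)
  f <- fit_one_site(bc)
  expect_false(f$converged)
  expect_equal(f$flag, "weak_binding")
})

test_that("ANOVA comparison of K_D groups behaves at both extremes", {
  mk_fits <- function(kds) lapply(kds, function(k) {
    f <- fit_one_site(simulate_binding_curve(k, 50, 200, conc12, sd = 1,
                                             seed = round(k * 13)))
    f
  })
  same <- list(a = mk_fits(c(100, 101, 99)), b = mk_fits(c(100.5, 99.5, 100)))
  r <- compare_kd(same)
  expect_lt(r$f_statistic, 4)
  expect_gt(r$p_value, 0.05)
  diffg <- list(a = mk_fits(c(100, 110, 95)), b = mk_fits(c(400, 396, 405)))
  expect_lt(compare_kd(diffg)$p_value, 0.001)
  expect_error(compare_kd(list(a = mk_fits(c(100, 100)))), "2 groups")
  # non-converged member drops its group with a warning
  bad <- diffg
  bad$a[[1]]$converged <- FALSE
  expect_warning(expect_error(compare_kd(bad), "2 groups"), "excluding")
})

test_that("one-phase decay recovers rate, plateau and the stable flag", {
  f <- fit_one_phase_decay(simulate_decay(2, 0, c(0, 1, 2, 4, 8), sd = 0))
  expect_equal(f$t_half, 2, tolerance = 1e-6)
  expect_equal(f$plateau, 0)
  f2 <- fit_one_phase_decay(simulate_decay(2, 0.2, c(0, 0.5, 1, 2, 4, 8, 12),
                                           sd = 0))
  expect_equal(f2$plateau, 0.2, tolerance = 1e-4)
  expect_equal(f2$t_half, 2, tolerance = 1e-4)
  # essentially undecayed input reports infinite half-life
  fs <- fit_one_phase_decay(simulate_decay(5000, 0, c(0, 1, 2, 4, 8), sd = 0))
  expect_equal(fs$flag, "stable")
  expect_equal(fs$t_half, Inf)
  expect_error(fit_one_phase_decay(data.frame(time_h = 1:5,
                                              relative_abundance = 0.5)),
               "t = 0")
})

test_that("decay rate rescales exactly with the time unit", {
  d <- simulate_decay(2, 0.1, c(0, 1, 2, 4, 8), sd = 0.05, n_reps = 3, seed = 7)
  fh <- fit_one_phase_decay(d)
  dm <- d
  dm$time_h <- dm$time_h * 60
  fm <- fit_one_phase_decay(dm)
  expect_equal(fm$k, fh$k / 60, tolerance = 1e-6)
})

test_that("relative quantification matches brute-force arithmetic", {
  ct <- data.frame(sample = rep(c("t0", "t4"), each = 2),
                   gene = rep(c("H4C8", "GAPDH"), 2),
                   ct = c(20, 15, 22, 15))
  r <- relative_quantification(ct, reference = "GAPDH", calibrator = "t0")
  expect_equal(r$rel_level[r$sample == "t0"], 1)
  # target one cycle higher... here two cycles: 2^-2
  expect_equal(r$rel_level[r$sample == "t4"], 0.25)
  # random table vs independent spreadsheet-style recomputation
  set.seed(4)
  samples <- paste0("s", 1:6); genes <- c("ref", "a", "b")
  tab <- expand.grid(sample = samples, gene = genes,
                     stringsAsFactors = FALSE)
  tab$ct <- round(runif(nrow(tab), 15, 30), 2)
  out <- relative_quantification(tab, reference = "ref", calibrator = "s1")
  for (g in c("a", "b")) for (s in samples) {
    dct <- tab$ct[tab$sample == s & tab$gene == g] -
      tab$ct[tab$sample == s & tab$gene == "ref"]
    dct0 <- tab$ct[tab$sample == "s1" & tab$gene == g] -
      tab$ct[tab$sample == "s1" & tab$gene == "ref"]
    expect_equal(out$rel_level[out$sample == s & out$target == g],
                 2^-(dct - dct0))
  }
  expect_error(relative_quantification(tab[tab$gene != "ref", ],
                                       reference = "ref", calibrator = "s1"),
               "s1|reference")
})

test_that("RIP enrichment is the double delta over the IgG control", {
  expect_equal(rip_enrichment(20, 18, 22, 20), 1)
  expect_equal(rip_enrichment(17, 18, 20, 18), 8)
  set.seed(8)
  ip <- runif(5, 18, 28); inp <- runif(5, 15, 20)
  igg <- runif(5, 25, 32); igg_in <- runif(5, 15, 20)
  expect_equal(rip_enrichment(ip, inp, igg, igg_in),
               2^-((ip - inp) - (igg - igg_in)))
  expect_error(rip_enrichment(NA, 1, 2, 3), "missing")
})

test_that("unwinding velocity finds the linear phase", {
  v <- unwinding_velocity(simulate_unwinding(2, timepoints = 0:20, sd = 0))
  expect_equal(v$velocity, 2)
  expect_equal(v$window, c(0, 20))
  # lag then linear rise until the acquisition end
  u <- simulate_unwinding(3, lag = 5, plateau = 45, timepoints = 0:20, sd = 0)
  v2 <- unwinding_velocity(u)
  expect_equal(v2$velocity, 3, tolerance = 1e-8)
  expect_gte(v2$window[1], 5)
  expect_lte(v2$window[2], 20)
  # flat and monotone-decreasing inputs report zero with a flag
  v3 <- unwinding_velocity(simulate_unwinding(0, timepoints = 0:15, sd = 0))
  expect_equal(v3$velocity, 0)
  expect_equal(v3$flag, "flat")
  dec <- data.frame(time_min = 0:10, signal = 10 - (0:10))
  v4 <- unwinding_velocity(dec)
  expect_equal(v4$velocity, 0)
  expect_equal(v4$flag, "decreasing")
})
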