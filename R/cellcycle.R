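#' @title Watson pragmatic cell-cycle deconvolution
#' @name cellcycle
#' @description
#' DNA-content histograms are modelled pragmatically: Gaussians for the G1
#' and G2/M peaks (the G2 mean constrained to 1.8-2.2x the G1 mean) and no
#' parametric S-phase model - S is whatever remains between the two means
#' after subtracting both Gaussians. A flat S background with CV-blurred
#' edges is estimated from the inter-peak region and subtracted while
#' fitting the peaks, so that S-phase events do not inflate the Gaussian
#' amplitudes.
NULL

gauss <- function(x, a, mu, s) a * exp(-(x - mu)^2 / (2 * s^2))

# Poisson-weighted least-squares Gaussian; falls back to the start values
.fit_gauss <- function(x, y, w, a0, mu0, s0, mu_lower = -Inf, mu_upper = Inf,
                       fix_mu = FALSE) {
  co <- if (fix_mu) {
    fit <- tryCatch(stats::nls(y ~ gauss(x, a, mu0, s),
                               start = list(a = a0, s = s0), weights = w,
                               algorithm = "port",
                               lower = c(a = 0, s = 1e-6)),
                    error = function(e) NULL)
    if (is.null(fit)) c(a0, s0) else stats::coef(fit)
  } else NULL
  if (fix_mu)
    return(list(a = co[[1L]], mu = mu0, s = co[[2L]]))
  fit <- tryCatch(stats::nls(y ~ gauss(x, a, mu, s),
                             start = list(a = a0, mu = mu0, s = s0),
                             weights = w, algorithm = "port",
                             lower = c(a = 0, mu = mu_lower, s = 1e-6),
                             upper = c(a = Inf, mu = mu_upper, s = Inf)),
                  error = function(e) NULL)
  if (is.null(fit)) return(list(a = a0, mu = mu0, s = s0))
  co <- stats::coef(fit)
  list(a = co[["a"]], mu = co[["mu"]], s = co[["s"]])
}

#' Estimate G1/S/G2-M fractions from a DNA-content histogram
#'
#' Watson pragmatic model. The G1 peak is located as the tallest
#' low-channel mode (a lone high-channel mode with no mass at half its
#' position is treated as G2). Both peaks are fitted as Gaussians
#' (Poisson-weighted least squares on a +-3 sd window) after subtracting
#' an estimated S-phase background - a flat rate between the two means
#' with CV-blurred edges - and the G2 mean is constrained to
#' `[1.8, 2.2]` times the G1 mean. S-phase counts are the residual counts
#' between the two means (clipped at zero) plus the modelled blur of the
#' S background just beyond the means; fractions are normalized to sum
#' to 1.
#'
#' @param histogram a `dna_histogram` (see [simulate_dna_histogram()]), a
#'   data frame with columns `channel` and `count`, or a path to a
#'   two-column CSV.
#' @return object of class `cellcycle_fit`: `g1`, `s`, `g2m` fractions
#'   (summing to 1), `g1_mean`, `g2_mean`, `g1_cv`, `g2_cv`, `flag`.
#' @export
watson_fit <- function(histogram) {
  if (is.character(histogram)) {
    df <- utils::read.csv(histogram)
    histogram <- list(bin_centers = df[[1L]], counts = df[[2L]])
  }
  if (is.data.frame(histogram))
    histogram <- list(bin_centers = histogram$channel %||% histogram[[1L]],
                      counts = histogram$count %||% histogram[[2L]])
  x <- histogram$bin_centers
  y <- histogram$counts
  if (length(x) < 50L) stop("histogram must have at least 50 bins")
  if (sum(y) < 1000L) stop("histogram must have at least 1000 events")
  ys <- stats::runmed(y, 5L)
  mode_idx <- which.max(ys)
  if (ys[mode_idx] <= 0) stop("no detectable G1 mode")
  c_main <- x[mode_idx]

  peak_in <- function(lo, hi) {
    sel <- x >= lo & x <= hi
    if (!any(sel)) return(c(0, NA))
    i <- which(sel)[which.max(ys[sel])]
    c(ys[i], x[i])
  }
  up <- peak_in(1.8 * c_main, 2.2 * c_main)
  down <- peak_in(c_main / 2.2, c_main / 1.8)
  flag <- "none"
  if (up[1L] >= 0.05 * ys[mode_idx]) {
    g1_guess <- c_main
  } else if (down[1L] >= 0.05 * ys[mode_idx]) {
    g1_guess <- down[2L]
  } else if (c_main <= (min(x) + max(x)) / 2) {
    g1_guess <- c_main            # single low-channel peak: G1 population
  } else {
    g1_guess <- c_main / 2        # single high-channel peak: G2 population
    flag <- "g1_absent"
  }

  # initial sd guess from the left half-maximum of the G1 peak
  i0 <- which.min(abs(x - g1_guess))
  hm <- which(x < x[i0] & ys <= ys[i0] / 2)
  s0 <- if (length(hm) > 0) (x[i0] - x[max(hm)]) / 1.1774 else 0.05 * g1_guess
  s0 <- max(s0, x[2L] - x[1L])

  fit_peak <- function(ynet, a0, mu0, s00, mu_lower = -Inf, mu_upper = Inf,
                       fix_mu = FALSE) {
    win <- x >= mu0 - 3 * s00 & x <= mu0 + 3 * s00
    f <- .fit_gauss(x[win], ynet[win], 1 / pmax(ys[win], 1), a0, mu0, s00,
                    mu_lower, mu_upper, fix_mu)
    win <- x >= f$mu - 3 * f$s & x <= f$mu + 3 * f$s   # refine once
    if (sum(win) >= 4L)
      f <- .fit_gauss(x[win], ynet[win], 1 / pmax(ys[win], 1), f$a, f$mu,
                      f$s, mu_lower, mu_upper, fix_mu)
    f
  }

  g1 <- fit_peak(y, max(ys[i0], 1e-6), g1_guess, s0)
  g2_bounds <- c(1.8, 2.2) * g1$mu
  up2 <- peak_in(g2_bounds[1L], g2_bounds[2L])
  g2_present <- up2[1L] >= max(0.02 * g1$a, 3)
  if (!g2_present) {
    if (flag == "none") flag <- "g2_absent"
    warning("no detectable G2 peak; bounded fit at 2x the G1 mean")
  }
  g2 <- if (g2_present)
    fit_peak(y, up2[1L], up2[2L], 2 * g1$s, g2_bounds[1L], g2_bounds[2L])
  else
    fit_peak(y, 0, 2 * g1$mu, 2 * g1$s, fix_mu = TRUE)

  # iterate: S background (flat between the means, CV-blurred edges)
  # subtracted before refitting each peak
  rate <- 0
  for (it in 1:4) {
    mid <- x > g1$mu + 2 * g1$s & x < g2$mu - 2 * g2$s
    rate <- if (sum(mid) >= 3L)
      max(0, stats::median(y[mid] - gauss(x[mid], g1$a, g1$mu, g1$s) -
                             gauss(x[mid], g2$a, g2$mu, g2$s)))
    else 0
    sbg <- rate * (stats::pnorm(x, g1$mu, g1$s) - stats::pnorm(x, g2$mu, g2$s))
    g1 <- fit_peak(y - sbg - gauss(x, g2$a, g2$mu, g2$s), g1$a, g1$mu, g1$s)
    g2_bounds <- c(1.8, 2.2) * g1$mu
    g2 <- if (g2_present)
      fit_peak(y - sbg - gauss(x, g1$a, g1$mu, g1$s), g2$a, g2$mu, g2$s,
               g2_bounds[1L], g2_bounds[2L])
    else
      fit_peak(y - sbg - gauss(x, g1$a, g1$mu, g1$s), g2$a, 2 * g1$mu,
               g2$s, fix_mu = TRUE)
  }
  if (flag == "g1_absent" && g1$a < 0.02 * g2$a)
    g1$a <- 0                     # suppress the phantom G1 for pure-G2 input

  g1_pred <- gauss(x, g1$a, g1$mu, g1$s)
  g2_pred <- gauss(x, g2$a, g2$mu, g2$s)
  between <- x > g1$mu & x < g2$mu
  sbg <- rate * (stats::pnorm(x, g1$mu, g1$s) - stats::pnorm(x, g2$mu, g2$s))
  s_count <- max(0, sum((y - g1_pred - g2_pred)[between])) +
    sum(sbg[!between])
  g1_count <- sum(g1_pred)
  g2_count <- sum(g2_pred)
  tot <- g1_count + g2_count + s_count
  if (tot <= 0) stop("no detectable G1 mode")
  structure(list(
    g1 = g1_count / tot, s = s_count / tot, g2m = g2_count / tot,
    g1_mean = g1$mu, g2_mean = g2$mu,
    g1_cv = g1$s / g1$mu, g2_cv = g2$s / g2$mu,
    flag = flag), class = "cellcycle_fit")
}

#' @export
print.cellcycle_fit <- function(x, ...) {
  cat(sprintf("<cellcycle_fit> G1 %.1f%% | S %.1f%% | G2/M %.1f%% (G1 mean %.1f, G2 mean %.1f)\n",
              100 * x$g1, 100 * x$s, 100 * x$g2m, x$g1_mean, x$g2_mean))
  invisible(x)
}

#' Compare cell-cycle fractions between conditions over a time course
#'
#' Per release time and phase, the mean difference between the two
#' conditions with an unpaired two-sided Student's t-test across
#' replicates (descriptive output only when a condition has a single
#' replicate).
#'
#' @param fractions data frame with columns `condition`, `time`,
#'   `replicate`, `g1`, `s`, `g2m`.
#' @return data frame `time`, `phase`, `mean_diff` (condition 2 minus
#'   condition 1, conditions in sorted order), `p_value`.
#' @export
compare_timecourse <- function(fractions) {
  conds <- sort(unique(fractions$condition))
  if (length(conds) != 2L) stop("exactly 2 conditions required")
  out <- list()
  for (tm in sort(unique(fractions$time))) {
    for (ph in c("g1", "s", "g2m")) {
      a <- fractions[[ph]][fractions$condition == conds[1L] & fractions$time == tm]
      b <- fractions[[ph]][fractions$condition == conds[2L] & fractions$time == tm]
      md <- mean(b) - mean(a)
      p <- if (length(a) < 2L || length(b) < 2L) NA_real_ else {
        pooled <- sqrt(((length(a) - 1) * stats::var(a) +
                          (length(b) - 1) * stats::var(b)) /
                         (length(a) + length(b) - 2))
        if (pooled == 0) {
          if (md == 0) 1 else 0
        } else {
          stats::t.test(a, b, var.equal = TRUE)$p.value
        }
      }
      out[[length(out) + 1L]] <- data.frame(time = tm, phase = ph,
                                            mean_diff = md, p_value = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
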