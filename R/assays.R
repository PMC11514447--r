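#' @title Quantitative assay model fits
#' @name assays
#' @description
#' Fitters for the in-vitro and qPCR readouts: one-site binding (K_D from
#' fluorescence polarization), one-phase mRNA decay (half-life after
#' transcription shut-off), progress-curve unwinding velocity, qPCR
#' relative quantification (delta-delta-Ct) and RIP enrichment over an
#' IgG control.
NULL

rsq <- function(obs, fitted) {
  tss <- sum((obs - mean(obs))^2)
  rss <- sum((obs - fitted)^2)
  if (tss <= .Machine$double.eps) return(if (rss <= 1e-12) 1 else 0)
  1 - rss / tss
}

#' Fit a one-site binding model to a polarization curve
#'
#' `FP(c) = fp_free + (fp_bound - fp_free) c / (kd + c)`, least squares.
#' Initialization: `fp_free` = minimum reading, `fp_bound` = maximum
#' reading, `kd` = concentration nearest the half-maximal signal. The fit
#' never throws on failure: `converged = FALSE` when the optimizer fails
#' or when the fitted K_D exceeds 10x the largest concentration (flag
#' `weak_binding`).
#'
#' @param curve data frame with `concentration_nM` and `polarization_mP`
#'   (replicates pooled).
#' @return object of class `kd_fit`: `kd`, `fp_free`, `fp_bound`,
#'   `se_kd`, `r_squared`, `converged`, `flag`.
#' @export
fit_one_site <- function(curve) {
  conc <- curve$concentration_nM
  fp <- curve$polarization_mP
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations")
  f0 <- min(fp); f1 <- max(fp)
  half <- f0 + (f1 - f0) / 2
  kd0 <- conc[which.min(abs(fp - half))]
  if (kd0 <= 0) kd0 <- min(conc[conc > 0], na.rm = TRUE)
  fit <- tryCatch(
    stats::nls(fp ~ fp_free + (fp_bound - fp_free) * conc / (kd + conc),
               start = list(fp_free = f0, fp_bound = f1, kd = kd0),
               algorithm = "port",
               lower = c(fp_free = -Inf, fp_bound = -Inf, kd = 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(kd = NA_real_, fp_free = NA_real_,
                          fp_bound = NA_real_, se_kd = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          flag = "fit_failed"), class = "kd_fit"))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  weak <- co[["kd"]] > 10 * max(conc)
  structure(list(kd = co[["kd"]], fp_free = co[["fp_free"]],
                 fp_bound = co[["fp_bound"]], se_kd = se,
                 r_squared = rsq(fp, stats::fitted(fit)),
                 converged = !weak,
                 flag = if (weak) "weak_binding" else "none"),
            class = "kd_fit")
}

#' Compare fitted K_D values across conditions by one-way ANOVA
#'
#' @param fits named list of conditions, each a list of `kd_fit`
#'   replicates. Groups containing a non-converged fit are excluded with a
#'   warning.
#' @return list: `f_statistic`, `p_value`, `df`, `group_means`,
#'   `excluded_groups`.
#' @export
compare_kd <- function(fits) {
  ok <- vapply(fits, function(g) all(vapply(g, `[[`, TRUE, "converged")), TRUE)
  if (any(!ok))
    warning("excluding group(s) with non-converged fits: ",
            paste(names(fits)[!ok], collapse = ", "))
  fits <- fits[ok]
  if (length(fits) < 2L)
    stop("need at least 2 groups of converged fits")
  if (any(vapply(fits, length, 1L) < 2L))
    stop("need at least 2 replicates per group")
  kd <- unlist(lapply(fits, function(g) vapply(g, `[[`, 0, "kd")))
  grp <- factor(rep(names(fits), vapply(fits, length, 1L)))
  av <- stats::anova(stats::aov(kd ~ grp))
  list(f_statistic = av[["F value"]][1L], p_value = av[["Pr(>F)"]][1L],
       df = c(between = av[["Df"]][1L], within = av[["Df"]][2L]),
       group_means = tapply(kd, grp, mean),
       excluded_groups = names(ok)[!ok])
}

#' Fit a one-phase decay model
#'
#' `y(t) = (1 - plateau) exp(-k t) + plateau` with y(0) fixed at 1,
#' `k >= 0`, `plateau` in `[0, 1)`; replicates are pooled into a single
#' fit. Half-life `t_half = ln 2 / k`. Rates below `1e-3` per hour are
#' reported as stable (infinite half-life).
#'
#' By default (`plateau_mode = "auto"`) the plateau is kept only when an
#' extra-sum-of-squares F test (alpha = 0.05) prefers the free-plateau
#' model over complete decay to zero; with typical 4-half-life time
#' courses a free plateau is weakly identified and inflates the variance
#' of the rate estimate.
#'
#' @param series data frame with `time_h` and `relative_abundance`
#'   (replicates pooled; must include t = 0).
#' @param plateau_mode `"auto"` (F-test model choice), `"free"` or
#'   `"zero"`.
#' @return object of class `decay_fit`: `k`, `plateau`, `t_half`,
#'   `se_t_half`, `converged`, `flag`.
#' @export
fit_one_phase_decay <- function(series, plateau_mode = c("auto", "free", "zero")) {
  plateau_mode <- match.arg(plateau_mode)
  t <- series$time_h
  y <- series$relative_abundance
  if (!any(t == 0))
    stop("series must include the t = 0 point (normalization undefined)")
  if (length(unique(t)) < 4L) stop("need at least 4 timepoints")
  # starting values: for fixed k the model is linear in the plateau, so
  # profile the residual sum of squares over a log-spaced k grid
  k_grid <- exp(seq(log(1e-4), log(20), length.out = 80L))
  prof <- vapply(k_grid, function(k) {
    e <- exp(-k * t)
    w <- 1 - e
    p <- if (sum(w^2) > 0) sum((y - e) * w) / sum(w^2) else 0
    p <- min(max(p, 0), 1 - 1e-9)
    sum((y - ((1 - p) * e + p))^2)
  }, 0)
  k0 <- k_grid[which.min(prof)]
  e0 <- exp(-k0 * t)
  p0 <- min(max(sum((y - e0) * (1 - e0)) / max(sum((1 - e0)^2), 1e-12), 0),
            1 - 1e-9)
  # port may flag "false convergence" on nearly flat series; the fit is
  # still usable and the stable flag reports the regime, so the optimizer
  # chatter is suppressed
  fit_free <- tryCatch(suppressWarnings(
    stats::nls(y ~ (1 - plateau) * exp(-k * t) + plateau,
               start = list(k = k0, plateau = p0), algorithm = "port",
               lower = c(k = 0, plateau = 0),
               upper = c(k = Inf, plateau = 1 - 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  fit_zero <- tryCatch(suppressWarnings(
    stats::nls(y ~ exp(-k * t), start = list(k = max(k0, 1e-4)),
               algorithm = "port", lower = c(k = 0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  fit <- switch(plateau_mode,
    free = fit_free,
    zero = fit_zero,
    auto = {
      if (is.null(fit_free)) fit_zero
      else if (is.null(fit_zero)) fit_free
      else {
        rss1 <- sum(stats::resid(fit_free)^2)
        rss0 <- sum(stats::resid(fit_zero)^2)
        df1 <- length(y) - 2L
        f_stat <- if (rss1 <= 0) Inf else (rss0 - rss1) / (rss1 / df1)
        p_f <- if (rss0 <= rss1) 1 else
          stats::pf(f_stat, 1L, df1, lower.tail = FALSE)
        if (!is.na(p_f) && p_f < 0.05) fit_free else fit_zero
      }
    })
  if (is.null(fit))
    return(structure(list(k = NA_real_, plateau = NA_real_,
                          t_half = NA_real_, se_t_half = NA_real_,
                          converged = FALSE, flag = "fit_failed"),
                     class = "decay_fit"))
  co <- stats::coef(fit)
  k <- co[["k"]]
  se_k <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
  stable <- k < 1e-3
  structure(list(
    k = k, plateau = if ("plateau" %in% names(co)) co[["plateau"]] else 0,
    t_half = if (stable) Inf else log(2) / k,
    se_t_half = if (stable) NA_real_ else se_k * log(2) / k^2,
    converged = TRUE,
    flag = if (stable) "stable" else "none"), class = "decay_fit")
}

#' qPCR relative quantification (delta-delta-Ct)
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; the relative level is
#' `efficiency^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_table data frame with columns `sample`, `gene`, `ct`.
#' @param reference reference gene name.
#' @param calibrator calibrator sample name (typically the 0-h sample).
#' @param efficiency amplification efficiency (default 2).
#' @return data frame `sample`, `target`, `delta_ct`, `rel_level`.
#' @export
relative_quantification <- function(ct_table, reference, calibrator,
                                    efficiency = 2) {
  samples <- unique(ct_table$sample)
  ref_ct <- vapply(samples, function(s) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == reference]
    if (length(v) == 0L || anyNA(v))
      stop("missing reference Ct for sample ", s)
    mean(v)
  }, 0)
  names(ref_ct) <- samples
  if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
  targets <- setdiff(unique(ct_table$gene), reference)
  out <- list()
  for (tg in targets) {
    dct <- vapply(samples, function(s) {
      v <- ct_table$ct[ct_table$sample == s & ct_table$gene == tg]
      if (length(v) == 0L) return(NA_real_)
      mean(v) - ref_ct[[s]]
    }, 0)
    rel <- efficiency^-(dct - dct[[calibrator]])
    out[[tg]] <- data.frame(sample = samples, target = tg, delta_ct = dct,
                            rel_level = rel, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' RIP-qPCR enrichment over an IgG control
#'
#' Ct values of the immunoprecipitation are normalized to input and
#' expressed relative to the IgG control:
#' `fold = efficiency^-((ct_ip - ct_input) - (ct_igg - ct_igg_input))`.
#'
#' @param ct_ip,ct_input,ct_igg,ct_igg_input numeric Ct vectors (one entry
#'   per target); no missing values allowed.
#' @param efficiency amplification efficiency (default 2).
#' @return numeric vector of fold enrichments.
#' @export
rip_enrichment <- function(ct_ip, ct_input, ct_igg, ct_igg_input,
                           efficiency = 2) {
  if (anyNA(c(ct_ip, ct_input, ct_igg, ct_igg_input)))
    stop("missing Ct values")
  efficiency^-((ct_ip - ct_input) - (ct_igg - ct_igg_input))
}

# slope and r-squared of y ~ x over index window [i, j] from cumulative sums
.window_lm <- function(cum, i, j) {
  n <- j - i + 1
  sx <- cum$x[j + 1L] - cum$x[i]
  sy <- cum$y[j + 1L] - cum$y[i]
  sxx <- cum$xx[j + 1L] - cum$xx[i]
  syy <- cum$yy[j + 1L] - cum$yy[i]
  sxy <- cum$xy[j + 1L] - cum$xy[i]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- if (vx > 0) cxy / vx else 0
  r2 <- if (vy <= max(1e-12, 1e-12 * abs(syy))) 1 else
    if (vx > 0) min(1, cxy^2 / (vx * vy)) else 0
  c(slope = slope, r2 = r2)
}

#' Unwinding velocity from a progress curve
#'
#' Fits a linear model to the linear part of the progress curve and
#' reports the slope as the velocity. If the whole curve is linear
#' (r-squared >= `r2_min`) the full range is used; otherwise the longest
#' window of at least `min_points` observations, starting at or after the
#' signal first exceeds baseline + 3 baseline-sd, with window r-squared
#' >= `r2_min` is selected (ties: earliest). If no window qualifies the
#' best-r-squared minimal window is used and flagged.
#'
#' @param progress data frame with `time_min` and `signal`.
#' @param min_points minimum window size.
#' @param r2_min linearity requirement.
#' @return object of class `velocity_fit`: `velocity`, `window` (time
#'   span), `r_squared`, `flag`.
#' @export
unwinding_velocity <- function(progress, min_points = 4L, r2_min = 0.98) {
  t <- progress$time_min
  y <- progress$signal
  n <- length(t)
  if (n < min_points) stop("need at least ", min_points, " observations")
  vfit <- function(velocity, window, r2, flag)
    structure(list(velocity = velocity, window = window, r_squared = r2,
                   flag = flag), class = "velocity_fit")
  rng <- diff(range(y))
  if (rng <= 1e-12 * max(1, abs(mean(y))))
    return(vfit(0, range(t), NA_real_, "flat"))
  if (all(diff(y) <= 0))
    return(vfit(0, range(t), NA_real_, "decreasing"))
  full <- stats::lm(y ~ t)
  if (rsq(y, stats::fitted(full)) >= r2_min)
    return(vfit(stats::coef(full)[[2L]], range(t),
                rsq(y, stats::fitted(full)), "none"))
  base <- mean(y[1:3])
  bsd <- max(stats::sd(y[1:3]), 1e-9 * rng)
  start_idx <- which(y > base + 3 * bsd)[1L]
  if (is.na(start_idx))
    return(vfit(0, range(t), NA_real_, "flat"))
  cum <- list(x = c(0, cumsum(t)), y = c(0, cumsum(y)),
              xx = c(0, cumsum(t^2)), yy = c(0, cumsum(y^2)),
              xy = c(0, cumsum(t * y)))
  best <- NULL; best_len <- 0L
  fallback <- NULL; fallback_r2 <- -Inf
  for (i in start_idx:(n - min_points + 1L)) {
    for (j in (i + min_points - 1L):n) {
      w <- .window_lm(cum, i, j)
      len <- j - i + 1L
      if (w[["r2"]] >= r2_min && len > best_len) {
        best <- c(i, j, w); best_len <- len
      }
      if (len == min_points && w[["r2"]] > fallback_r2) {
        fallback <- c(i, j, w); fallback_r2 <- w[["r2"]]
      }
    }
  }
  if (!is.null(best))
    return(vfit(best[[3L]], t[best[1:2]], best[[4L]], "none"))
  vfit(fallback[[3L]], t[fallback[1:2]], fallback[[4L]], "no_linear_region")
}
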