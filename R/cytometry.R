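# Single-cell fluorescence preprocessing: cell-size correction by local
# regression on forward scatter, correlation between the two reporter
# channels, and the sorted-pool heritability t-test.

#' Read a flow-cytometry event table
#'
#' Tab-separated table with one row per cell and columns `FSC`, `SSC`,
#' `GFP`, `mCherry` (arbitrary fluorescence units).
#'
#' @param path file path.
#' @return data frame with the four channels.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t")
  check_columns(ev, c("FSC", "SSC", "GFP", "mCherry"), "event table")
  ev
}

#' Cell-size correction of a fluorescence channel
#'
#' Residuals of a loess regression of the channel on forward scatter
#' (FSC), which removes the dependence of fluorescence on cell size
#' without assuming a parametric relationship.  Events outside the
#' given FSC/SSC percentile bands are treated as outliers and excluded
#' (their residuals are `NA`).
#'
#' @param events event table with at least `FSC` and the channel column
#'   (and `SSC` if `ssc_quantiles` filtering is active).
#' @param channel `"GFP"` or `"mCherry"` (any numeric column name works).
#' @param span loess span (default 0.3, local-linear).
#' @param log if `TRUE`, fluorescence is natural-log transformed before
#'   the regression.
#' @param fsc_quantiles,ssc_quantiles retained percentile bands; set to
#'   `NULL` to disable the outlier pre-filter.
#' @return numeric vector of residuals aligned with `events` (`NA` for
#'   filtered events); mean residual is ~0.  With constant FSC the
#'   channel is mean-centered instead, with a warning.
#' @export
size_correct <- function(events, channel = c("GFP", "mCherry"),
                         span = 0.3, log = FALSE,
                         fsc_quantiles = c(0.01, 0.99),
                         ssc_quantiles = c(0.01, 0.99)) {
  channel <- if (is.character(channel) && length(channel) > 1) {
    match.arg(channel)
  } else {
    channel
  }
  check_columns(events, c("FSC", channel), "events")
  if (nrow(events) < 30) stop_input("need at least 30 events")
  keep <- rep(TRUE, nrow(events))
  if (!is.null(fsc_quantiles)) {
    b <- stats::quantile(events$FSC, fsc_quantiles, names = FALSE)
    keep <- keep & events$FSC >= b[1] & events$FSC <= b[2]
  }
  if (!is.null(ssc_quantiles) && "SSC" %in% names(events)) {
    b <- stats::quantile(events$SSC, ssc_quantiles, names = FALSE)
    keep <- keep & events$SSC >= b[1] & events$SSC <= b[2]
  }
  y <- events[[channel]][keep]
  x <- events$FSC[keep]
  if (log) y <- base::log(y)
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    stop_input("non-finite values in ", channel, " or FSC")
  }
  res <- rep(NA_real_, nrow(events))
  if (stats::sd(x) == 0) {
    warning("constant FSC; falling back to mean-centering")
    res[keep] <- y - mean(y)
    return(res)
  }
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian")
  res[keep] <- stats::residuals(fit)
  res
}

#' Correlation between the two size-corrected reporter channels
#'
#' Pearson correlation of size-corrected GFP (protein reporter) and
#' size-corrected mCherry (mRNA reporter) across cells.  Genes whose
#' expression variation is dominated by concordant genetic effects show
#' higher correlations than genes dominated by channel-specific
#' effects.
#'
#' @param events event table.
#' @param span,log,fsc_quantiles,ssc_quantiles passed to
#'   [size_correct()].
#' @return the correlation coefficient; `NA` with a warning when either
#'   corrected channel has zero variance.
#' @export
channel_correlation <- function(events, span = 0.3, log = FALSE,
                                fsc_quantiles = c(0.01, 0.99),
                                ssc_quantiles = c(0.01, 0.99)) {
  g <- size_correct(events, "GFP", span, log, fsc_quantiles, ssc_quantiles)
  m <- size_correct(events, "mCherry", span, log, fsc_quantiles,
                    ssc_quantiles)
  ok <- !is.na(g) & !is.na(m)
  near_constant <- function(v, raw) {
    stats::sd(v) <= 1e-10 * (abs(mean(raw)) + 1)
  }
  if (sum(ok) < 3 || near_constant(g[ok], events$GFP) ||
      near_constant(m[ok], events$mCherry)) {
    warning("zero variance in a corrected channel; correlation undefined")
    return(NA_real_)
  }
  stats::cor(g[ok], m[ok])
}

#' Heritability t-test between regrown high and low pools
#'
#' Welch two-sample t-test of the size-corrected channel between cells
#' regrown from the high- and low-fluorescence sorted pools.  The size
#' regression is fit on the two populations combined, so that the
#' between-pool fluorescence difference is preserved in the residuals.
#' A significant difference after regrowth demonstrates that the sorted
#' fluorescence difference is heritable.
#'
#' @param high,low event tables of the two regrown populations.
#' @param channel `"GFP"` or `"mCherry"`.
#' @param span,log passed to [size_correct()]; combined tables with
#'   fewer than 30 events skip the size correction (with a warning).
#' @return list with `t` (statistic), `p_value` (two-sided), `df`,
#'   `mean_high`, `mean_low`.  Degenerate variance yields `NA` values
#'   with a warning.
#' @export
heritability_ttest <- function(high, low, channel = c("GFP", "mCherry"),
                               span = 0.3, log = FALSE) {
  channel <- match.arg(channel)
  if (nrow(high) < 2 || nrow(low) < 2) {
    stop_input("both populations need at least 2 events")
  }
  cols <- intersect(names(high), names(low))
  combined <- rbind(high[, cols, drop = FALSE], low[, cols, drop = FALSE])
  grp <- rep(c("high", "low"), c(nrow(high), nrow(low)))
  if (nrow(combined) >= 30) {
    res <- size_correct(combined, channel, span, log,
                        fsc_quantiles = NULL, ssc_quantiles = NULL)
  } else {
    warning("fewer than 30 events; using uncorrected fluorescence")
    res <- combined[[channel]]
    if (log) res <- base::log(res)
  }
  vh <- res[grp == "high" & !is.na(res)]
  vl <- res[grp == "low" & !is.na(res)]
  scale <- stats::sd(combined[[channel]]) + abs(mean(combined[[channel]]))
  if (stats::sd(c(vh, vl)) <= 1e-10 * (scale + 1)) {
    warning("degenerate variance; t-test undefined")
    return(list(t = NA_real_, p_value = NA_real_, df = NA_real_,
                mean_high = mean(vh), mean_low = mean(vl)))
  }
  tt <- stats::t.test(vh, vl, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_high = mean(vh), mean_low = mean(vl))
}
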