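#' Bland-Altman agreement of two paired sessions
#'
#' Bias is the mean paired difference `mean(t2 - t1)` (session 2 minus
#' session 1); the 95% limits of agreement are
#' `bias +/- 1.96 * SD(differences)` with the sample (n - 1) SD.
#'
#' @param t1,t2 Equal-length numeric vectors of paired measurements
#'   (>= 2 complete pairs).
#' @return A list: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(t1, t2) {
  d <- complete_diffs(t1, t2)
  sdd <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       sd_diff = sdd, n = length(d))
}

complete_diffs <- function(t1, t2) {
  if (length(t1) != length(t2)) stop("paired series must have equal length")
  ok <- is.finite(t1) & is.finite(t2)
  if (sum(ok) < 2) stop("need >= 2 complete pairs")
  t2[ok] - t1[ok]
}

#' Within-subject coefficient of variation (percent)
#'
#' The ratio of the standard deviation of the paired session differences to
#' the mean, in percent:
#' `100 * SD(t2 - t1) / mean(c(t1, t2))`. The denominator is the grand mean
#' over both sessions (`denominator = "grand"`, the default) or the
#' session-1 mean (`"baseline"`). `classical = TRUE` divides the difference
#' SD by sqrt(2), giving the classical within-subject SD variant.
#'
#' @param t1,t2 Paired measurements, >= 2 complete pairs.
#' @param denominator `"grand"` or `"baseline"`.
#' @param classical Use the within-subject SD (difference SD / sqrt(2))
#'   in the numerator.
#' @return wsCV in percent.
#' @export
wscv <- function(t1, t2, denominator = c("grand", "baseline"),
                 classical = FALSE) {
  denominator <- match.arg(denominator)
  d <- complete_diffs(t1, t2)
  ok <- is.finite(t1) & is.finite(t2)
  mu <- if (denominator == "grand") mean(c(t1[ok], t2[ok])) else mean(t1[ok])
  if (mu == 0) stop("zero mean: wsCV undefined")
  num <- stats::sd(d)
  if (classical) num <- num / sqrt(2)
  100 * num / mu
}

#' Minimal detectable difference
#'
#' `1.96 * SD(t2 - t1)` with the sample SD: the smallest between-session
#' change distinguishable from test-retest variability at the 95% level.
#' Identical to half the width of the Bland-Altman limits of agreement.
#'
#' @param t1,t2 Paired measurements, >= 2 complete pairs.
#' @return MDD in the units of the measurements.
#' @export
mdd <- function(t1, t2) 1.96 * stats::sd(complete_diffs(t1, t2))

#' Mean and SD of per-muscle wsCV values
#'
#' Aggregates per-muscle wsCV percentages into the per-parameter summary
#' (mean over muscles, sample SD), reported to one decimal.
#'
#' @param wscv_values Numeric vector of per-muscle wsCV percentages
#'   (typically 14 values: 7 muscles x 2 legs).
#' @return A list: `mean`, `sd` (unrounded) and `mean_1dp`, `sd_1dp`.
#' @export
summarize_wscv <- function(wscv_values) {
  if (any(!is.finite(wscv_values))) stop("wsCV values must be finite")
  m <- mean(wscv_values)
  s <- stats::sd(wscv_values)
  list(mean = m, sd = s, mean_1dp = round(m, 1), sd_1dp = round(s, 1))
}

#' Paired comparison of wsCV between two processing modes
#'
#' Two-sided paired t-test of per-muscle wsCV values between two signal
#' models (e.g. perfusion-corrected vs standard), paired by muscle.
#'
#' @param wscv_a,wscv_b Per-muscle wsCV vectors, paired by position.
#' @return A list: `p_value` (NA when degenerate), `t`, `df`, `degenerate`
#'   (TRUE when the paired differences have zero variance).
#' @export
compare_wscv_modes <- function(wscv_a, wscv_b) {
  if (length(wscv_a) != length(wscv_b) || length(wscv_a) < 2)
    stop("need >= 2 muscles, paired")
  d <- wscv_a - wscv_b
  if (stats::sd(d) == 0)
    return(list(p_value = NA_real_, t = NA_real_,
                df = length(d) - 1L, degenerate = TRUE))
  tt <- stats::t.test(wscv_a, wscv_b, paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Per-muscle repeatability table
#'
#' For every muscle x DTI parameter x mode present in a cohort record table,
#' pairs the two sessions across subjects (complete, pair-included records
#' only) and computes bias, limits of agreement, wsCV and MDD.
#'
#' @param records Record table from [muscle_table()] /
#'   [apply_snr_exclusion()].
#' @param parameters DTI parameters to summarize (default all five).
#' @param min_pairs Minimum complete pairs required per cell (default 2).
#' @return Data.frame with columns code, mode, parameter, n_pairs, bias,
#'   loa_low, loa_high, wscv, mdd.
#' @export
repeatability_table <- function(records,
                                parameters = c("l1", "l2", "l3", "md", "fa"),
                                min_pairs = 2L) {
  records <- records[records$pair_included, ]
  out <- list()
  for (mode in unique(records$mode)) for (code in unique(records$code)) {
    r <- records[records$mode == mode & records$code == code, ]
    s1 <- r[r$session == 1, ]
    s2 <- r[r$session == 2, ]
    s2 <- s2[match(s1$subject, s2$subject), ]
    for (p in parameters) {
      t1 <- s1[[p]]; t2 <- s2[[p]]
      ok <- is.finite(t1) & is.finite(t2)
      if (sum(ok) < min_pairs) next
      ba <- bland_altman(t1[ok], t2[ok])
      out[[length(out) + 1L]] <- data.frame(
        code = code, mode = mode, parameter = p, n_pairs = ba$n,
        bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
        wscv = wscv(t1[ok], t2[ok]), mdd = mdd(t1[ok], t2[ok]))
    }
  }
  do.call(rbind, out)
}

#' Per-parameter wsCV summary across muscles, with mode comparison
#'
#' Builds the per-parameter summary table: mean and SD of the per-muscle
#' wsCV for each mode, plus the paired t-test p-value between the two modes
#' when exactly two are present.
#'
#' @param rep_table Output of [repeatability_table()].
#' @return Data.frame with parameter, mode, wscv_mean, wscv_sd, and (when
#'   two modes are present) `p_vs_other`.
#' @export
wscv_summary <- function(rep_table) {
  modes <- unique(rep_table$mode)
  out <- list()
  for (p in unique(rep_table$parameter)) {
    sub <- rep_table[rep_table$parameter == p, ]
    pval <- NA_real_
    if (length(modes) == 2) {
      a <- sub[sub$mode == modes[1], c("code", "wscv")]
      b <- sub[sub$mode == modes[2], c("code", "wscv")]
      common <- intersect(a$code, b$code)
      if (length(common) >= 2)
        pval <- compare_wscv_modes(a$wscv[match(common, a$code)],
                                   b$wscv[match(common, b$code)])$p_value
    }
    for (m in modes) {
      v <- sub$wscv[sub$mode == m]
      sm <- summarize_wscv(v)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, mode = m, n_muscles = length(v),
        wscv_mean = sm$mean, wscv_sd = sm$sd, p_vs_other = pval)
    }
  }
  do.call(rbind, out)
}

#' Bland-Altman plot of a repeatability table
#'
#' One panel per DTI parameter; per-muscle session means against paired
#' differences, with the solid mean-difference line and dashed 95% limits
#' of agreement.
#'
#' @param records Record table (pair-included rows are used).
#' @param mode Which fitted mode to plot.
#' @param parameters Parameters to facet over.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(records, mode = "ivim",
                              parameters = c("l1", "l2", "l3", "md", "fa")) {
  records <- records[records$pair_included & records$mode == mode, ]
  pieces <- list()
  for (p in parameters) {
    s1 <- records[records$session == 1, ]
    s2 <- records[records$session == 2, ]
    s2 <- s2[match(interaction(s1$subject, s1$code),
                   interaction(s2$subject, s2$code)), ]
    pieces[[p]] <- data.frame(parameter = p, code = s1$code,
                              mean = (s1[[p]] + s2[[p]]) / 2,
                              diff = s2[[p]] - s1[[p]])
  }
  df <- do.call(rbind, pieces)
  df <- df[is.finite(df$mean) & is.finite(df$diff), ]
  lims <- do.call(rbind, lapply(split(df, df$parameter), function(g) {
    ba <- bland_altman(rep(0, nrow(g)), g$diff)
    data.frame(parameter = g$parameter[1], bias = ba$bias,
               lo = ba$loa_low, hi = ba$loa_high)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff, colour = code)) +
    ggplot2::geom_point(size = 1.4, alpha = 0.8) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = bias)) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = lo),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = hi),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Session mean", y = "Session 2 - session 1",
                  colour = "Muscle") +
    ggplot2::theme_minimal()
}
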