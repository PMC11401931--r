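#' Trial periods of interest, shifted for hemodynamic delay
#'
#' Default analysis windows on the trial timecourse, already including the
#' ~6 s hemodynamic delay: mid-delay 11.3-15.1 s and retrieval 20.7-24.5 s
#' post-onset.
#'
#' @param delay,retrieval numeric `c(start, end)` in seconds post-onset.
#' @return data.frame with columns `period`, `start_s`, `end_s`.
#' @export
analysis_periods <- function(delay = c(11.3, 15.1),
                             retrieval = c(20.7, 24.5)) {
  stopifnot(delay[1] < delay[2], retrieval[1] < retrieval[2])
  data.frame(period = c("delay", "retrieval"),
             start_s = c(delay[1], retrieval[1]),
             end_s = c(delay[2], retrieval[2]),
             stringsAsFactors = FALSE)
}

#' Condition contrast of trial timecourses
#'
#' Pointwise difference `a - b` of two conditions' timecourses per layer,
#' e.g. high minus low load (load effect) or response minus abstain (motor
#' effect).
#'
#' @param tc a `trial_timecourse` from [layer_timecourse()].
#' @param a,b condition labels.
#' @return data.frame with columns `layer`, `knot_time`, `effect`.
#' @export
condition_contrast <- function(tc, a, b) {
  ta <- tc[tc$condition == a, ]
  tb <- tc[tc$condition == b, ]
  if (!nrow(ta) || !nrow(tb)) stop_ld("condition missing from timecourse")
  key_a <- paste(ta$layer, ta$knot_time)
  key_b <- paste(tb$layer, tb$knot_time)
  if (!identical(sort(key_a), sort(key_b))) {
    stop_ld("conditions '", a, "' and '", b, "' are on mismatched grids")
  }
  tb <- tb[match(key_a, key_b), ]
  data.frame(layer = ta$layer, knot_time = ta$knot_time,
             effect = ta$value - tb$value, stringsAsFactors = FALSE)
}

#' Average an effect timecourse over a trial period
#'
#' Unweighted mean of the knots whose times fall inside the closed interval
#' `[start_s, end_s]` (so the default 11.3-15.1 s delay window on a 2 s knot
#' grid averages the 12 and 14 s knots).
#'
#' @param effect data.frame from [condition_contrast()] (columns `layer`,
#'   `knot_time`, `effect`).
#' @param period one row of [analysis_periods()] or a list with `start_s`,
#'   `end_s`.
#' @return data.frame with one row per layer: `layer`, `value`, `n_knots`.
#' @export
period_average <- function(effect, period) {
  sel <- effect$knot_time >= period$start_s & effect$knot_time <= period$end_s
  if (!any(sel)) {
    stop_ld(sprintf("no knots inside [%g, %g] s", period$start_s,
                    period$end_s))
  }
  agg <- stats::aggregate(effect$effect[sel],
                          by = list(layer = effect$layer[sel]), FUN = mean)
  data.frame(layer = agg$layer, value = agg$x,
             n_knots = as.vector(table(effect$layer[sel])[agg$layer]),
             stringsAsFactors = FALSE)
}

#' Two-tailed paired t-test with effect size
#'
#' Classical paired t on the within-subject differences `x - y`, with the
#' 95% confidence interval on the raw difference scale and Cohen's d for the
#' paired design, `d = mean(diff) / sd(diff) = t / sqrt(n)`.
#'
#' @param x,y per-subject values, equal length n >= 2.
#' @return list of class `test_result`: `t`, `df`, `p` (two-tailed), `ci95`,
#'   `d`, `mean_diff`, `n`. Zero-variance differences with nonzero mean are
#'   flagged degenerate (`p = 0`, `d = Inf` with the sign of the mean).
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop_ld("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop_ld("need n >= 2 pairs")
  d_i <- x - y
  if (any(!is.finite(d_i))) stop_ld("differences must be finite")
  m <- mean(d_i)
  s <- stats::sd(d_i)
  if (s == 0) {
    if (m == 0) {
      res <- list(t = 0, df = n - 1L, p = 1, ci95 = c(0, 0), d = 0,
                  mean_diff = 0, n = n, degenerate = FALSE)
    } else {
      res <- list(t = sign(m) * Inf, df = n - 1L, p = 0, ci95 = c(m, m),
                  d = sign(m) * Inf, mean_diff = m, n = n, degenerate = TRUE)
    }
    class(res) <- "test_result"
    return(res)
  }
  se <- s / sqrt(n)
  tval <- m / se
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  res <- list(t = tval, df = df, p = p, ci95 = c(m - crit * se, m + crit * se),
              d = m / s, mean_diff = m, n = n, degenerate = FALSE)
  class(res) <- "test_result"
  res
}

#' Cohen's d for a paired design from its t statistic
#'
#' `d = t / sqrt(n)`; e.g. t(8) = 3.58 with n = 9 gives d = 1.19.
#'
#' @param t paired t statistic.
#' @param n number of subjects (>= 2).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) {
  n <- check_count(n, "n", lower = 2L)
  t / sqrt(n)
}

#' Layer-wise period effects for one subject
#'
#' Convenience wrapper: contrast two conditions, average over the analysis
#' periods, and return one row per layer x period.
#'
#' @param tc `trial_timecourse` for one subject.
#' @param a,b conditions to contrast (`a - b`).
#' @param periods data.frame from [analysis_periods()].
#' @return data.frame `layer`, `period`, `value`.
#' @export
period_effects <- function(tc, a, b, periods = analysis_periods()) {
  eff <- condition_contrast(tc, a, b)
  do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
    pa <- period_average(eff, periods[i, ])
    data.frame(layer = pa$layer, period = periods$period[i], value = pa$value,
               stringsAsFactors = FALSE)
  }))
}
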