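#' Detect action potentials in a voltage trace
#'
#' An event is one contiguous suprathreshold (>= 0 mV) excursion.  It is
#' accepted as an action potential only if the maximal first-difference
#' derivative of its rising slope (from the start of the rise to the peak)
#' exceeds 10 mV/ms; slow depolarisations that drift across 0 mV are
#' rejected.  The event time is the voltage threshold: the first sample at
#' which dV/dt exceeds 10 mV/ms on the rise leading into the 0 mV crossing.
#'
#' @param trace a [voltage_trace()].
#' @return Object of class `spike_train`: data.frame-like list with `times`
#'   (ms), `peaks` (mV), `max_dvdt` (mV/ms) and `meta` (warnings such as a
#'   too-coarse sampling interval).
#' @examples
#' g <- gen_spiky_voltage(c(50, 120), dt = 0.1, duration = 200)
#' detect_aps(g$trace)$times
#' @export
detect_aps <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"), trace$dt > 0)
  V <- trace$V; dt <- trace$dt
  meta <- list()
  if (dt > 1) {
    meta$warning <- "sampling interval > 1 ms: derivative criterion unreliable"
    warning(meta$warning)
  }
  d <- diff(V) / dt
  above <- V >= 0
  times <- numeric(0); peaks <- numeric(0); maxd_out <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      m <- a - 1 + which.max(V[a:b])
      # rise start: previous local minimum before the crossing
      i <- a
      while (i > 1 && V[i - 1] < V[i]) i <- i - 1
      rise <- i:max(i, m - 1)
      maxd <- max(d[rise])
      if (maxd > 10) {
        th <- rise[which(d[rise] > 10)[1]]
        times <- c(times, (th - 1) * dt)
        peaks <- c(peaks, V[m])
        maxd_out <- c(maxd_out, maxd)
      }
    }
  }
  structure(list(times = times, peaks = peaks, max_dvdt = maxd_out,
                 meta = meta), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d accepted APs", length(x$times)))
  if (length(x$times))
    cat(sprintf(" (first at %.2f ms, max dV/dt %.1f-%.1f mV/ms)",
                x$times[1], min(x$max_dvdt), max(x$max_dvdt)))
  cat("\n")
  invisible(x)
}

#' Per-burst spike metrics for one playback
#'
#' Assigns each action potential (by its threshold time) to the burst
#' window containing it and computes, per window: the AP count, the latency
#' of the first AP from the window's excitatory-conductance onset, and the
#' burst duration (first to last AP; 0 for a single AP, `NA` when no AP).
#' APs falling outside every window are counted separately and reported as
#' an attribute.
#'
#' @param spikes a `spike_train` (or a numeric vector of AP times, ms).
#' @param windows data.frame with `start`, `end` (ms), sorted,
#'   non-overlapping; optional `onset` column (defaults to `start`).
#' @param onsets optional numeric vector of per-window conductance onset
#'   times overriding `windows$onset`.
#' @return data.frame with one row per window: `window`, `n_ap`,
#'   `latency_ms`, `duration_ms`; attribute `n_outside`.
#' @export
burst_metrics <- function(spikes, windows, onsets = NULL) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  stopifnot(is.data.frame(windows), nrow(windows) >= 1)
  if (is.unsorted(windows$start)) stop("windows must be sorted")
  if (nrow(windows) > 1 &&
      any(windows$start[-1] < windows$end[-nrow(windows)]))
    stop("overlapping burst windows")
  if (is.null(onsets))
    onsets <- if (!is.null(windows$onset)) windows$onset else windows$start
  stopifnot(length(onsets) == nrow(windows))

  out <- lapply(seq_len(nrow(windows)), function(i) {
    s <- times[times >= windows$start[i] & times <= windows$end[i]]
    data.frame(window = i, n_ap = length(s),
               latency_ms = if (length(s)) s[1] - onsets[i] else NA_real_,
               duration_ms = if (length(s)) max(s) - min(s) else NA_real_)
  })
  res <- do.call(rbind, out)
  in_any <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows)))
    in_any <- in_any | (times >= windows$start[i] & times <= windows$end[i])
  attr(res, "n_outside") <- sum(!in_any)
  res
}

#' Across-repeat latency, jitter and ordinal AP reliability
#'
#' Given the per-burst metrics of repeated identical-template playbacks,
#' computes for every window the mean first-AP latency, the latency jitter
#' (coefficient of variation, SD/mean, across repeats) and the ordinal AP
#' reliability: `reliability_i` is the fraction of repeats in which at
#' least `i` APs occurred in the window, so `reliability_1 >=
#' reliability_2 >= ...` by construction.
#'
#' @param repeats a list of [burst_metrics()] data.frames, one per repeat
#'   (all over the same windows).
#' @param max_ordinal highest AP ordinal reported.
#' @return List with `latency` (per-window data.frame: `latency_mean_ms`,
#'   `latency_cv`, `n_with_ap`) and `reliability` (long data.frame:
#'   `window`, `ordinal`, `reliability`).
#' @export
repeat_metrics <- function(repeats, max_ordinal = 3) {
  stopifnot(length(repeats) >= 1)
  n_win <- nrow(repeats[[1]])
  counts <- vapply(repeats, function(r) r$n_ap, numeric(n_win))
  lats <- vapply(repeats, function(r) r$latency_ms, numeric(n_win))
  if (n_win == 1) { counts <- matrix(counts, 1); lats <- matrix(lats, 1) }

  latency <- do.call(rbind, lapply(seq_len(n_win), function(i) {
    l <- lats[i, ]; l <- l[!is.na(l)]
    m <- if (length(l)) mean(l) else NA_real_
    cv <- if (length(l) >= 2 && isTRUE(m != 0)) stats::sd(l) / m else NA_real_
    data.frame(window = i, latency_mean_ms = m, latency_cv = cv,
               n_with_ap = length(l),
               cv_flagged = length(l) >= 2 && isTRUE(m == 0))
  }))
  reliability <- do.call(rbind, lapply(seq_len(n_win), function(i) {
    data.frame(window = i, ordinal = seq_len(max_ordinal),
               reliability = vapply(seq_len(max_ordinal), function(j)
                 mean(counts[i, ] >= j), numeric(1)))
  }))
  list(latency = latency, reliability = reliability)
}

#' Interburst interval statistics
#'
#' Intervals between consecutive burst event times; the coefficient of
#' variation is the sample SD (n - 1 denominator) divided by the mean.
#'
#' @param times burst event times (ms or s; units propagate).
#' @return List with `intervals`, `mean`, `cv` (NA with fewer than 3
#'   events) and `count`.
#' @examples
#' interburst_stats(c(0, 1, 3, 6))$cv  # intervals 1,2,3 -> 0.5
#' @export
interburst_stats <- function(times) {
  times <- sort(times)
  if (length(times) < 2)
    return(list(intervals = numeric(0), mean = NA_real_, cv = NA_real_,
                count = length(times)))
  iv <- diff(times)
  list(intervals = iv, mean = mean(iv),
       cv = if (length(times) >= 3) stats::sd(iv) / mean(iv) else NA_real_,
       count = length(times))
}

#' Paired condition contrast
#'
#' Standard paired two-sample comparison for control-versus-drug metric
#' vectors: paired t-test, Wilcoxon matched-pairs signed-rank test, or sign
#' test (exact binomial on the sign of the non-zero differences).  A
#' Shapiro-Wilk normality screen on the differences is recorded alongside.
#'
#' @param x,y paired metric vectors (same length, `x` = control).
#' @param test `"paired-t"`, `"wilcoxon"` or `"sign"`.
#' @param alternative passed to the underlying test.
#' @return One-row data.frame: `test`, `n`, `effect` (mean of `y - x`),
#'   `p_value`, `shapiro_p`.
#' @export
compare_paired <- function(x, y, test = c("paired-t", "wilcoxon", "sign"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  d <- y - x
  shapiro_p <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value
               else NA_real_
  if (all(d == 0)) {
    p <- 1
  } else {
    p <- switch(test,
      "paired-t" = stats::t.test(y, x, paired = TRUE,
                                 alternative = alternative)$p.value,
      "wilcoxon" = suppressWarnings(
        stats::wilcox.test(y, x, paired = TRUE,
                           alternative = alternative)$p.value),
      "sign" = {
        nz <- d[d != 0]
        stats::binom.test(sum(nz > 0), length(nz), 0.5,
                          alternative = alternative)$p.value
      })
  }
  data.frame(test = test, n = length(x), effect = mean(d), p_value = p,
             shapiro_p = shapiro_p)
}
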