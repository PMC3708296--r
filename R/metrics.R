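# Evoked-response measures: mismatch difference waves, mean amplitude and
# peak latency over 100-200 ms, and the M100 peak over 50-150 ms.

.match_axes <- function(a, b) {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-9)
    stop("time axes do not match")
  invisible(TRUE)
}

#' Deviant-minus-standard difference waveforms
#'
#' @param evoked_deviant,evoked_standard \linkS4class{EvokedResponse}
#'   objects (or channel x time matrices) on the same time axis.
#' @param deviant,standard condition labels to pull from the evoked
#'   objects.
#' @return A channels x time matrix of sample-wise differences, with the
#'   time axis attached as attribute \code{"time"}.
#' @export
differenceWave <- function(evoked_deviant, evoked_standard,
                           deviant = NULL, standard = "standard") {
  if (is(evoked_deviant, "EvokedResponse")) {
    if (is.null(deviant)) {
      cand <- setdiff(names(evoked_deviant@waveforms), "standard")
      if (length(cand) != 1)
        stop("specify which deviant condition to use")
      deviant <- cand
    }
    tme <- timeAxis(evoked_deviant)
    d <- waveforms(evoked_deviant, deviant)
  } else { d <- evoked_deviant; tme <- attr(evoked_deviant, "time") }
  if (is(evoked_standard, "EvokedResponse")) {
    .match_axes(tme, timeAxis(evoked_standard))
    s <- waveforms(evoked_standard, standard)
  } else s <- evoked_standard
  if (!identical(dim(d), dim(s))) stop("waveform dimensions do not match")
  out <- d - s
  attr(out, "time") <- tme
  out
}

#' Mismatch-response metrics from a difference wave
#'
#' Mean amplitude is the time average over the analysis window; peak
#' latency is the time of the largest absolute deflection of the
#' difference within the window (earliest sample on ties).
#'
#' @param diff channels x time matrix from \code{\link{differenceWave}}
#'   (time axis in attribute \code{"time"}, or given via \code{time}).
#' @param window_ms analysis window, default 100-200 ms.
#' @param time optional explicit time axis.
#' @return data.frame per channel: mean amplitude (signed), mean magnitude,
#'   peak amplitude, peak latency (ms), and the window used.
#' @export
mmnMetrics <- function(diff, window_ms = c(100, 200), time = NULL) {
  if (is.null(time)) time <- attr(diff, "time")
  if (is.null(time)) stop("no time axis available")
  sel <- which(time >= window_ms[1] & time <= window_ms[2])
  if (length(sel) == 0) stop("analysis window lies outside the time axis")
  res <- lapply(seq_len(nrow(diff)), function(j) {
    w <- diff[j, sel]
    pk <- which.max(abs(w))          # which.max takes the earliest on ties
    data.frame(channel = rownames(diff)[j],
               mmn_mean_amplitude = mean(w),
               mmn_mean_magnitude = mean(abs(w)),
               mmn_peak_amplitude = w[pk],
               mmn_peak_latency_ms = time[sel][pk],
               window_lo_ms = window_ms[1], window_hi_ms = window_ms[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' M100 peak amplitude of the standard response
#'
#' The signed value at the maximum-magnitude sample of the standard-tone
#' evoked response within the window (default 50-150 ms), per channel.
#'
#' @param evoked_standard an \linkS4class{EvokedResponse} (uses its
#'   "standard" condition) or a channels x time matrix.
#' @param window_ms search window.
#' @param time explicit time axis when a matrix is supplied.
#' @return data.frame per channel with \code{m100_peak_amplitude} and
#'   \code{m100_peak_latency_ms}.
#' @export
m100Peak <- function(evoked_standard, window_ms = c(50, 150), time = NULL) {
  if (is(evoked_standard, "EvokedResponse")) {
    time <- timeAxis(evoked_standard)
    w <- waveforms(evoked_standard, "standard")
  } else w <- evoked_standard
  if (is.null(time)) stop("no time axis available")
  sel <- which(time >= window_ms[1] & time <= window_ms[2])
  if (length(sel) == 0) stop("window lies outside the time axis")
  res <- lapply(seq_len(nrow(w)), function(j) {
    v <- w[j, sel]
    pk <- which.max(abs(v))
    data.frame(channel = rownames(w)[j],
               m100_peak_amplitude = v[pk],
               m100_peak_latency_ms = time[sel][pk],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-subject waveform metric table
#'
#' Computes, for the two temporal sources, the M100 peak of the standard
#' response and the mismatch metrics of every deviant type present in the
#' evoked object.
#'
#' @param evoked an \linkS4class{EvokedResponse} with a "standard"
#'   condition and one condition per deviant type.
#' @param mmn_window_ms,m100_window_ms analysis windows.
#' @return Tidy data.frame: subject, source, deviant, measure, value.
#' @export
computeMetrics <- function(evoked, mmn_window_ms = c(100, 200),
                           m100_window_ms = c(50, 150)) {
  temporal <- grep("^temporal", evoked@channels, value = TRUE)
  rows <- list()
  m1 <- m100Peak(evoked, m100_window_ms)
  m1 <- m1[m1$channel %in% temporal, ]
  for (i in seq_len(nrow(m1)))
    rows[[length(rows) + 1]] <- data.frame(
      subject = evoked@subject, source = m1$channel[i], deviant = "none",
      measure = "m100_peak_amplitude", value = m1$m100_peak_amplitude[i],
      stringsAsFactors = FALSE)
  for (ty in setdiff(names(evoked@waveforms), "standard")) {
    d <- differenceWave(evoked, evoked, deviant = ty)
    mm <- mmnMetrics(d, mmn_window_ms, time = timeAxis(evoked))
    mm <- mm[mm$channel %in% temporal, ]
    for (i in seq_len(nrow(mm))) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = evoked@subject, source = mm$channel[i], deviant = ty,
        measure = c("mmn_mean_amplitude", "mmn_peak_latency_ms"),
        value = c(mm$mmn_mean_amplitude[i], mm$mmn_peak_latency_ms[i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group summary of waveform metrics
#'
#' Mean, standard error and n per group x source x deviant x measure.
#' With a single subject in a group the SE is reported as NA and flagged.
#'
#' @param metrics data.frame as from \code{\link{computeMetrics}}, rows
#'   from several subjects.
#' @param groups named vector mapping subject id to group label.
#' @return Summary data.frame.
#' @export
groupSummary <- function(metrics, groups) {
  metrics$group <- groups[as.character(metrics$subject)]
  key <- interaction(metrics$group, metrics$source, metrics$deviant,
                     metrics$measure, drop = TRUE)
  res <- lapply(split(metrics, key), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], source = d$source[1],
               deviant = d$deviant[1], measure = d$measure[1],
               mean = mean(d$value),
               se = if (n > 1) stats::sd(d$value) / sqrt(n) else NA_real_,
               n = n, single_subject = n == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
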