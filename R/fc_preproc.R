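#' BOLD timeseries session
#'
#' A regions x timepoints matrix of regional mean BOLD activation sampled
#' at a fixed repetition time.
#'
#' @param data Numeric matrix, regions in rows, timepoints in columns.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#'   Defaults to 0.72 s, the common multiband rsfMRI protocol value.
#' @return An object of class `timeseries_session`.
#' @export
timeseries_session <- function(data, tr_seconds = 0.72) {
  data <- as.matrix(data)
  if (ncol(data) < 3) stop("a session needs at least 3 timepoints")
  if (any(!is.finite(data))) stop("timeseries contains non-finite values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be a positive number")
  }
  structure(list(data = data, tr_seconds = tr_seconds),
            class = "timeseries_session")
}

#' Z-score a session per region
#'
#' Standardizes each region's series to mean 0 and sample standard
#' deviation 1 (denominator n - 1) within the session, independently of
#' any other session.
#'
#' @param s A `timeseries_session`.
#' @return A `timeseries_session` of standardized values.
#' @export
zscore_session <- function(s) {
  stopifnot(inherits(s, "timeseries_session"))
  mu <- rowMeans(s$data)
  sd <- apply(s$data, 1L, stats::sd)
  if (any(sd == 0)) {
    stop("zero-variance region(s) cannot be z-scored: ",
         paste(which(sd == 0), collapse = ", "))
  }
  timeseries_session((s$data - mu) / sd, s$tr_seconds)
}

#' Zero-phase band-pass filter a session
#'
#' Applies a 2nd-order Butterworth band-pass (designed with
#' `signal::butter`) forward and backward over each region's series:
#' zero phase shift, effective order 4.  Edge transients are suppressed
#' the standard way — the series is extended by odd reflection at both
#' ends and the filter starts from its steady state for the first
#' sample — so a constant (DC) series comes back essentially zero
#' rather than ringing.  The default band 0.01-0.1 Hz is the
#' conventional resting-state fMRI band.
#'
#' @param s A `timeseries_session`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)` (Nyquist).
#' @return A filtered `timeseries_session`.
#' @export
bandpass <- function(s, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(s, "timeseries_session"))
  nyq <- 1 / (2 * s$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    stop(sprintf("high_hz = %g must be below Nyquist = %g Hz", high_hz, nyq))
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(s$data, 1L, function(x) filtfilt_ss(bf$b, bf$a, x)))
  timeseries_session(out, s$tr_seconds)
}

# steady-state initial conditions of a DF2T filter for a unit step
# (solves (I - A') zi = B' where A', B' are the state recursion terms)
filter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1) return(numeric(0))
  comp <- rbind(-a[-1] / a[1], cbind(diag(n - 2), 0))
  if (n == 2) comp <- matrix(-a[2] / a[1], 1, 1)
  solve(diag(n - 1) - t(comp), b[-1] - b[1] * a[-1])
}

# zero-phase forward-backward filtering with odd extension
filtfilt_ss <- function(b, a, x) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  pad <- min(length(x) - 1L, 30L * (nf - 1L))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  ext <- c(front, x, back)
  zi <- filter_zi(b, a)
  y <- .iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + length(x))]
}

#' Concatenate sessions in time
#'
#' @param sessions List of `timeseries_session`s with equal region counts
#'   and repetition times.
#' @return One `timeseries_session` whose columns are the sessions in
#'   order (e.g. four 1200-point sessions give 4800 timepoints).
#' @export
concat_sessions <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  lapply(sessions, function(s) stopifnot(inherits(s, "timeseries_session")))
  nr <- vapply(sessions, function(s) nrow(s$data), integer(1))
  if (length(unique(nr)) != 1) {
    stop("sessions have mismatched region counts: ",
         paste(unique(nr), collapse = ", "))
  }
  tr <- vapply(sessions, function(s) s$tr_seconds, numeric(1))
  if (length(unique(tr)) != 1) stop("sessions have mismatched tr_seconds")
  timeseries_session(do.call(cbind, lapply(sessions, `[[`, "data")), tr[1])
}

#' Pearson functional connectivity from a timeseries
#'
#' Entry (i, j) is the Pearson correlation of region i's and region j's
#' series; the diagonal is set to zero.
#'
#' @param ts A `timeseries_session` (typically the concatenation of all
#'   preprocessed sessions).
#' @param atlas Optional `region_atlas` labelling the rows.
#' @return A functional `connectivity_matrix`.
#' @export
pearson_fc <- function(ts, atlas = NULL) {
  stopifnot(inherits(ts, "timeseries_session"))
  sds <- apply(ts$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s), correlation undefined: ",
         paste(which(sds == 0), collapse = ", "))
  }
  r <- stats::cor(t(ts$data))
  diag(r) <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  connectivity_matrix(r, "functional", atlas)
}

#' Full session-to-FC preprocessing pipeline
#'
#' Per session: z-score each region, band-pass filter; then concatenate
#' all sessions and compute Pearson functional connectivity.
#'
#' @param sessions List of `timeseries_session`s.
#' @param atlas Optional `region_atlas`.
#' @param low_hz,high_hz Band edges passed to [bandpass()].
#' @return A functional `connectivity_matrix`.
#' @export
sessions_to_fc <- function(sessions, atlas = NULL,
                           low_hz = 0.01, high_hz = 0.1) {
  pre <- lapply(sessions, function(s) bandpass(zscore_session(s),
                                               low_hz, high_hz))
  pearson_fc(concat_sessions(pre), atlas)
}
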