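#' Median-filter artifact detection and correction
#'
#' Flags beat i when its interval deviates from the median of the
#' five-beat window centred on it (`i-2 .. i+2`, truncated at the edges) by
#' more than `threshold_fraction` of that median; flagged beats are replaced
#' by the local median. Standard local-median ectopic/artefact handling for
#' RR series.
#'
#' @param series an [rr_series()] of length >= 5.
#' @param threshold_fraction proportion of the local median (default 0.2).
#' @return A list: `series` (corrected [rr_series()]), `flagged` (indices),
#'   `n_replaced`. A warning is emitted above 5% replacements; above 20% the
#'   segment is rejected with an error.
#' @export
filter_artifacts <- function(series, threshold_fraction = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals
  n <- length(x)
  if (n < 5) stop("artifact filtering needs at least 5 beats", call. = FALSE)
  if (threshold_fraction <= 0)
    stop("threshold_fraction must be > 0", call. = FALSE)
  med <- vapply(seq_len(n), function(i)
    stats::median(x[max(1L, i - 2L):min(n, i + 2L)]), numeric(1))
  flagged <- which(abs(x - med) > threshold_fraction * med)
  frac <- length(flagged) / n
  if (frac > 0.20)
    stop(sprintf("segment rejected: %.1f%% of beats flagged as artifacts",
                 100 * frac), call. = FALSE)
  if (frac > 0.05)
    warning(sprintf("%.1f%% of beats flagged as artifacts", 100 * frac),
            call. = FALSE)
  y <- x
  y[flagged] <- med[flagged]
  out <- rr_series(y, subject = series$subject, condition = series$condition,
                   context = series$context)
  list(series = out, flagged = flagged, n_replaced = length(flagged))
}

#' Smoothness-priors detrending
#'
#' Removes the slow trend of a series by the regularised least-squares fit
#' `trend = (I + lambda^2 * t(D2) %*% D2)^{-1} z`, where `D2` is the
#' (n-2) x n second-difference operator and `lambda` the single smoothing
#' parameter (default 500, the conventional value for short-term RR
#' analysis). Solved with a sparse Cholesky factorisation, so series of 1e5
#' beats detrend in well under a second.
#'
#' @param z numeric vector (ms), length >= 3.
#' @param lambda smoothing parameter, >= 0. `lambda = 0` returns the input
#'   as its own trend (zero residual).
#' @return A list with `trend` and `detrended` (`z - trend`).
#' @export
detrend_sp <- function(z, lambda = 500) {
  z <- as.numeric(z)
  n <- length(z)
  if (n < 3) stop("detrending needs at least 3 values", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be finite and >= 0", call. = FALSE)
  if (lambda == 0) return(list(trend = z, detrended = rep(0, n)))
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, z))
  list(trend = trend, detrended = z - trend)
}

#' Select the opening 5-minute supine window
#'
#' Returns the maximal run of beats from the start of the recording whose
#' onset times fall in the half-open window `[0, duration_s)` seconds, with
#' the first beat at t = 0.
#'
#' @param series an [rr_series()].
#' @param duration_s window length in seconds (default 300).
#' @return An [rr_series()] restricted to the window.
#' @export
select_supine_segment <- function(series, duration_s = 300) {
  stopifnot(inherits(series, "rr_series"))
  total <- sum(series$intervals) / 1000
  if (total < duration_s)
    stop(sprintf("recording lasts %.1f s; %.0f s required", total,
                 duration_s), call. = FALSE)
  keep <- series$beat_times < duration_s
  rr_series(series$intervals[keep], subject = series$subject,
            condition = series$condition, context = series$context)
}

stationarity_score <- function(w, n_quarters = 4L) {
  m <- mean(w)
  s <- stats::sd(w)
  if (s < .Machine$double.eps) return(0)
  q <- split(w, cut(seq_along(w), n_quarters, labels = FALSE))
  qm <- vapply(q, mean, numeric(1))
  qs <- vapply(q, stats::sd, numeric(1))
  max(abs(qm - m) / s) + max(abs(qs / s - 1))
}

#' Select a stationary fixed-length segment within a time-trial third
#'
#' Splits the recording into thirds by beat count (beginning / midway /
#' final), scores every `window`-beat window at the given stride inside the
#' requested third with a quartile-homogeneity statistic (maximum
#' standardised deviation of quarter means from the window mean, plus
#' maximum relative deviation of quarter SDs from the window SD), and
#' returns the minimal-score window — a deterministic surrogate for the
#' visual stationarity inspection traditionally used. Ties break to the
#' earliest start.
#'
#' @param series an [rr_series()].
#' @param moment one of `"beginning"`, `"midway"`, `"final"`.
#' @param window segment length in beats (default 1000).
#' @param stride window-start stride in beats (default 50).
#' @return A list: `series` (the selected segment), `start` (1-based index
#'   of its first beat in the input), `score`.
#' @export
select_stationary_segment <- function(series, moment = c("beginning",
                                                         "midway", "final"),
                                      window = 1000L, stride = 50L) {
  stopifnot(inherits(series, "rr_series"))
  moment <- match.arg(moment)
  x <- series$intervals
  n <- length(x)
  n3 <- floor(n / 3)
  bounds <- switch(moment,
    beginning = c(1L, n3),
    midway    = c(n3 + 1L, 2L * n3),
    final     = c(2L * n3 + 1L, n))
  third_len <- bounds[2L] - bounds[1L] + 1L
  if (third_len < window)
    stop(sprintf("the %s third holds %d beats; %d required", moment,
                 third_len, window), call. = FALSE)
  starts <- seq.int(bounds[1L], bounds[2L] - window + 1L, by = stride)
  scores <- vapply(starts, function(s)
    stationarity_score(x[s:(s + window - 1L)]), numeric(1))
  best <- starts[which.min(scores)]  # which.min takes the earliest tie
  seg <- rr_series(x[best:(best + window - 1L)], subject = series$subject,
                   condition = series$condition, context = series$context)
  list(series = seg, start = best, score = min(scores))
}
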