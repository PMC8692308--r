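#' Uniform-range quantization of an RR segment
#'
#' Divides the full observed range `[min, max]` of the segment into
#' `n_levels` equal-width bins (half-open, except the last which is closed
#' at the maximum) and maps every value to its bin index `0 .. n_levels-1`.
#' A degenerate range (max - min below 1e-9) maps every value to symbol 0.
#'
#' @param x numeric vector (ms), length >= 3.
#' @param n_levels number of quantization levels (>= 2; default 6).
#' @return Integer vector of symbols in `0:(n_levels-1)`.
#' @examples
#' rr_quantize(c(700, 733, 734, 800, 899, 900))  # 0 0 1 3 5 5
#' @export
rr_quantize <- function(x, n_levels = 6L) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("segment must hold at least 3 beats", call. = FALSE)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-9) return(rep(0L, length(x)))
  sym <- as.integer(floor((x - lo) / (hi - lo) * n_levels))
  sym[sym >= n_levels] <- n_levels - 1L   # top edge closed
  sym
}

#' Classify a three-symbol word into its variation family
#'
#' Counts the adjacent unequal pairs in a three-symbol word: 0 variations is
#' V0 (no variation — sympathetic predominance marker), 1 is V1 (one
#' variation — mixed modulation), 2 is V2 (two variations, like or unlike —
#' parasympathetic/vagal modulation marker; the two-variation subfamilies
#' are merged in the reported V2 family).
#'
#' @param word integer vector of exactly 3 symbols.
#' @return `"V0"`, `"V1"` or `"V2"`.
#' @examples
#' classify_word(c(4, 4, 4))  # "V0"
#' classify_word(c(2, 2, 5))  # "V1"
#' classify_word(c(1, 3, 1))  # "V2"
#' @export
classify_word <- function(word) {
  if (length(word) != 3) stop("a word has exactly 3 symbols", call. = FALSE)
  v <- (word[1] != word[2]) + (word[2] != word[3])
  c("V0", "V1", "V2")[v + 1L]
}

#' Symbolic-dynamics profile of an RR segment
#'
#' Quantizes the segment, forms overlapping three-beat words at the given
#' stride and reports the percentage occupancy of the V0/V1/V2 pattern
#' families. With `split_v2 = TRUE` the two-variation family is additionally
#' split into its like (2LV: both changes in the same direction) and unlike
#' (2UV) subfamilies for cross-checks against the source symbolic-analysis
#' method; the merged V2 is what is reported.
#'
#' @param x numeric vector (ms), length >= 3, or an [rr_series()].
#' @param n_levels quantization levels (default 6).
#' @param stride word-start stride (default 1, fully overlapping).
#' @param split_v2 also report the 2LV/2UV split of V2.
#' @return An object of class `symbolic_profile`: list with `v0_pct`,
#'   `v1_pct`, `v2_pct`, `counts` (named V0/V1/V2), `n_words`, `n_levels`,
#'   `stride` and, if requested, `v2lv_count`/`v2uv_count`.
#' @export
symbolic_profile <- function(x, n_levels = 6L, stride = 1L,
                             split_v2 = FALSE) {
  if (inherits(x, "rr_series")) x <- x$intervals
  sym <- rr_quantize(x, n_levels)
  n <- length(sym)
  starts <- seq.int(1L, n - 2L, by = stride)
  s1 <- sym[starts]; s2 <- sym[starts + 1L]; s3 <- sym[starts + 2L]
  d1 <- s2 - s1; d2 <- s3 - s2
  nvar <- (d1 != 0L) + (d2 != 0L)
  counts <- c(V0 = sum(nvar == 0L), V1 = sum(nvar == 1L),
              V2 = sum(nvar == 2L))
  n_words <- length(starts)
  out <- list(v0_pct = 100 * counts[["V0"]] / n_words,
              v1_pct = 100 * counts[["V1"]] / n_words,
              v2_pct = 100 * counts[["V2"]] / n_words,
              counts = counts, n_words = n_words,
              n_levels = as.integer(n_levels), stride = as.integer(stride))
  if (split_v2) {
    two <- nvar == 2L
    like <- two & (sign(d1) == sign(d2))
    out$v2lv_count <- sum(like)
    out$v2uv_count <- sum(two & !like)
  }
  structure(out, class = "symbolic_profile")
}

#' @export
print.symbolic_profile <- function(x, ...) {
  cat(sprintf(
    "<symbolic_profile> %d words (xi=%d): V0 %.1f%%  V1 %.1f%%  V2 %.1f%%\n",
    x$n_words, x$n_levels, x$v0_pct, x$v1_pct, x$v2_pct))
  invisible(x)
}
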