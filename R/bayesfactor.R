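#' JZS default Bayes factor for the paired / one-sample t setting
#'
#' Computes the Jeffreys–Zellner–Siow Bayes factor BF10 for a one-sample (or
#' paired-difference) t design with a Cauchy(0, r) prior on the standardised
#' effect size, written as the usual normal-by-inverse-gamma mixture over
#' the prior variance g. The g-integral is evaluated by adaptive quadrature
#' after the bounded transform u = g/(1+g), in log space, to relative
#' accuracy ~1e-8.
#'
#' @param differences numeric vector of paired differences; the t statistic
#'   and n are derived from it. Alternatively supply `t` and `n` directly.
#' @param t observed t statistic (ignored when `differences` given).
#' @param n sample size (number of differences), >= 2.
#' @param r Cauchy prior scale (default `1/sqrt(2)`, the default t test).
#' @return BF10 (numeric scalar), evidence for H1 over H0.
#' @examples
#' jzs_bf10(t = 0, n = 14)        # < 1: data favour the null
#' jzs_bf10(t = 3.2, n = 14)      # > 1
#' @export
jzs_bf10 <- function(differences = NULL, t = NULL, n = NULL,
                     r = 1 / sqrt(2)) {
  if (!is.null(differences)) {
    differences <- as.numeric(differences)
    n <- length(differences)
    if (n < 2) stop("need at least 2 differences", call. = FALSE)
    s <- stats::sd(differences)
    if (s < .Machine$double.eps)
      stop("zero variance in differences; t statistic undefined",
           call. = FALSE)
    t <- mean(differences) / (s / sqrt(n))
  }
  if (is.null(t) || is.null(n))
    stop("supply either `differences` or both `t` and `n`", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.finite(t)) stop("non-finite t statistic rejected", call. = FALSE)
  if (r <= 0) stop("Cauchy scale r must be > 0", call. = FALSE)
  .jzs_bf10_core(t, N_eff = n, nu = n - 1, r = r)
}

#' @rdname jzs_bf10
#' @param n1,n2 group sizes for the independent-samples variant.
#' @export
jzs_bf10_indep <- function(t, n1, n2, r = 1 / sqrt(2)) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (!is.finite(t)) stop("non-finite t statistic rejected", call. = FALSE)
  if (r <= 0) stop("Cauchy scale r must be > 0", call. = FALSE)
  .jzs_bf10_core(t, N_eff = n1 * n2 / (n1 + n2), nu = n1 + n2 - 2, r = r)
}

.jzs_bf10_core <- function(t, N_eff, nu, r) {
  # log marginal-likelihood ratio integrand over u = g/(1+g) in (0,1);
  # prior g ~ InverseGamma(1/2, r^2/2)  <=>  delta ~ Cauchy(0, r)
  log_num <- function(u) {
    g <- u / (1 - u)
    q <- 1 + N_eff * g
    -0.5 * log(q) - ((nu + 1) / 2) * log1p(t^2 / (q * nu)) +
      0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g) -
      2 * log(1 - u)
  }
  peak <- stats::optimize(log_num, c(1e-12, 1 - 1e-12), maximum = TRUE)
  off <- peak$objective
  I <- stats::integrate(function(u) exp(log_num(u) - off), 0, 1,
                        rel.tol = 1e-8, abs.tol = 0,
                        subdivisions = 500L)$value
  log_h0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  exp(off + log(I) - log_h0)
}

#' Westfall multiplicity-corrected prior odds
#'
#' Fixes at 0.5 the prior probability that the null hypothesis holds
#' simultaneously across all pairwise comparisons among `k_groups`
#' conditions. Each of the `choose(k, 2)` comparisons then carries
#' per-comparison prior null probability `p0 = 0.5^(2/k)` (so that
#' `p0^choose(k,2)` recovers 0.5 up to pair dependence) and prior odds
#' `(1 - p0)/p0`. For k = 3 this is `2^(2/3) - 1 = 0.5874`, the value
#' applied to every pairwise contrast among three conditions.
#'
#' @param k_groups number of conditions (>= 2).
#' @return Prior odds P(H1)/P(H0), numeric scalar at full precision.
#' @examples
#' round(westfall_prior_odds(3), 3)  # 0.587
#' westfall_prior_odds(2)            # 1: single comparison, no correction
#' @export
westfall_prior_odds <- function(k_groups) {
  if (k_groups < 2) stop("k_groups must be >= 2", call. = FALSE)
  p0 <- 0.5^(2 / k_groups)
  (1 - p0) / p0
}

#' Posterior odds from prior odds and a Bayes factor
#' @param prior_odds,bf10 positive numerics.
#' @return `prior_odds * bf10`.
#' @export
posterior_odds <- function(prior_odds, bf10) {
  if (any(prior_odds <= 0) || any(bf10 <= 0))
    stop("prior odds and BF10 must be > 0", call. = FALSE)
  prior_odds * bf10
}

#' Posterior probability of H1 implied by a Bayes factor
#'
#' The replication-probability reading of a Bayes factor under even prior
#' odds: `100 * bf10 / (bf10 + 1)` percent.
#'
#' @param bf10 non-negative numeric (vectorised).
#' @return Percentage in `[0, 100)`.
#' @examples
#' posterior_probability_pct(1)       # 50
#' posterior_probability_pct(11.728)  # 92.1...
#' @export
posterior_probability_pct <- function(bf10) {
  if (any(bf10 < 0)) stop("bf10 must be >= 0", call. = FALSE)
  100 * bf10 / (bf10 + 1)
}

#' Lee–Wagenmakers evidence band for a Bayes factor
#'
#' Bands: anecdotal (1–3), moderate (3–10), strong (10–30), very strong
#' (30–100), extreme (> 100) favouring H1; mirrored at the reciprocal
#' thresholds 1/3, 0.1, 0.03, 0.01 favouring H0. BF10 exactly 1 is labelled
#' anecdotal favouring H1 by convention. Codes follow the table convention:
#' upper case (A/M/S/VS/E) for H1, lower case for H0.
#'
#' @param bf10 positive numeric (vectorised).
#' @return data.frame with columns `bf10`, `band`, `direction`
#'   (`"H1"`/`"H0"`), `code`.
#' @export
evidence_label <- function(bf10) {
  if (any(bf10 <= 0)) stop("bf10 must be > 0", call. = FALSE)
  bands <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
  codes <- c("A", "M", "S", "VS", "E")
  h1 <- bf10 >= 1
  mag <- ifelse(h1, bf10, 1 / bf10)
  idx <- findInterval(mag, c(3, 10, 30, 100), left.open = TRUE) + 1L
  data.frame(bf10 = bf10, band = bands[idx],
             direction = ifelse(h1, "H1", "H0"),
             code = ifelse(h1, codes[idx], tolower(codes[idx])),
             stringsAsFactors = FALSE)
}

#' Pairwise Bayesian post-hoc comparisons across conditions
#'
#' For every pair of condition levels, aligns values by subject (paired
#' crossover design), computes the JZS Bayes factor of the paired
#' differences, applies the Westfall-corrected prior odds for the number of
#' conditions and reports the posterior odds, posterior probability and
#' evidence band — the structure of a Bayesian post-hoc table.
#'
#' @param data data.frame in long format.
#' @param value,condition,subject column names in `data`.
#' @param r Cauchy prior scale.
#' @param prior_odds prior odds applied to every comparison; default the
#'   Westfall correction for the observed number of conditions. Pass `1` for
#'   no correction.
#' @return data.frame with one row per contrast: `contrast`, `prior_odds`,
#'   `posterior_odds`, `bf10`, `probability_pct`, `band`, `direction`,
#'   `code`, `n`.
#' @export
bayes_posthoc <- function(data, value, condition, subject,
                          r = 1 / sqrt(2), prior_odds = NULL) {
  levs <- unique(as.character(data[[condition]]))
  k <- length(levs)
  if (k < 2) stop("need at least two conditions", call. = FALSE)
  if (is.null(prior_odds)) prior_odds <- westfall_prior_odds(k)
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    da <- data[data[[condition]] == a, c(subject, value)]
    db <- data[data[[condition]] == b, c(subject, value)]
    m <- merge(da, db, by = subject, suffixes = c("_a", "_b"))
    diffs <- m[[paste0(value, "_a")]] - m[[paste0(value, "_b")]]
    bf <- jzs_bf10(differences = diffs, r = r)
    lab <- evidence_label(bf)
    data.frame(contrast = paste(a, b, sep = "-"),
               prior_odds = prior_odds,
               posterior_odds = posterior_odds(prior_odds, bf),
               bf10 = bf,
               probability_pct = posterior_probability_pct(bf),
               band = lab$band, direction = lab$direction, code = lab$code,
               n = nrow(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a Bayesian post-hoc table with publication rounding
#'
#' Emits CSV with the conventional column order and rounding: prior and
#' posterior odds at 2 (or 3) decimals, BF at `digits_bf` decimals,
#' probability at 1 decimal, evidence code letters as the label column.
#'
#' @param comparisons output of [bayes_posthoc()] (possibly rbind-ed with a
#'   `variable` column).
#' @param path output CSV path.
#' @param digits_bf decimals for the BF column (default 3).
#' @param digits_odds decimals for the odds columns (default 2).
#' @return The rounded data.frame, invisibly (written to `path` if given).
#' @export
emit_bayes_table <- function(comparisons, path = NULL, digits_bf = 3,
                             digits_odds = 2) {
  keep <- intersect(c("variable", "contrast", "prior_odds", "posterior_odds",
                      "bf10", "probability_pct", "code"),
                    names(comparisons))
  out <- comparisons[, keep, drop = FALSE]
  if (nrow(out)) {
    out$prior_odds <- round(out$prior_odds, 3)
    out$posterior_odds <- round(out$posterior_odds, digits_odds)
    out$bf10 <- round(out$bf10, digits_bf)
    out$probability_pct <- round(out$probability_pct, 1)
  }
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
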