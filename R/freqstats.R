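#' Shapiro–Wilk normality gate
#'
#' Runs the Shapiro–Wilk test in every design cell and routes the variable
#' to the parametric repeated-measures ANOVA track when no cell rejects
#' normality at `alpha`, otherwise to the rank-based Kruskal–Wallis track.
#'
#' @param data long-format data.frame.
#' @param value value column name.
#' @param cells character vector of cell-defining column names.
#' @param alpha cell-wise significance level (default 0.05).
#' @return list with `route` (`"normal"` / `"non_normal"`) and `table`
#'   (per-cell W and p).
#' @export
shapiro_gate <- function(data, value, cells, alpha = 0.05) {
  key <- interaction(data[cells], drop = TRUE)
  groups <- split(data[[value]], key)
  tab <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 3)
      stop(sprintf("cell %s has %d observations; >= 3 required", g,
                   length(x)), call. = FALSE)
    if (stats::sd(x) < .Machine$double.eps)
      stop(sprintf("cell %s has zero variance; normality undefined", g),
           call. = FALSE)
    sw <- stats::shapiro.test(x)
    data.frame(cell = g, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  list(route = if (all(tab$p > alpha)) "normal" else "non_normal",
       table = tab)
}

orthonormal_contrasts <- function(m) {
  C <- stats::contr.helmert(m)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Mauchly sphericity test and Greenhouse-Geisser epsilon from the
# orthonormal-contrast covariance of the subject x cell matrix
sphericity_stats <- function(M, C) {
  n <- nrow(M)
  S <- stats::cov(M %*% C)
  d <- ncol(S)
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  if (d < 2 || n - 1 <= d) {
    W <- if (d < 2) 1 else NA_real_
    return(list(W = W, p = NA_real_, epsilon = if (d < 2) 1 else eps))
  }
  W <- det(S) / (sum(diag(S)) / d)^d
  # Box's chi-square approximation with second-order correction term
  nd <- n - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nd)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * d^2 * nd^2 * rho^2)
  z <- -nd * rho * log(W)
  df <- d * (d + 1) / 2 - 1
  p1 <- stats::pchisq(z, df, lower.tail = FALSE)
  p2 <- stats::pchisq(z, df + 4, lower.tail = FALSE)
  list(W = W, p = p1 + w2 * (p2 - p1), epsilon = eps)
}

#' Repeated-measures ANOVA for a fully within-subject crossover
#'
#' One- or two-way within-subject decomposition on a balanced complete
#' design. Each within effect is tested against its own subject-interaction
#' error term (`F = MS_effect / MS_(effect x subject)`). Per effect the
#' Mauchly sphericity test is computed from the orthonormal-contrast
#' covariance and the Greenhouse–Geisser epsilon
#' `tr(S)^2 / ((m-1) tr(S^2))` is applied to the degrees of freedom when
#' Mauchly rejects at `alpha` (or always, with
#' `gg = "always"`). Effect sizes are partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. Tukey HSD contrasts on the first
#' factor's marginal means use the within-subject error term and the
#' studentised range distribution, by default only when the omnibus effect
#' is significant.
#'
#' @param data long-format data.frame, one row per subject x cell.
#' @param value,subject column names.
#' @param within character vector of one or two within-subject factor
#'   column names (first factor = treatment for post-hoc purposes).
#' @param alpha significance level for the Mauchly gate and the post-hoc
#'   trigger (default 0.05).
#' @param gg `"mauchly"` (default: apply Greenhouse–Geisser when Mauchly
#'   p < alpha), `"always"`, or `"never"`.
#' @param posthoc `"if_significant"` (default), `"always"`, `"never"`.
#' @return An object of class `rm_anova_result`: list with `table` (one row
#'   per effect: df, F, p, GG-corrected p where applied, partial eta
#'   squared, Mauchly W/p, epsilon), `posthoc` (Tukey contrasts or NULL),
#'   `n_subjects`, `within`.
#' @export
rm_anova <- function(data, value, subject, within, alpha = 0.05,
                     gg = c("mauchly", "always", "never"),
                     posthoc = c("if_significant", "always", "never")) {
  gg <- match.arg(gg)
  posthoc <- match.arg(posthoc)
  if (!length(within) %in% 1:2)
    stop("within must name one or two factors", call. = FALSE)
  dat <- data.frame(y = data[[value]],
                    s = factor(data[[subject]]),
                    A = factor(data[[within[1]]]))
  two_way <- length(within) == 2
  dat$B <- if (two_way) factor(data[[within[2]]]) else factor("b1")
  if (anyNA(dat$y)) stop("missing values in response", call. = FALSE)
  counts <- table(dat$s, dat$A, dat$B)
  if (any(counts != 1))
    stop("unbalanced design: every subject needs exactly one observation ",
         "per cell", call. = FALSE)
  n <- nlevels(dat$s); a <- nlevels(dat$A); b <- nlevels(dat$B)
  if (a < 2) stop("first within factor needs >= 2 levels", call. = FALSE)

  mu <- mean(dat$y)
  m_s <- tapply(dat$y, dat$s, mean)
  m_a <- tapply(dat$y, dat$A, mean)
  m_b <- tapply(dat$y, dat$B, mean)
  m_ab <- tapply(dat$y, list(dat$A, dat$B), mean)
  m_as <- tapply(dat$y, list(dat$s, dat$A), mean)
  m_bs <- tapply(dat$y, list(dat$s, dat$B), mean)

  ss_total <- sum((dat$y - mu)^2)
  ss_s <- a * b * sum((m_s - mu)^2)
  ss_a <- n * b * sum((m_a - mu)^2)
  dev_as <- sweep(sweep(m_as, 1, m_s, "-"), 2, m_a, "-") + mu
  ss_as <- b * sum(dev_as^2)

  effects <- list()
  # subject x cell matrix, cells ordered (A slowest, B fastest)
  Ymat <- t(tapply(dat$y, list(interaction(dat$A, dat$B, lex.order = TRUE),
                               dat$s), mean))
  C_a <- orthonormal_contrasts(a)

  add_effect <- function(name, ss_eff, df_eff, ss_err, df_err, M, C) {
    sph <- sphericity_stats(M, C)
    Fv <- (ss_eff / df_eff) / (ss_err / df_err)
    p_raw <- stats::pf(Fv, df_eff, df_err, lower.tail = FALSE)
    apply_gg <- df_eff > 1 &&
      ((gg == "always") ||
         (gg == "mauchly" && !is.na(sph$p) && sph$p < alpha))
    p_gg <- if (apply_gg)
      stats::pf(Fv, df_eff * sph$epsilon, df_err * sph$epsilon,
                lower.tail = FALSE) else NA_real_
    data.frame(effect = name, df1 = df_eff, df2 = df_err, F = Fv,
               p = p_raw, gg_applied = apply_gg, p_gg = p_gg,
               p_reported = if (apply_gg) p_gg else p_raw,
               eta_sq_p = ss_eff / (ss_eff + ss_err),
               mauchly_W = sph$W, mauchly_p = sph$p,
               gg_epsilon = sph$epsilon, stringsAsFactors = FALSE)
  }

  if (!two_way) {
    tab <- add_effect(within[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1),
                      Ymat, C_a)
    ms_err_a <- (ss_as) / ((a - 1) * (n - 1))
    df_err_a <- (a - 1) * (n - 1)
  } else {
    ss_b <- n * a * sum((m_b - mu)^2)
    dev_bs <- sweep(sweep(m_bs, 1, m_s, "-"), 2, m_b, "-") + mu
    ss_bs <- a * sum(dev_bs^2)
    dev_ab <- sweep(sweep(m_ab, 1, m_a, "-"), 2, m_b, "-") + mu
    ss_ab <- n * sum(dev_ab^2)
    ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
    ss_abs <- max(ss_abs, 0)
    C_b <- orthonormal_contrasts(b)
    # subject x A means / subject x B means for per-effect sphericity
    M_a <- t(tapply(dat$y, list(dat$A, dat$s), mean))
    M_b <- t(tapply(dat$y, list(dat$B, dat$s), mean))
    tab <- rbind(
      add_effect(within[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), M_a, C_a),
      add_effect(within[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), M_b, C_b),
      add_effect(paste(within, collapse = ":"), ss_ab, (a - 1) * (b - 1),
                 ss_abs, (a - 1) * (b - 1) * (n - 1), Ymat,
                 C_a %x% C_b))
    ms_err_a <- ss_as / ((a - 1) * (n - 1))
    df_err_a <- (a - 1) * (n - 1)
  }
  rownames(tab) <- NULL

  tukey <- NULL
  run_posthoc <- posthoc == "always" ||
    (posthoc == "if_significant" && tab$p_reported[1] < alpha)
  if (run_posthoc && a >= 2) {
    se_mean <- sqrt(ms_err_a / (n * b))
    levs <- levels(dat$A)
    pairs <- utils::combn(levs, 2)
    tukey <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      d <- m_a[[pairs[1, j]]] - m_a[[pairs[2, j]]]
      q <- abs(d) / se_mean
      data.frame(contrast = paste(pairs[1, j], pairs[2, j], sep = "-"),
                 diff = d, q = q,
                 p = stats::ptukey(q, a, df_err_a, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(table = tab, posthoc = tukey, n_subjects = n,
                 within = within,
                 ss = list(total = ss_total, subject = ss_s)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, within: %s)\n",
              x$n_subjects, paste(x$within, collapse = " x ")))
  print(format(x$table[, c("effect", "df1", "df2", "F", "p_reported",
                           "eta_sq_p", "gg_epsilon", "gg_applied")],
               digits = 4), row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("Tukey HSD contrasts:\n")
    print(format(x$posthoc, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Kruskal–Wallis fallback for non-normal variables
#'
#' Rank-based omnibus test across condition groups with tie correction,
#' delegating to [stats::kruskal.test()].
#'
#' @param data long-format data.frame.
#' @param value,group column names.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_fallback <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(y) < 3) stop("need >= 3 observations", call. = FALSE)
  if (stats::sd(y) < .Machine$double.eps)
    stop("all values identical; ranks degenerate", call. = FALSE)
  kt <- stats::kruskal.test(y, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Condition deltas against the placebo reference
#'
#' Difference of condition means from the reference condition, in the
#' variable's units; the caffeine-supplementation delta convention (a
#' negative time delta means faster under caffeine).
#'
#' @param data long-format data.frame.
#' @param value,condition column names.
#' @param ref reference condition label (default `"PP"`).
#' @return data.frame with `contrast` (e.g. `"PC-PP"`) and `delta`.
#' @export
condition_deltas <- function(data, value, condition, ref = "PP") {
  levs <- unique(as.character(data[[condition]]))
  if (!ref %in% levs)
    stop("unknown reference condition: ", ref, call. = FALSE)
  means <- tapply(data[[value]], data[[condition]], mean)
  others <- setdiff(levs, ref)
  data.frame(contrast = paste(others, ref, sep = "-"),
             delta = as.numeric(means[others] - means[[ref]]),
             stringsAsFactors = FALSE)
}

#' Power of a one-group repeated-measures within-factors ANOVA
#'
#' Noncentral-F power under the G*Power convention for "ANOVA: repeated
#' measures, within factors" with one group: noncentrality
#' `lambda = f^2 * N * m * eps / (1 - rho)`, numerator df `(m-1)*eps`,
#' denominator df `(N-1)*(m-1)*eps`.
#'
#' @param N sample size (subjects).
#' @param f Cohen's effect size f.
#' @param m number of repeated measurements.
#' @param alpha significance level.
#' @param rho correlation among repeated measures (default 0.5).
#' @param eps nonsphericity correction (default 1).
#' @return Achieved power in (0, 1).
#' @export
rm_power <- function(N, f, m, alpha = 0.05, rho = 0.5, eps = 1) {
  if (f <= 0) stop("effect size f must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0,1)", call. = FALSE)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  lambda <- f^2 * N * m * eps / (1 - rho)
  df1 <- (m - 1) * eps
  df2 <- (N - 1) * (m - 1) * eps
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A priori sample size for the repeated-measures design
#'
#' Smallest N whose [rm_power()] reaches `target_power`; increasing scan
#' from N = 2 (power is nondecreasing in N).
#'
#' @inheritParams rm_power
#' @param target_power required power (default 0.80).
#' @param n_max scan ceiling.
#' @return Integer sample size.
#' @examples
#' rm_sample_size(f = 0.36, m = 3)  # 14
#' rm_sample_size(f = 0.41, m = 3)  # 12
#' @export
rm_sample_size <- function(f, m, alpha = 0.05, target_power = 0.80,
                           rho = 0.5, eps = 1, n_max = 100000L) {
  if (f <= 0) stop("effect size f must be > 0: power unreachable",
                   call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must be in (0,1)", call. = FALSE)
  for (N in 2:n_max) {
    if (rm_power(N, f, m, alpha = alpha, rho = rho, eps = eps) >=
          target_power)
      return(N)
  }
  stop("target power not reached by N = ", n_max, call. = FALSE)
}
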