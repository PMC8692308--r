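# Independent oracles used across the suite. Each deliberately re-derives
# the quantity from first principles by a different route than the package.

# Monte-Carlo JZS Bayes factor: sample g from its inverse-gamma prior and
# average the conditional likelihood ratio.
mc_jzs_bf10 <- function(t, n, r = 1 / sqrt(2), ndraws = 2e5, seed = 1) {
  withr::local_seed(seed)
  nu <- n - 1
  g <- 1 / rgamma(ndraws, shape = 0.5, rate = r^2 / 2)
  q <- 1 + n * g
  f <- q^(-0.5) * (1 + t^2 / (q * nu))^(-(nu + 1) / 2)
  denom <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  list(bf = mean(f) / denom, se = stats::sd(f) / sqrt(ndraws) / denom)
}

# Naive symbolic recount: rebuild bin edges with seq(), assign symbols by
# linear search, classify each word with explicit branching.
naive_symbolic <- function(x, n_levels = 6L) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-9) {
    sym <- rep(0L, length(x))
  } else {
    edges <- seq(lo, hi, length.out = n_levels + 1L)
    sym <- integer(length(x))
    for (i in seq_along(x)) {
      s <- n_levels - 1L  # top bin closed at max
      for (b in seq_len(n_levels - 1L)) {
        if (x[i] >= edges[b] && x[i] < edges[b + 1L]) { s <- b - 1L; break }
      }
      sym[i] <- s
    }
  }
  counts <- c(V0 = 0L, V1 = 0L, V2 = 0L)
  for (i in seq_len(length(sym) - 2L)) {
    w <- sym[i:(i + 2L)]
    nv <- 0L
    if (w[1] != w[2]) nv <- nv + 1L
    if (w[2] != w[3]) nv <- nv + 1L
    if (nv == 0L) counts["V0"] <- counts["V0"] + 1L
    else if (nv == 1L) counts["V1"] <- counts["V1"] + 1L
    else counts["V2"] <- counts["V2"] + 1L
  }
  nw <- length(sym) - 2L
  list(counts = counts, pct = 100 * counts / nw, n_words = nw)
}

# Brute-force two-way within-subject decomposition by explicit mean
# subtraction loops over the long table.
brute_rm_anova <- function(d) {
  subs <- unique(d$s); As <- unique(d$A); Bs <- unique(d$B)
  n <- length(subs); a <- length(As); b <- length(Bs)
  mu <- mean(d$y)
  cm <- function(rows) mean(d$y[rows])
  ss <- list(A = 0, B = 0, AB = 0, AS = 0, BS = 0, S = 0)
  for (j in As) ss$A <- ss$A + n * b * (cm(d$A == j) - mu)^2
  for (k in Bs) ss$B <- ss$B + n * a * (cm(d$B == k) - mu)^2
  for (i in subs) ss$S <- ss$S + a * b * (cm(d$s == i) - mu)^2
  for (j in As) for (k in Bs)
    ss$AB <- ss$AB + n * (cm(d$A == j & d$B == k) - cm(d$A == j) -
                            cm(d$B == k) + mu)^2
  for (i in subs) for (j in As)
    ss$AS <- ss$AS + b * (cm(d$s == i & d$A == j) - cm(d$s == i) -
                            cm(d$A == j) + mu)^2
  for (i in subs) for (k in Bs)
    ss$BS <- ss$BS + a * (cm(d$s == i & d$B == k) - cm(d$s == i) -
                            cm(d$B == k) + mu)^2
  ss$total <- sum((d$y - mu)^2)
  ss$ABS <- ss$total - ss$S - ss$A - ss$B - ss$AB - ss$AS - ss$BS
  ss$F_A <- (ss$A / (a - 1)) / (ss$AS / ((a - 1) * (n - 1)))
  ss$F_B <- (ss$B / (b - 1)) / (ss$BS / ((b - 1) * (n - 1)))
  ss$F_AB <- (ss$AB / ((a - 1) * (b - 1))) /
    (ss$ABS / ((a - 1) * (b - 1) * (n - 1)))
  ss
}

# Exhaustive stride-1 stationarity scorer over one third of a series,
# reported on the stride-50 grid used by the selector.
brute_best_window <- function(x, moment, window = 1000L, stride = 50L) {
  n <- length(x); n3 <- floor(n / 3)
  bounds <- switch(moment, beginning = c(1L, n3),
                   midway = c(n3 + 1L, 2L * n3),
                   final = c(2L * n3 + 1L, n))
  score1 <- function(w) {
    m <- mean(w); s <- sd(w)
    qlen <- length(w) / 4
    qs <- lapply(0:3, function(q) w[(q * qlen + 1):((q + 1) * qlen)])
    max(vapply(qs, function(z) abs(mean(z) - m) / s, 1)) +
      max(vapply(qs, function(z) abs(sd(z) / s - 1), 1))
  }
  starts <- seq.int(bounds[1L], bounds[2L] - window + 1L, by = stride)
  sc <- vapply(starts, function(st) score1(x[st:(st + window - 1L)]), 1)
  list(start = starts[which.min(sc)], score = min(sc), scores = sc,
       starts = starts)
}

# quick long-format design builder for ANOVA tests
make_within_data <- function(n, a, b = NULL, seed = 1,
                             a_effects = rep(0, a), subj_sd = 1,
                             noise_sd = 1) {
  withr::local_seed(seed)
  if (is.null(b)) {
    d <- expand.grid(s = factor(seq_len(n)), A = factor(paste0("a", 1:a)))
    d$y <- rnorm(n)[as.integer(d$s)] * subj_sd +
      a_effects[as.integer(d$A)] + rnorm(nrow(d), 0, noise_sd)
  } else {
    d <- expand.grid(s = factor(seq_len(n)), A = factor(paste0("a", 1:a)),
                     B = factor(paste0("b", 1:b)))
    d$y <- rnorm(n)[as.integer(d$s)] * subj_sd +
      a_effects[as.integer(d$A)] + rnorm(nrow(d), 0, noise_sd)
  }
  d
}
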