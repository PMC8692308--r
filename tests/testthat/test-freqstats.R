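test_that("two-way within ANOVA matches a brute-force decomposition", {
  withr::local_seed(14)
  d <- make_within_data(4, 3, 3, a_effects = c(0, 0.8, 1.4))
  res <- rm_anova(d, "y", "s", c("A", "B"), posthoc = "never")
  oracle <- brute_rm_anova(d)
  expect_equal(res$table$F[1], oracle$F_A, tolerance = 1e-10)
  expect_equal(res$table$F[2], oracle$F_B, tolerance = 1e-10)
  expect_equal(res$table$F[3], oracle$F_AB, tolerance = 1e-10)
  expect_equal(res$table$eta_sq_p[1],
               oracle$A / (oracle$A + oracle$AS), tolerance = 1e-10)
  # SS decomposition is exact on balanced data
  expect_equal(oracle$S + oracle$A + oracle$B + oracle$AB + oracle$AS +
                 oracle$BS + oracle$ABS, oracle$total, tolerance = 1e-10)
})

test_that("ANOVA agrees with the car multivariate-model cross-check", {
  withr::local_seed(70)
  n <- 10; a <- 3; b <- 3
  d <- make_within_data(n, a, b, a_effects = c(0, 0.5, 1))
  res <- rm_anova(d, "y", "s", c("A", "B"), gg = "always",
                  posthoc = "never")
  cells <- interaction(d$A, d$B, lex.order = TRUE)
  Y <- t(tapply(d$y, list(cells, d$s), mean))
  idata <- data.frame(A = factor(rep(paste0("a", 1:a), each = b)),
                      B = factor(rep(paste0("b", 1:b), a)))
  av <- suppressWarnings(  # car warns when HF epsilon exceeds 1
    summary(car::Anova(lm(Y ~ 1), idata = idata, idesign = ~ A * B,
                       type = 3), multivariate = FALSE))
  ut <- av$univariate.tests
  expect_equal(res$table$F, unname(ut[c("A", "B", "A:B"), "F value"]),
               tolerance = 1e-8)
  expect_equal(res$table$p, unname(ut[c("A", "B", "A:B"), "Pr(>F)"]),
               tolerance = 1e-8)
  adj <- av$pval.adjustments
  expect_equal(res$table$gg_epsilon,
               unname(adj[c("A", "B", "A:B"), "GG eps"]), tolerance = 1e-8)
  expect_equal(res$table$p_gg,
               unname(adj[c("A", "B", "A:B"), "Pr(>F[GG])"]),
               tolerance = 1e-8)
  sph <- av$sphericity.tests
  expect_equal(res$table$mauchly_W,
               unname(sph[c("A", "B", "A:B"), "Test statistic"]),
               tolerance = 1e-8)
  # Mauchly p: same Box expansion up to R's use of the raw cell dimension
  # in the second-order term
  expect_equal(res$table$mauchly_p,
               unname(sph[c("A", "B", "A:B"), "p-value"]), tolerance = 5e-3)
})

test_that("an exactly compound-symmetric covariance gives epsilon 1", {
  withr::local_seed(9)
  n <- 10; m <- 3
  X <- scale(matrix(rnorm(n * m), n, m), center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(cov(X)))  # exact identity sample covariance
  cs <- 0.5 * diag(m) + 0.5       # sigma2 = 1, rho = 0.5
  M <- X %*% chol(cs)
  d <- data.frame(s = factor(rep(1:n, m)),
                  A = factor(rep(paste0("a", 1:m), each = n)),
                  y = as.vector(M))
  res <- rm_anova(d, "y", "s", "A", posthoc = "never")
  expect_equal(res$table$gg_epsilon, 1, tolerance = 1e-10)
  expect_equal(res$table$mauchly_W, 1, tolerance = 1e-10)
})

test_that("partial eta squared is invariant under affine rescaling", {
  withr::local_seed(15)
  d <- make_within_data(8, 3, a_effects = c(0, 1, 2))
  r1 <- rm_anova(d, "y", "s", "A", posthoc = "never")
  d$y <- 100 + 7 * d$y
  r2 <- rm_anova(d, "y", "s", "A", posthoc = "never")
  expect_equal(r1$table$eta_sq_p, r2$table$eta_sq_p, tolerance = 1e-10)
  expect_equal(r1$table$F, r2$table$F, tolerance = 1e-10)
})

test_that("unbalanced or malformed designs are rejected", {
  d <- make_within_data(6, 3)
  expect_error(rm_anova(d[-1, ], "y", "s", "A"), "unbalanced")
  expect_error(rm_anova(d, "y", "s", c("A", "B", "C")), "one or two")
})

test_that("Tukey post-hoc flags the separated condition", {
  withr::local_seed(44)
  d <- make_within_data(14, 3, a_effects = c(0, 0, 2), noise_sd = 0.8)
  res <- rm_anova(d, "y", "s", "A")
  expect_false(is.null(res$posthoc))
  ph <- res$posthoc
  expect_lt(ph$p[ph$contrast == "a1-a3"], 0.05)
  expect_lt(ph$p[ph$contrast == "a2-a3"], 0.05)
  expect_gt(ph$p[ph$contrast == "a1-a2"], 0.05)
})

test_that("the Shapiro gate routes by distribution shape", {
  d0 <- data.frame(g = "x", v = rep(1, 10))
  expect_error(shapiro_gate(d0, "v", "g"), "zero variance")
  expect_error(shapiro_gate(data.frame(g = "x", v = c(1, 2)), "v", "g"),
               ">= 3")
  withr::local_seed(23)
  normal_hits <- sum(vapply(1:100, function(i) {
    d <- data.frame(g = "x", v = rnorm(5000))
    shapiro_gate(d, "v", "g")$route == "normal"
  }, TRUE))
  expect_gte(normal_hits, 94)
  exp_hits <- sum(vapply(1:100, function(i) {
    d <- data.frame(g = "x", v = rexp(50))
    shapiro_gate(d, "v", "g")$route == "non_normal"
  }, TRUE))
  expect_gte(exp_hits, 90)
})

test_that("Kruskal-Wallis fallback matches the rank formula and has power", {
  d_eq <- data.frame(g = rep(c("a", "b"), each = 5),
                     v = rep(c(1, 2, 3, 4, 5), 2))
  expect_equal(kruskal_fallback(d_eq, "v", "g")$H, 0, tolerance = 1e-12)
  d_toy <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                      v = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  # direct rank computation: H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1)
  expect_equal(kruskal_fallback(d_toy, "v", "g")$H,
               12 / (9 * 10) * (36 + 225 + 576) / 3 - 3 * 10,
               tolerance = 1e-12)
  expect_error(kruskal_fallback(data.frame(g = c("a", "b"), v = c(1, 1)),
                                "v", "g"), "identical|>= 3")
  withr::local_seed(61)
  rej <- sum(vapply(1:200, function(i) {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 30),
                    v = rnorm(90) + rep(c(0, 1, 1), each = 30))
    kruskal_fallback(d, "v", "g")$p < 0.05
  }, TRUE))
  expect_gt(rej / 200, 0.8)
})

test_that("condition deltas recover configured generator effects", {
  d_id <- data.frame(condition = rep(c("PP", "PC"), each = 4),
                     v = rep(1:4, 2))
  expect_equal(condition_deltas(d_id, "v", "condition")$delta, 0)
  expect_error(condition_deltas(d_id, "v", "condition", ref = "XX"),
               "unknown")
  spec <- cohort_spec(n_subjects = 200, contexts = "tt_final", seed = 8)
  study <- generate_study(spec, include_rr = FALSE)
  perf <- unique(study$cohort[, c("subject_id", "condition",
                                  "power_beginning_w", "power_midway_w",
                                  "power_final_w")])
  perf$pw <- rowMeans(perf[, 3:5])
  d <- condition_deltas(perf, "pw", "condition")
  expect_lt(abs(d$delta[d$contrast == "PC-PP"] - 6.17), 2)
  expect_gt(d$delta[d$contrast == "PC-PP"], 0)
})

test_that("power analysis reproduces the a priori design sample sizes", {
  expect_equal(rm_sample_size(f = 0.36, m = 3), 14)
  expect_equal(rm_sample_size(f = 0.41, m = 3), 12)
  expect_error(rm_sample_size(f = 0, m = 3), "unreachable|> 0")
})

test_that("power is monotone in N and f; sample size nonincreasing in f", {
  pw <- vapply(seq(4, 60, by = 4), function(N) rm_power(N, 0.3, 3), 1)
  expect_true(all(diff(pw) > 0))
  pf_ <- vapply(seq(0.1, 0.8, by = 0.1), function(f) rm_power(20, f, 3), 1)
  expect_true(all(diff(pf_) > 0))
  ns <- vapply(c(0.2, 0.3, 0.4, 0.6), function(f) rm_sample_size(f, 3), 1)
  expect_true(all(diff(ns) <= 0))
})
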