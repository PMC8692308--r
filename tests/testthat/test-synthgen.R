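test_that("a noiseless flat profile generates a constant series", {
  p <- autonomic_profile(mean_rr = 800)
  s <- generate_rr_series(p, 50, seed = 1)
  expect_equal(s$intervals, rep(800, 50))
})

test_that("generation is deterministic under a fixed seed", {
  p <- autonomic_profile(900, lf_amplitude = 30, hf_amplitude = 40,
                         noise_sd = 15)
  s1 <- generate_rr_series(p, 200, seed = 11)
  s2 <- generate_rr_series(p, 200, seed = 11)
  expect_identical(s1$intervals, s2$intervals)
  s3 <- generate_rr_series(p, 200, seed = 12)
  expect_false(identical(s1$intervals, s3$intervals))
})

test_that("implausible profiles and degenerate cohorts are rejected", {
  expect_error(autonomic_profile(-100), "> 0")
  expect_error(autonomic_profile(800, lf_freq = 0.3, hf_freq = 0.2),
               "below")
  p <- autonomic_profile(500, lf_amplitude = 150, hf_amplitude = 160)
  expect_error(generate_rr_series(p, 100), "non-positive")
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
})

test_that("every generated interval stays in the physiological band", {
  spec <- cohort_spec(n_subjects = 3, seed = 5)
  study <- generate_study(spec)
  for (s in study$series) {
    expect_true(all(s$intervals > 200))
    expect_true(all(s$intervals < 2500))
  }
})

test_that("higher hf amplitude yields higher downstream V2 occupancy", {
  v2_at <- function(hf, seed) {
    p <- autonomic_profile(800, hf_amplitude = hf, noise_sd = 4)
    symbolic_profile(generate_rr_series(p, 2000, seed = seed))$v2_pct
  }
  seeds <- 1:15
  lo <- mean(vapply(seeds, function(s) v2_at(5, s), 1))
  hi <- mean(vapply(seeds, function(s) v2_at(40, s), 1))
  expect_gt(hi, lo)
})

test_that("V2 responds monotonically to hf amplitude across a grid", {
  grid <- c(2, 6, 12, 20, 30, 45)
  mean_v2 <- vapply(grid, function(hf) {
    mean(vapply(1:8, function(seed) {
      p <- autonomic_profile(800, hf_amplitude = hf, noise_sd = 4)
      symbolic_profile(generate_rr_series(p, 1500, seed = seed))$v2_pct
    }, 1))
  }, 1)
  expect_gt(cor(grid, mean_v2, method = "spearman"), 0.9)
})

test_that("generate_study is reproducible and writes a parsable bundle", {
  spec <- cohort_spec(n_subjects = 2, contexts = c("supine_pre_suppl",
                                                   "tt_final"), seed = 3)
  dir <- withr::local_tempdir()
  a <- generate_study(spec, dir = dir)
  csv1 <- readLines(file.path(dir, "cohort.csv"))
  b <- generate_study(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$series[[1]]$intervals, b$series[[1]]$intervals)
  dir2 <- withr::local_tempdir()
  generate_study(spec, dir = dir2)
  expect_identical(csv1, readLines(file.path(dir2, "cohort.csv")))
  back <- read_rr_file(file.path(dir, a$cohort$rr_file[1]))
  expect_equal(back$intervals, a$series[[1]]$intervals, tolerance = 1e-12)
})

test_that("adding subjects does not perturb existing subjects' series", {
  small <- cohort_spec(n_subjects = 2, contexts = "tt_final", seed = 9)
  big <- cohort_spec(n_subjects = 4, contexts = "tt_final", seed = 9)
  a <- generate_study(small)
  b <- generate_study(big)
  for (key in names(a$series))
    expect_identical(a$series[[key]]$intervals, b$series[[key]]$intervals)
})

test_that("null configuration gives identical HRV summaries per condition", {
  profs <- default_profiles()
  profs$PC <- profs$PP
  profs$CC <- profs$PP
  spec <- cohort_spec(n_subjects = 2, contexts = "tt_final",
                      profiles = profs, rr_between_sd = 0,
                      amp_between_sd = 0, seed = 2)
  study <- generate_study(spec)
  v2 <- vapply(c("PP", "PC", "CC"), function(cond) {
    ints <- lapply(c("S01", "S02"), function(s)
      symbolic_profile(study$series[[paste(s, cond, "tt_final",
                                           sep = "_")]])$v2_pct)
    mean(unlist(ints))
  }, 1)
  # per-recording seeds differ across conditions, but the distributions
  # coincide; with zero between-subject terms condition means agree closely
  expect_lt(max(v2) - min(v2), 6)
})

test_that("configured TT deltas are recovered at large n (CLT check)", {
  spec <- cohort_spec(n_subjects = 200, contexts = "tt_final", seed = 4)
  study <- generate_study(spec, include_rr = FALSE)
  perf <- unique(study$cohort[, c("subject_id", "condition", "tt_time_s")])
  d <- condition_deltas(perf, "tt_time_s", "condition")
  # subject effects cancel in paired deltas; the sampling SE of a delta is
  # within_sd * sqrt(2/n), and 3 SE bounds the estimate
  tol <- 3 * spec$tt_time_within_sd * sqrt(2 / spec$n_subjects)
  expect_lt(abs(d$delta[d$contrast == "PC-PP"] - (-43.4)), tol)
  expect_lt(abs(d$delta[d$contrast == "CC-PP"] - (-39.3)), tol)
})
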