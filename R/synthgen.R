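#' Autonomic oscillator profile for synthetic RR generation
#'
#' Parameterises the beat-domain generative model used throughout the
#' package: a mean RR level plus two sinusoidal oscillators — a slow one near
#' 0.1 Hz (Mayer-wave band, sympathetically mediated) and a faster one near
#' 0.25 Hz (respiratory band, vagally mediated) — a linear drift and white
#' jitter. Raising `hf_amplitude` increases fast beat-to-beat alternation and
#' therefore downstream V2 occupancy; drift and `lf_amplitude` feed the slow,
#' pattern-free V0 end.
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param lf_amplitude,hf_amplitude oscillation amplitudes, ms (>= 0).
#' @param drift_slope linear trend, ms per beat.
#' @param noise_sd white jitter SD, ms (>= 0).
#' @param lf_freq,hf_freq oscillator frequencies, Hz; `lf_freq < hf_freq`.
#' @return An object of class `autonomic_profile`.
#' @export
autonomic_profile <- function(mean_rr, lf_amplitude = 0, hf_amplitude = 0,
                              drift_slope = 0, noise_sd = 0,
                              lf_freq = 0.1, hf_freq = 0.25) {
  if (!is.finite(mean_rr) || mean_rr <= 0)
    stop("mean_rr must be > 0", call. = FALSE)
  if (lf_amplitude < 0 || hf_amplitude < 0 || noise_sd < 0)
    stop("amplitudes and noise_sd must be >= 0", call. = FALSE)
  if (lf_freq >= hf_freq)
    stop("lf_freq must be below hf_freq", call. = FALSE)
  structure(list(mean_rr = mean_rr, lf_amplitude = lf_amplitude,
                 hf_amplitude = hf_amplitude, drift_slope = drift_slope,
                 noise_sd = noise_sd, lf_freq = lf_freq, hf_freq = hf_freq),
            class = "autonomic_profile")
}

# deterministic per-recording seed: adding subjects/conditions/contexts never
# perturbs already-generated series
recording_seed <- function(master, subject_idx, cond_idx, context_idx) {
  as.integer((master + 1009 * subject_idx + 97 * cond_idx +
                11 * context_idx) %% 2147483629)
}

#' Generate a synthetic RR series from an autonomic profile
#'
#' Beat-domain sampling: each interval is
#' `mean_rr + lf_amplitude*sin(2*pi*lf_freq*t) + hf_amplitude*sin(2*pi*hf_freq*t)
#'  + drift_slope*i + noise`, with `t` the running beat time in seconds
#' (recursion: the time axis is itself built from the generated intervals).
#' Deterministic under a fixed seed. Profiles whose deterministic amplitude
#' budget (`lf + hf + |drift|*n_beats`) reaches `mean_rr - 200` ms are
#' rejected up front, and every generated interval is checked against the
#' physiological band (200, 2500) ms.
#'
#' @param profile an [autonomic_profile()].
#' @param n_beats number of beats (>= 3).
#' @param seed integer RNG seed.
#' @param subject,condition,context metadata passed to [rr_series()].
#' @return An [rr_series()].
#' @export
generate_rr_series <- function(profile, n_beats, seed = 1L,
                               subject = NA, condition = NA, context = NA) {
  stopifnot(inherits(profile, "autonomic_profile"))
  if (n_beats < 3) stop("n_beats must be >= 3", call. = FALSE)
  budget <- profile$lf_amplitude + profile$hf_amplitude +
    abs(profile$drift_slope) * n_beats
  if (budget >= profile$mean_rr - 200)
    stop("profile can produce non-positive/implausible intervals: ",
         "amplitude budget ", round(budget, 1), " ms >= mean_rr - 200 ms",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  eps <- rnorm(n_beats, 0, profile$noise_sd)
  rr <- numeric(n_beats)
  t <- 0
  for (i in seq_len(n_beats)) {
    rr[i] <- profile$mean_rr +
      profile$lf_amplitude * sin(2 * pi * profile$lf_freq * t) +
      profile$hf_amplitude * sin(2 * pi * profile$hf_freq * t) +
      profile$drift_slope * (i - 1) + eps[i]
    t <- t + rr[i] / 1000
  }
  if (any(rr <= 200) || any(rr >= 2500))
    stop("generated intervals left the physiological band (200, 2500) ms; ",
         "reduce noise_sd or amplitudes", call. = FALSE)
  rr_series(rr, subject = subject, condition = condition, context = context)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

default_profiles <- function() {
  supine <- autonomic_profile(900, lf_amplitude = 30, hf_amplitude = 40,
                              drift_slope = 0, noise_sd = 15)
  tt_beg <- autonomic_profile(450, lf_amplitude = 10, hf_amplitude = 4,
                              drift_slope = -0.01, noise_sd = 3)
  tt_mid <- autonomic_profile(400, lf_amplitude = 8, hf_amplitude = 6,
                              drift_slope = -0.005, noise_sd = 3)
  tt_fin_pp <- autonomic_profile(370, lf_amplitude = 10, hf_amplitude = 6,
                                 drift_slope = -0.01, noise_sd = 3)
  tt_fin_caf <- autonomic_profile(380, lf_amplitude = 4, hf_amplitude = 16,
                                  drift_slope = -0.002, noise_sd = 3)
  out <- list()
  for (cond in c("PP", "PC", "CC")) {
    out[[cond]] <- list(
      supine_pre_suppl = supine,
      supine_pre_exerc = supine,
      supine_post      = supine,
      tt_beginning     = tt_beg,
      tt_midway        = tt_mid,
      tt_final         = if (cond == "PP") tt_fin_pp else tt_fin_caf)
  }
  out
}

#' Cohort specification for the synthetic crossover study
#'
#' Defaults emulate the study design the analysis pipeline targets: 14
#' subjects, three supplementation conditions (PP placebo-placebo, PC
#' placebo-caffeine, CC caffeine-caffeine), three 5-min supine recordings
#' and a 16 km time trial split into beginning/midway/final thirds. Time
#' trial outcome defaults: PP mean 1560 s with caffeine deltas -43.4 s (PC)
#' and -39.3 s (CC); mean power near 199.67 W with deltas +6.17 W (PC) and
#' +5.55 W (CC) concentrated at the trial beginning. Within-subject residual
#' SD for time defaults to 35 s, chosen so the treatment effect at n = 14
#' has the magnitude the design assumes (F near 6.5, partial eta squared
#' near 1/3); between-subject SD 70 s.
#'
#' @param n_subjects number of subjects (>= 2); default 14.
#' @param conditions condition labels; default `c("PP","PC","CC")`.
#' @param contexts recording contexts to generate; any subset of the six
#'   defaults.
#' @param profiles nested list `profiles[[condition]][[context]]` of
#'   [autonomic_profile()]s; defaults described above.
#' @param tt_time_means named per-condition mean TT times, s.
#' @param tt_time_between_sd,tt_time_within_sd between-/within-subject SD of
#'   TT time, s.
#' @param tt_power_means matrix (condition x interval) of mean power, W.
#' @param tt_power_between_sd,tt_power_within_sd power SD components, W.
#' @param rr_between_sd between-subject SD added to each profile's mean RR,
#'   ms (applied as one shift per subject, scaled down 10x in TT contexts).
#' @param amp_between_sd between-subject log-SD of a per-subject amplitude
#'   scale factor.
#' @param n_beats_supine,n_beats_tt beats generated per supine recording and
#'   per TT third.
#' @param seed master seed; per-recording streams are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14,
                        conditions = c("PP", "PC", "CC"),
                        contexts = c("supine_pre_suppl", "supine_pre_exerc",
                                     "supine_post", "tt_beginning",
                                     "tt_midway", "tt_final"),
                        profiles = default_profiles(),
                        tt_time_means = c(PP = 1560, PC = 1560 - 43.4,
                                          CC = 1560 - 39.3),
                        tt_time_between_sd = 70,
                        tt_time_within_sd = 35,
                        tt_power_means = rbind(
                          PP = c(beginning = 192, midway = 198, final = 202),
                          PC = c(beginning = 201.5, midway = 203, final = 206.01),
                          CC = c(beginning = 200.5, midway = 202.5, final = 205.65)),
                        tt_power_between_sd = 16,
                        tt_power_within_sd = 8,
                        rr_between_sd = 30,
                        amp_between_sd = 0.15,
                        n_beats_supine = 400,
                        n_beats_tt = 1300,
                        seed = 1L) {
  if (n_subjects < 2)
    stop("n_subjects must be >= 2 (no variance estimable otherwise)",
         call. = FALSE)
  if (anyDuplicated(conditions))
    stop("condition labels must be distinct", call. = FALSE)
  for (cond in conditions) for (ctx in contexts) {
    p <- profiles[[cond]][[ctx]]
    if (is.null(p) || !inherits(p, "autonomic_profile"))
      stop(sprintf("missing autonomic profile for %s x %s", cond, ctx),
           call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions, contexts = contexts,
                 profiles = profiles, tt_time_means = tt_time_means,
                 tt_time_between_sd = tt_time_between_sd,
                 tt_time_within_sd = tt_time_within_sd,
                 tt_power_means = tt_power_means,
                 tt_power_between_sd = tt_power_between_sd,
                 tt_power_within_sd = tt_power_within_sd,
                 rr_between_sd = rr_between_sd,
                 amp_between_sd = amp_between_sd,
                 n_beats_supine = as.integer(n_beats_supine),
                 n_beats_tt = as.integer(n_beats_tt),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

scale_profile <- function(p, rr_shift, amp_scale) {
  autonomic_profile(mean_rr = p$mean_rr + rr_shift,
                    lf_amplitude = p$lf_amplitude * amp_scale,
                    hf_amplitude = p$hf_amplitude * amp_scale,
                    drift_slope = p$drift_slope,
                    noise_sd = p$noise_sd,
                    lf_freq = p$lf_freq, hf_freq = p$hf_freq)
}

#' Generate a full synthetic study cohort
#'
#' Produces one RR series per subject x condition x context plus a cohort
#' table of time-trial outcomes (TT time and per-interval power). Subject
#' heterogeneity enters as a per-subject mean-RR shift and a log-normal
#' amplitude scale shared across that subject's recordings. Fully
#' deterministic for a fixed spec (the master seed is split per recording, so
#' enlarging the cohort reproduces existing subjects' series byte-for-byte).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; when given, each series is written
#'   with [write_rr_file()] and the cohort table as `cohort.csv`.
#' @param include_rr generate the RR series (default `TRUE`); `FALSE` yields
#'   only the outcome table, which is cheap at large `n_subjects`.
#' @return A list with `cohort` (data.frame: subject_id, condition, context,
#'   tt_time_s, power_beginning_w, power_midway_w, power_final_w, rr_file)
#'   and `series` (named list of [rr_series()], empty if
#'   `include_rr = FALSE`).
#' @export
generate_study <- function(spec = cohort_spec(), dir = NULL,
                           include_rr = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  series <- list()
  rows <- list()

  for (si in seq_along(subjects)) {
    # per-subject random effects from a dedicated stream
    old <- .Random.seed_save()
    set.seed(recording_seed(spec$seed, si, 0L, 0L))
    rr_shift <- rnorm(1, 0, spec$rr_between_sd)
    amp_scale <- exp(rnorm(1, 0, spec$amp_between_sd))
    time_re <- rnorm(1, 0, spec$tt_time_between_sd)
    pow_re <- rnorm(1, 0, spec$tt_power_between_sd)
    .Random.seed_restore(old)

    for (ci in seq_along(spec$conditions)) {
      cond <- spec$conditions[ci]
      # TT outcomes per subject x condition
      old <- .Random.seed_save()
      set.seed(recording_seed(spec$seed + 7919L, si, ci, 0L))
      tt_time <- spec$tt_time_means[[cond]] + time_re +
        rnorm(1, 0, spec$tt_time_within_sd)
      pw <- spec$tt_power_means[cond, ] + pow_re +
        rnorm(3, 0, spec$tt_power_within_sd)
      .Random.seed_restore(old)

      for (ki in seq_along(spec$contexts)) {
        ctx <- spec$contexts[ki]
        key <- paste(subjects[si], cond, ctx, sep = "_")
        fname <- paste0(key, ".txt")
        if (include_rr) {
          prof <- scale_profile(spec$profiles[[cond]][[ctx]],
                                rr_shift = if (startsWith(ctx, "tt"))
                                  rr_shift / 10 else rr_shift,
                                amp_scale = amp_scale)
          n_beats <- if (startsWith(ctx, "tt")) spec$n_beats_tt
                     else spec$n_beats_supine
          s <- generate_rr_series(prof, n_beats,
                                  seed = recording_seed(spec$seed, si, ci, ki),
                                  subject = subjects[si], condition = cond,
                                  context = ctx)
          series[[key]] <- s
          if (!is.null(dir)) write_rr_file(s, file.path(dir, fname))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects[si], condition = cond, context = ctx,
          tt_time_s = tt_time,
          power_beginning_w = pw[[1L]], power_midway_w = pw[[2L]],
          power_final_w = pw[[3L]], rr_file = fname,
          stringsAsFactors = FALSE)
      }
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  if (!is.null(dir))
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  list(cohort = cohort, series = series)
}
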