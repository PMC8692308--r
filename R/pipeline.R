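#' Maximal workload from a graded ergometer test
#'
#' Extrapolates over the final uncompleted stage of a ramp protocol with
#' fixed workload increments: `Wmax = output + (t / divisor) * increment`,
#' where `output` is the workload of the last completed stage and `t` the
#' seconds spent in the final, uncompleted stage. The default divisor of
#' 113 follows the protocol description this package reproduces; the
#' conventional Kuipers formulation divides by the stage duration (120 s
#' for 2-min stages) and is selectable via `divisor = 120`.
#'
#' @param output last completed workload, W (> 0).
#' @param t time in the final uncompleted stage, s (>= 0, <= divisor).
#' @param increment stage increment, W (default 45).
#' @param divisor stage-time divisor, s (default 113).
#' @return Wmax in watts.
#' @examples
#' wmax(338, 0)    # 338
#' wmax(338, 113)  # 383
#' @export
wmax <- function(output, t, increment = 45, divisor = 113) {
  if (output <= 0) stop("output workload must be > 0", call. = FALSE)
  if (t < 0) stop("stage time t must be >= 0", call. = FALSE)
  output + (t / divisor) * increment
}

#' Body-mass-scaled caffeine dose
#'
#' @param body_mass_kg body mass in kg (> 0; vectorised).
#' @param dose_per_kg dose in mg per kg (default 6).
#' @return Dose in mg, rounded to 2 decimals.
#' @examples
#' caffeine_dose(100)  # 600
#' @export
caffeine_dose <- function(body_mass_kg, dose_per_kg = 6) {
  if (any(body_mass_kg <= 0)) stop("body mass must be > 0", call. = FALSE)
  round(body_mass_kg * dose_per_kg, 2)
}

#' Run the full simulate-preprocess-symbolize-analyze pipeline
#'
#' Generates (or accepts) a synthetic cohort, preprocesses every recording
#' (artifact filter, segment selection, smoothness-priors detrending),
#' computes symbolic V0/V1/V2 profiles per recording context, and analyses
#' them: repeated-measures ANOVA across conditions (x moments for the time
#' trial), Bayesian pairwise post-hoc tables with Westfall-corrected prior
#' odds for the supine and time-trial symbolic variables and the
#' time-trial performance outcomes, and condition deltas versus PP.
#'
#' Time-trial recordings are assembled by concatenating the three `tt_*`
#' context series of a subject x condition (the trial's thirds) and, for
#' each moment, selecting the most stationary 1000-beat window inside the
#' corresponding beat-count third.
#'
#' @param spec a [cohort_spec()].
#' @param study optional pre-generated output of [generate_study()];
#'   regenerated from `spec` when NULL.
#' @param lambda smoothness-priors parameter (default 500); `detrend =
#'   FALSE` disables detrending before symbolisation.
#' @param n_levels,stride symbolic quantization configuration.
#' @param artifact_threshold local-median artifact threshold.
#' @param r Cauchy prior scale for the Bayes factors.
#' @param tt_window,tt_stride stationary-segment search configuration.
#' @param detrend logical; detrend segments before symbolisation.
#' @param out_dir optional directory; when given, symbolic profiles, ANOVA
#'   tables, Bayes tables and deltas are written as CSV/JSON.
#' @return A list of class `hrv_pipeline_result`: `symbolic` (long
#'   data.frame of per-recording V0/V1/V2), `anova` (named list of
#'   [rm_anova()] results), `bayes` (named list of [bayes_posthoc()]
#'   tables), `deltas`, `performance` (per subject x condition TT outcomes),
#'   `log` (character vector of per-recording preprocessing decisions).
#' @export
run_pipeline <- function(spec = cohort_spec(), study = NULL, lambda = 500,
                         n_levels = 6L, stride = 1L,
                         artifact_threshold = 0.2, r = 1 / sqrt(2),
                         tt_window = 1000L, tt_stride = 50L,
                         detrend = TRUE, out_dir = NULL) {
  if (is.null(study)) study <- generate_study(spec)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  supine_ctx <- grep("^supine", spec$contexts, value = TRUE)
  tt_ctx <- intersect(c("tt_beginning", "tt_midway", "tt_final"),
                      spec$contexts)
  moments <- sub("^tt_", "", tt_ctx)
  subjects <- unique(study$cohort$subject_id)

  prep <- function(vals) if (detrend) detrend_sp(vals, lambda)$detrended
                         else vals

  sym_rows <- list()
  for (subj in subjects) for (cond in spec$conditions) {
    for (ctx in supine_ctx) {
      s <- study$series[[paste(subj, cond, ctx, sep = "_")]]
      flt <- filter_artifacts(s, artifact_threshold)
      note("%s %s %s: %d artifacts replaced", subj, cond, ctx,
           flt$n_replaced)
      seg <- select_supine_segment(flt$series)
      prof <- symbolic_profile(prep(seg$intervals), n_levels, stride)
      sym_rows[[length(sym_rows) + 1L]] <- data.frame(
        subject = subj, condition = cond, context = ctx,
        v0_pct = prof$v0_pct, v1_pct = prof$v1_pct, v2_pct = prof$v2_pct,
        n_words = prof$n_words, stringsAsFactors = FALSE)
    }
    if (length(tt_ctx) == 3L) {
      tt <- rr_series(unlist(lapply(tt_ctx, function(ctx)
        study$series[[paste(subj, cond, ctx, sep = "_")]]$intervals)),
        subject = subj, condition = cond, context = "tt")
      flt <- filter_artifacts(tt, artifact_threshold)
      note("%s %s tt: %d artifacts replaced", subj, cond, flt$n_replaced)
      for (mom in moments) {
        sel <- select_stationary_segment(flt$series, mom, tt_window,
                                         tt_stride)
        note("%s %s tt_%s: window start %d score %.4f", subj, cond, mom,
             sel$start, sel$score)
        prof <- symbolic_profile(prep(sel$series$intervals), n_levels,
                                 stride)
        sym_rows[[length(sym_rows) + 1L]] <- data.frame(
          subject = subj, condition = cond, context = paste0("tt_", mom),
          v0_pct = prof$v0_pct, v1_pct = prof$v1_pct, v2_pct = prof$v2_pct,
          n_words = prof$n_words, stringsAsFactors = FALSE)
      }
    }
  }
  symbolic <- do.call(rbind, sym_rows)

  perf <- unique(study$cohort[, c("subject_id", "condition", "tt_time_s",
                                  "power_beginning_w", "power_midway_w",
                                  "power_final_w")])
  perf$power_mean_w <- rowMeans(perf[, c("power_beginning_w",
                                         "power_midway_w",
                                         "power_final_w")])

  anova <- list(); bayes <- list(); deltas <- list()
  for (v in c("v0_pct", "v1_pct", "v2_pct")) {
    if (length(tt_ctx) == 3L) {
      tt_dat <- symbolic[startsWith(symbolic$context, "tt_"), ]
      anova[[paste0("tt_", v)]] <- rm_anova(
        tt_dat, v, "subject", c("condition", "context"))
      agg <- stats::aggregate(tt_dat[[v]],
                              list(subject = tt_dat$subject,
                                   condition = tt_dat$condition), mean)
      names(agg)[3] <- v
      bayes[[paste0("tt_", v)]] <- bayes_posthoc(agg, v, "condition",
                                                 "subject", r = r)
      fin <- tt_dat[tt_dat$context == "tt_final", ]
      deltas[[paste0("tt_final_", v)]] <-
        condition_deltas(fin, v, "condition")
    }
    if (length(supine_ctx) >= 2L) {
      sp_dat <- symbolic[startsWith(symbolic$context, "supine"), ]
      anova[[paste0("supine_", v)]] <- rm_anova(
        sp_dat, v, "subject", c("condition", "context"))
      agg <- stats::aggregate(sp_dat[[v]],
                              list(subject = sp_dat$subject,
                                   condition = sp_dat$condition), mean)
      names(agg)[3] <- v
      bayes[[paste0("supine_", v)]] <- bayes_posthoc(agg, v, "condition",
                                                     "subject", r = r)
    }
  }

  anova$tt_time <- rm_anova(perf, "tt_time_s", "subject_id", "condition")
  bayes$tt_time <- bayes_posthoc(perf, "tt_time_s", "condition",
                                 "subject_id", r = r)
  deltas$tt_time <- condition_deltas(perf, "tt_time_s", "condition")
  pw_long <- do.call(rbind, lapply(
    c(beginning = "power_beginning_w", midway = "power_midway_w",
      final = "power_final_w"),
    function(col) data.frame(subject_id = perf$subject_id,
                             condition = perf$condition,
                             interval = sub("power_|_w", "", col),
                             power_w = perf[[col]],
                             stringsAsFactors = FALSE)))
  anova$tt_power <- rm_anova(pw_long, "power_w", "subject_id",
                             c("condition", "interval"))
  bayes$tt_power <- bayes_posthoc(perf, "power_mean_w", "condition",
                                  "subject_id", r = r)
  deltas$tt_power <- condition_deltas(perf, "power_mean_w", "condition")

  res <- structure(list(symbolic = symbolic, anova = anova, bayes = bayes,
                        deltas = deltas, performance = perf, log = log,
                        spec = spec),
                   class = "hrv_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

#' @export
print.hrv_pipeline_result <- function(x, ...) {
  cat(sprintf("<hrv_pipeline_result> %d recordings symbolised, %d analyses\n",
              nrow(x$symbolic), length(x$anova)))
  invisible(x)
}

write_pipeline_reports <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(res$symbolic, file.path(out_dir, "symbolic_profiles.csv"),
                   row.names = FALSE)
  anova_tab <- do.call(rbind, lapply(names(res$anova), function(nm) {
    tb <- res$anova[[nm]]$table
    cbind(variable = nm, tb)
  }))
  utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  bayes_tab <- do.call(rbind, lapply(names(res$bayes), function(nm)
    cbind(variable = nm, res$bayes[[nm]])))
  emit_bayes_table(bayes_tab, file.path(out_dir, "bayes_posthoc.csv"))
  delta_tab <- do.call(rbind, lapply(names(res$deltas), function(nm)
    cbind(variable = nm, res$deltas[[nm]])))
  utils::write.csv(delta_tab, file.path(out_dir, "deltas.csv"),
                   row.names = FALSE)
  writeLines(res$log, file.path(out_dir, "pipeline.log"))
  jsonlite::write_json(
    list(n_recordings = nrow(res$symbolic),
         variables = names(res$anova)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Persist / restore a pipeline run configuration
#'
#' Serialises the tunable arguments of [run_pipeline()] plus the scalar
#' fields of the cohort spec to YAML, so a run can be reproduced from its
#' config file. Profiles and outcome means round-trip as plain lists.
#'
#' @param config named list of run settings (any subset of the
#'   [run_pipeline()]/[cohort_spec()] arguments).
#' @param path YAML file path.
#' @return `save_run_config`: `path` invisibly. `load_run_config`: the
#'   configuration list.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  yaml::read_yaml(path)
}
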