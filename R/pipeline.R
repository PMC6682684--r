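## End-to-end orchestration: per-subject simulation -> preprocessing ->
## features -> classification, followed by cohort-level statistics.

#' Study configuration
#'
#' Bundles every tunable of a full study run: cohort size and seed,
#' paradigm timing, population distribution, preprocessing thresholds,
#' classifier settings and predictor settings. A run is fully determined
#' by its configuration (including the seed).
#'
#' @param n_subjects Cohort size.
#' @param seed Top-level seed; per-subject streams are split from it.
#' @param paradigm A [paradigm_config()].
#' @param population A [cohort_population()].
#' @param speller_words Words spelled in the classified (test) session.
#' @param preprocess List: `low`, `high`, `order`, `abs_thresh`,
#'   `sd_mult`, `k_adjacent`.
#' @param classifier List: `folds`, `block`, `max_features`, `p_enter`,
#'   `p_remove`.
#' @param predictor List: `p_enter`, `p_remove` (stepwise regression).
#' @param n_top,n_bottom High/low performance group sizes.
#' @param outlier_k SD multiplier for low-AUC outlier screening.
#' @param fdr_q FDR level for the correlation topography.
#' @param topography Compute per-channel features and the correlation
#'   topography (disable to speed up large simulation sweeps).
#' @param trial_sweep Run the trial-count sweep (`FALSE`, `TRUE`, or an
#'   integer vector of trial counts).
#' @return A `run_config` list.
#' @export
study_config <- function(n_subjects = 48, seed = 1,
                         paradigm = paradigm_config(),
                         population = cohort_population(),
                         speller_words = paradigm$test_words,
                         preprocess = list(),
                         classifier = list(),
                         predictor = list(),
                         n_top = 10, n_bottom = 10,
                         outlier_k = 2.5, fdr_q = 0.1,
                         topography = TRUE,
                         trial_sweep = FALSE) {
  prep <- utils::modifyList(
    list(low = 0.5, high = 10, order = 4, abs_thresh = 100, sd_mult = 5,
         k_adjacent = 3), preprocess)
  clf <- utils::modifyList(
    list(folds = 10, block = 24, max_features = 60, p_enter = 0.10,
         p_remove = 0.15), classifier)
  pred <- utils::modifyList(list(p_enter = 0.05, p_remove = 0.10),
                            predictor)
  structure(list(n_subjects = n_subjects, seed = seed,
                 paradigm = paradigm, population = population,
                 speller_words = speller_words, preprocess = prep,
                 classifier = clf, predictor = pred,
                 n_top = n_top, n_bottom = n_bottom,
                 outlier_k = outlier_k, fdr_q = fdr_q,
                 topography = topography, trial_sweep = trial_sweep),
            class = "run_config")
}

#' Simulate and analyze one subject
#'
#' Generates the subject's RSVP and speller test sessions, preprocesses
#' both, extracts the five RSVP features and the per-channel features,
#' and computes the cross-validated speller AUC.
#'
#' @param profile A [subject_profile()] (with `sim_seed` attribute, as
#'   produced by [sample_cohort()]).
#' @param config A `run_config` from [study_config()].
#' @return List: `features` (one-row tibble), `auc`, `series` (per-trial
#'   peak series), `behavior`, `channel_features`, `counts` (epoch
#'   bookkeeping).
#' @export
analyze_subject <- function(profile, config = study_config()) {
  prep <- config$preprocess
  clf <- config$classifier
  rsvp <- generate_rsvp_session(profile, config$paradigm)
  rsvp_ep <- preprocess_session(
    rsvp$session, low = prep$low, high = prep$high, order = prep$order,
    abs_thresh = prep$abs_thresh, sd_mult = prep$sd_mult,
    k_adjacent = prep$k_adjacent)
  series <- trial_peak_series(rsvp_ep)
  feats <- subject_features(rsvp_ep, rsvp$behavior, series = series)
  chan_feats <- if (isTRUE(config$topography)) {
    channel_features(rsvp_ep)
  } else NULL

  speller <- generate_speller_session(profile, config$paradigm,
                                      words = config$speller_words)
  spell_ep <- preprocess_session(
    speller, low = prep$low, high = prep$high, order = prep$order,
    abs_thresh = prep$abs_thresh, sd_mult = prep$sd_mult)
  subj_auc <- crossval_auc(
    spell_ep, k = clf$folds, seed = attr(profile, "sim_seed"),
    block = clf$block, max_features = clf$max_features,
    p_enter = clf$p_enter, p_remove = clf$p_remove)

  counts <- c(
    rsvp_extracted = n_epochs(rsvp_ep),
    rsvp_rejected = sum(rsvp_ep$reject_reason %in% c("abs", "sd"),
                        na.rm = TRUE),
    rsvp_adjacent_dropped = sum(rsvp_ep$reject_reason == "adjacent",
                                na.rm = TRUE),
    speller_extracted = n_epochs(spell_ep),
    speller_rejected = sum(spell_ep$reject_mask))
  list(features = feats, auc = as.numeric(subj_auc), series = series,
       behavior = rsvp$behavior, channel_features = chan_feats,
       counts = counts, fold_auc = attr(subj_auc, "fold_auc"))
}

#' Run the full study
#'
#' Simulates the whole cohort, analyzes every subject
#' ([analyze_subject()]), screens low-AUC outliers, and produces the
#' cohort-level report: the seven-predictor comparison (with and without
#' outliers), high/low group contrasts on the channel-averaged features,
#' per-channel correlation topographies with FDR flags, and (optionally)
#' the trial-count sweep. The manifest records the seed and per-stage
#' epoch bookkeeping.
#'
#' @param config A `run_config` from [study_config()].
#' @param progress Print one line per subject.
#' @return A `study_report` list; see Details.
#' @details The returned bundle has elements `cohort` (per-subject
#'   features, AUC and ground-truth profile parameters), `outliers`,
#'   `predictors` / `predictors_no_outliers`, `group_stats`,
#'   `topography`, `trial_sweep` (or `NULL`) and `manifest`.
#' @export
run_full_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  profiles <- sample_cohort(config$n_subjects, config$population,
                            seed = config$seed,
                            channel_names = config$paradigm$channel_names)
  res <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    res[[i]] <- analyze_subject(profiles[[i]], config)
    if (progress) {
      message(sprintf("subject %s: AUC %.3f", profiles[[i]]$subject_id,
                      res[[i]]$auc))
    }
  }
  ids <- vapply(profiles, `[[`, "", "subject_id")
  feats <- do.call(rbind, lapply(res, `[[`, "features"))
  cohort <- tibble::tibble(
    subject_id = ids,
    auc = vapply(res, `[[`, 0, "auc"),
    feats,
    true_amp_mean = vapply(profiles, `[[`, 0, "amp_mean"),
    true_amp_sd = vapply(profiles, `[[`, 0, "amp_sd"),
    true_lat_mean = vapply(profiles, `[[`, 0, "lat_mean"),
    true_lat_sd = vapply(profiles, `[[`, 0, "lat_sd"),
    true_t1_prob = vapply(profiles, `[[`, 0, "t1_prob"),
    true_noise_sd = vapply(profiles, `[[`, 0, "noise_sd"))

  auc_named <- stats::setNames(cohort$auc, ids)
  outliers <- detect_outliers(auc_named, k = config$outlier_k)
  keep <- !(ids %in% outliers)

  pred_all <- predictor_report(feats, cohort$auc,
                               p_enter = config$predictor$p_enter,
                               p_remove = config$predictor$p_remove)
  pred_clean <- if (sum(keep) >= 8 && any(!keep)) {
    predictor_report(feats[keep, ], cohort$auc[keep],
                     p_enter = config$predictor$p_enter,
                     p_remove = config$predictor$p_remove)
  } else pred_all

  ## high/low group contrast on the channel-averaged features
  grp <- split_groups(auc_named, n_top = config$n_top,
                      n_bottom = config$n_bottom)
  group_stats <- do.call(rbind, lapply(
    c("p300_amplitude", "p300_latency", "amp_trial_sd", "lat_trial_sd"),
    function(f) {
      hi <- feats[[f]][ids %in% grp$high]
      lo <- feats[[f]][ids %in% grp$low]
      tt <- tryCatch(unpaired_ttest(hi, lo), error = function(e)
        list(t = NA_real_, p = NA_real_))
      tibble::tibble(feature = f, mean_high = mean(hi), mean_low = mean(lo),
                     t = tt$t, p = tt$p)
    }))

  ## per-channel correlation topography
  topo <- if (!isTRUE(config$topography)) NULL else do.call(rbind, lapply(
    c("p300_amplitude", "p300_latency", "amp_trial_sd", "lat_trial_sd"),
    function(f) {
      M <- t(vapply(res, function(r) {
        stats::setNames(r$channel_features[[f]],
                        r$channel_features$channel)
      }, stats::setNames(numeric(config$paradigm$n_channels),
                         config$paradigm$channel_names)))
      tb <- correlation_topography(M, cohort$auc, q = config$fdr_q)
      tb$feature <- f
      tb
    }))

  sweep_tbl <- NULL
  if (!identical(config$trial_sweep, FALSE)) {
    n_range <- if (isTRUE(config$trial_sweep)) {
      5:config$paradigm$rsvp_trials
    } else config$trial_sweep
    sweep_tbl <- trial_sweep(lapply(res, `[[`, "series"),
                             lapply(res, `[[`, "behavior"),
                             cohort$auc, n_range = n_range)
  }

  counts <- Reduce(`+`, lapply(res, `[[`, "counts"))
  rejected <- counts[["rsvp_rejected"]] + counts[["speller_rejected"]]
  extracted <- counts[["rsvp_extracted"]] + counts[["speller_extracted"]]
  manifest <- list(
    seed = config$seed,
    n_subjects = config$n_subjects,
    counts = as.list(counts),
    rejection_percent = 100 * rejected / extracted,
    outliers = outliers)

  structure(list(cohort = cohort, outliers = outliers,
                 predictors = pred_all,
                 predictors_no_outliers = pred_clean,
                 group_stats = group_stats, topography = topo,
                 trial_sweep = sweep_tbl, manifest = manifest,
                 series = lapply(res, `[[`, "series"),
                 behavior = lapply(res, `[[`, "behavior")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d subjects (seed %s), mean AUC %.3f +/- %.3f\n",
              nrow(x$cohort), x$manifest$seed, mean(x$cohort$auc),
              stats::sd(x$cohort$auc)))
  cat(sprintf("  rejected epochs: %.2f%%; outliers: %s\n",
              x$manifest$rejection_percent,
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none"))
  cat("  predictor comparison (LOSO):\n")
  print(as.data.frame(x$predictors[, c("predictor", "r", "p", "MSE")]),
        digits = 3)
  invisible(x)
}

#' Write study fixtures to disk
#'
#' Materializes session directories for a named fixture: `"smoke"` is a
#' 6-subject miniature (10 RSVP trials, one test word, 3 repetitions);
#' `"cohort48"` is the full-size study emulation (48 subjects, 40 RSVP
#' trials, four 7-letter test words, 15 repetitions).
#'
#' @param name `"smoke"` or `"cohort48"`.
#' @param seed Integer seed.
#' @param out Output directory.
#' @param format Signal storage format, see [write_session()].
#' @return Invisibly, the vector of subject directories written.
#' @export
make_fixture <- function(name = c("smoke", "cohort48"), seed, out,
                         format = c("f32", "csv")) {
  name <- match.arg(name)
  format <- match.arg(format)
  cfg <- switch(name,
    smoke = study_config(
      n_subjects = 6, seed = seed,
      paradigm = paradigm_config(rsvp_trials = 10, response_window = 1,
                                 repetitions = 3,
                                 test_words = "BRAIN"),
      speller_words = "BRAIN"),
    cohort48 = study_config(n_subjects = 48, seed = seed))
  profiles <- sample_cohort(cfg$n_subjects, cfg$population,
                            seed = cfg$seed)
  dirs <- character(0)
  for (prof in profiles) {
    sub_dir <- file.path(out, prof$subject_id)
    rsvp <- generate_rsvp_session(prof, cfg$paradigm)
    write_session(rsvp$session, file.path(sub_dir, "rsvp"),
                  behavior = rsvp$behavior, format = format)
    spell <- generate_speller_session(prof, cfg$paradigm,
                                      words = cfg$speller_words)
    write_session(spell, file.path(sub_dir, "speller_test"),
                  format = format)
    dirs <- c(dirs, sub_dir)
  }
  invisible(dirs)
}

#' Write a study report bundle to disk
#'
#' Materializes the tabular outputs of [run_full_study()] as TSV files:
#' `features.tsv` (one row per subject: the five RSVP features),
#' `auc_summary.tsv` (subject, mean AUC), `predictor_report.tsv`,
#' `group_stats.tsv`, `topography.tsv`, `trial_sweep.tsv` (when
#' computed), and `manifest.json`.
#'
#' @param report A `study_report` from [run_full_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  feats <- report$cohort[, c("subject_id", "t1_percent", "p300_amplitude",
                             "p300_latency", "amp_trial_sd",
                             "lat_trial_sd", "n_trials_used")]
  tsv(feats, "features.tsv")
  tsv(report$cohort[, c("subject_id", "auc")], "auc_summary.tsv")
  tsv(report$predictors, "predictor_report.tsv")
  tsv(report$group_stats, "group_stats.tsv")
  if (!is.null(report$topography)) tsv(report$topography, "topography.tsv")
  if (!is.null(report$trial_sweep)) {
    tsv(report$trial_sweep, "trial_sweep.tsv")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
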