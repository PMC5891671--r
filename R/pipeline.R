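#' Configuration for the end-to-end validation pipeline
#'
#' The pipeline replicates the study design: an external training cohort
#' (default 18 PD / 13 control, in-clinic only) trains the ensemble; a
#' disjoint evaluation cohort (default 25 PD / 27 control) is scored in
#' both settings and the full validation-statistics layer compares them.
#' Training and evaluation subject ids are kept disjoint by construction
#' (distinct id prefixes).
#'
#' @param seed Master seed; fans out deterministically to per-stage
#'   sub-seeds.
#' @param train_config,eval_config [generator_config()] objects for the two
#'   cohorts; defaults are built from `seed` with the study's cohort sizes.
#' @param window_length_s,min_keystrokes_per_window,min_valid_windows
#'   Windowing and eligibility parameters (defaults 90, 30, 10).
#' @param max_gap_s Flight-time pause cutoff, seconds (default 5).
#' @param n_members,cost,epsilon Ensemble hyperparameters.
#' @param n_boot Bootstrap resamples for the ROC analysis (default 1000).
#' @param feature_set,feature_config Window feature set (see
#'   [window_features()]).
#' @param null_effects When TRUE, the default-constructed generator configs
#'   have all group effect multipliers set to 1 (no PD/control difference):
#'   a negative control whose pipeline AUC should sit near 0.5. Ignored if
#'   explicit `train_config`/`eval_config` are supplied.
#' @param out_dir Optional directory; when set, per-stage artifacts (logs
#'   summary, model JSON, score CSV, report JSON) are written there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            train_config = NULL, eval_config = NULL,
                            window_length_s = 90,
                            min_keystrokes_per_window = 30,
                            min_valid_windows = 10,
                            max_gap_s = 5,
                            n_members = 50, cost = 1, epsilon = 0.1,
                            n_boot = 1000,
                            feature_set = "nqi7_default",
                            feature_config = list(),
                            null_effects = FALSE,
                            out_dir = NULL) {
  mult <- if (null_effects) {
    list(pd_dispersion_multiplier = 1, pd_tail_multiplier = 1)
  } else {
    list()
  }
  train_config <- train_config %||%
    do.call(generator_config,
            c(list(n_pd = 18L, n_control = 13L,
                   seed = sub_seed(seed, 11L), id_prefix = "TR"), mult))
  eval_config <- eval_config %||%
    do.call(generator_config,
            c(list(n_pd = 25L, n_control = 27L,
                   seed = sub_seed(seed, 12L), id_prefix = "EV"), mult))
  cfg <- as.list(environment())
  cfg$mult <- NULL
  tr_ids <- sprintf("%s%s%02d", train_config$id_prefix,
                    c(rep("P", train_config$n_pd), rep("C", train_config$n_control)),
                    c(seq_len(train_config$n_pd), seq_len(train_config$n_control)))
  ev_ids <- sprintf("%s%s%02d", eval_config$id_prefix,
                    c(rep("P", eval_config$n_pd), rep("C", eval_config$n_control)),
                    c(seq_len(eval_config$n_pd), seq_len(eval_config$n_control)))
  if (length(intersect(tr_ids, ev_ids))) {
    stop_nqi("training and evaluation subject ids overlap; use distinct id prefixes")
  }
  structure(cfg, class = "pipeline_config")
}

# valid-window feature matrices for a list of logs, named by subject id
cohort_feature_matrices <- function(logs, cfg) {
  out <- lapply(logs, function(log) {
    windows <- filter_valid(
      segment_windows(compute_hold_times(log), cfg$window_length_s),
      cfg$min_keystrokes_per_window)
    feature_matrix(windows, cfg$feature_set, cfg$feature_config)
  })
  names(out) <- vapply(logs, `[[`, character(1), "subject_id")
  out
}

#' Run the end-to-end validation pipeline
#'
#' Executes, in order: synthetic-cohort generation for the training and
#' evaluation cohorts; at-home eligibility filtering (minimum 10 valid
#' windows); ensemble training on the training cohort's in-clinic windows;
#' nQi scoring of every eligible evaluation subject in both settings; and
#' the validation-statistics layer -- per-setting bootstrap ROC with
#' closest-to-(0,1) cutoffs, Mann-Whitney U tests, the paired DeLong test,
#' Bland-Altman agreement on the nQi, correlation/line-of-best-fit for the
#' nQi and the raw metrics (median HT, median FT), and the cross-setting
#' percentage agreement. Every reported statistic is recomputable from the
#' returned per-subject table.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `nqi_validation_report`: list with elements
#'   `per_subject` (data.frame), `roc` (per-setting `roc_result`),
#'   `mann_whitney`, `delong`, `bland_altman_nqi`, `correlations`,
#'   `percentage_agreement`, `exclusion_log`, `ensemble`, `config_echo`.
#' @export
run_validation_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  train <- generate_cohort(cfg$train_config)
  evalc <- generate_cohort(cfg$eval_config)

  # train on the external cohort's in-clinic windows
  train_feats <- cohort_feature_matrices(train$clinic, cfg)
  train_labels <- stats::setNames(
    as.numeric(train$metadata$group == "PD"), train$metadata$subject_id)
  ensemble <- train_ensemble(train_feats, train_labels,
                             n_members = cfg$n_members, cost = cfg$cost,
                             epsilon = cfg$epsilon,
                             seed = sub_seed(cfg$seed, 21L))

  # at-home eligibility on the evaluation cohort
  elig <- eligibility_filter(evalc$home, cfg$min_valid_windows,
                             cfg$window_length_s, cfg$min_keystrokes_per_window)
  keep_ids <- vapply(elig$included, `[[`, character(1), "subject_id")
  idx <- match(keep_ids, evalc$metadata$subject_id)

  clinic_feats <- cohort_feature_matrices(evalc$clinic[idx], cfg)
  home_feats <- cohort_feature_matrices(evalc$home[idx], cfg)

  score_one <- function(feats, id, setting) {
    suppressWarnings(
      score_subject(ensemble, feats[[id]], id, setting, cfg$min_valid_windows))
  }
  nqi_clinic <- lapply(keep_ids, function(id) score_one(clinic_feats, id, "CLINIC"))
  nqi_home <- lapply(keep_ids, function(id) score_one(home_feats, id, "HOME"))

  raw_clinic <- lapply(evalc$clinic[idx], subject_raw_metrics, max_gap = cfg$max_gap_s)
  raw_home <- lapply(evalc$home[idx], subject_raw_metrics, max_gap = cfg$max_gap_s)

  per_subject <- data.frame(
    subject_id = keep_ids,
    group = evalc$metadata$group[idx],
    updrs_iii = evalc$metadata$updrs_iii[idx],
    label = as.integer(evalc$metadata$group[idx] == "PD"),
    nqi_clinic = vapply(nqi_clinic, `[[`, numeric(1), "nqi"),
    nqi_home = vapply(nqi_home, `[[`, numeric(1), "nqi"),
    n_windows_clinic = vapply(nqi_clinic, `[[`, integer(1), "n_valid_windows"),
    n_windows_home = vapply(nqi_home, `[[`, integer(1), "n_valid_windows"),
    median_ht_clinic = vapply(raw_clinic, `[[`, numeric(1), "median_ht"),
    median_ht_home = vapply(raw_home, `[[`, numeric(1), "median_ht"),
    median_ft_clinic = vapply(raw_clinic, `[[`, numeric(1), "median_ft"),
    median_ft_home = vapply(raw_home, `[[`, numeric(1), "median_ft"),
    stringsAsFactors = FALSE)

  labels <- per_subject$label
  roc_clinic <- bootstrap_roc(per_subject$nqi_clinic, labels,
                              n_boot = cfg$n_boot, seed = sub_seed(cfg$seed, 31L))
  roc_home <- bootstrap_roc(per_subject$nqi_home, labels,
                            n_boot = cfg$n_boot, seed = sub_seed(cfg$seed, 32L))
  per_subject$class_clinic <-
    as.integer(per_subject$nqi_clinic >= roc_clinic$threshold)
  per_subject$class_home <-
    as.integer(per_subject$nqi_home >= roc_home$threshold)

  report <- structure(list(
    per_subject = per_subject,
    roc = list(CLINIC = roc_clinic, HOME = roc_home),
    mann_whitney = list(
      CLINIC = mann_whitney_u(per_subject$nqi_clinic[labels == 1L],
                              per_subject$nqi_clinic[labels == 0L]),
      HOME = mann_whitney_u(per_subject$nqi_home[labels == 1L],
                            per_subject$nqi_home[labels == 0L])),
    delong = delong_paired(per_subject$nqi_clinic, per_subject$nqi_home, labels),
    bland_altman_nqi = bland_altman(per_subject$nqi_clinic, per_subject$nqi_home),
    correlations = list(
      nqi = correlation_fit(per_subject$nqi_clinic, per_subject$nqi_home),
      median_ht = correlation_fit(per_subject$median_ht_clinic,
                                  per_subject$median_ht_home),
      median_ft = correlation_fit(per_subject$median_ft_clinic,
                                  per_subject$median_ft_home)),
    percentage_agreement = percentage_agreement(per_subject$class_clinic,
                                                per_subject$class_home),
    group_means = list(
      CLINIC = list(pd = mean(per_subject$nqi_clinic[labels == 1L]),
                    control = mean(per_subject$nqi_clinic[labels == 0L])),
      HOME = list(pd = mean(per_subject$nqi_home[labels == 1L]),
                  control = mean(per_subject$nqi_home[labels == 0L]))),
    exclusion_log = elig$exclusion_log,
    ensemble = ensemble,
    config_echo = list(
      seed = as.integer(cfg$seed),
      n_train = c(pd = cfg$train_config$n_pd, control = cfg$train_config$n_control),
      n_eval = c(pd = cfg$eval_config$n_pd, control = cfg$eval_config$n_control),
      n_eligible = length(keep_ids),
      window_length_s = cfg$window_length_s,
      min_keystrokes_per_window = cfg$min_keystrokes_per_window,
      min_valid_windows = cfg$min_valid_windows,
      n_members = cfg$n_members, cost = cfg$cost, epsilon = cfg$epsilon,
      n_boot = cfg$n_boot, feature_set = cfg$feature_set,
      sub_seeds = list(train_cohort = cfg$train_config$seed,
                       eval_cohort = cfg$eval_config$seed,
                       model = sub_seed(cfg$seed, 21L),
                       roc_clinic = sub_seed(cfg$seed, 31L),
                       roc_home = sub_seed(cfg$seed, 32L)))),
    class = "nqi_validation_report")

  if (!is.null(cfg$out_dir)) write_report_artifacts(report, cfg$out_dir)
  report
}

#' @export
print.nqi_validation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<nqi_validation_report> %d eligible subjects\n",
           "  CLINIC: AUC %.3f (%.3f-%.3f), cutoff %.4f, sens/spec %.2f/%.2f, MW p=%.3g\n",
           "  HOME:   AUC %.3f (%.3f-%.3f), cutoff %.4f, sens/spec %.2f/%.2f, MW p=%.3g\n",
           "  DeLong p=%.3f | agreement %.1f%% | r(nQi)=%.3f r(medHT)=%.3f r(medFT)=%.3f\n"),
    nrow(x$per_subject),
    x$roc$CLINIC$auc, x$roc$CLINIC$ci_lower, x$roc$CLINIC$ci_upper,
    x$roc$CLINIC$threshold, x$roc$CLINIC$sensitivity, x$roc$CLINIC$specificity,
    x$mann_whitney$CLINIC$p_value,
    x$roc$HOME$auc, x$roc$HOME$ci_lower, x$roc$HOME$ci_upper,
    x$roc$HOME$threshold, x$roc$HOME$sensitivity, x$roc$HOME$specificity,
    x$mann_whitney$HOME$p_value,
    x$delong$p_value, x$percentage_agreement,
    x$correlations$nqi$r, x$correlations$median_ht$r, x$correlations$median_ft$r))
  invisible(x)
}

# serializable view of the report (no closures, full float precision)
report_as_list <- function(report) {
  strip_roc <- function(r) {
    r$curve <- NULL
    unclass(r)
  }
  list(
    schema = "nqi_validation_report", schema_version = 1L,
    config = report$config_echo,
    roc = lapply(report$roc, strip_roc),
    mann_whitney = report$mann_whitney,
    delong = report$delong,
    bland_altman_nqi = report$bland_altman_nqi,
    correlations = report$correlations,
    percentage_agreement = report$percentage_agreement,
    group_means = report$group_means,
    n_excluded = nrow(report$exclusion_log),
    per_subject = report$per_subject)
}

#' Write the pipeline artifacts of a validation report
#'
#' Persists the model JSON, the flat per-subject score/class CSV and the
#' report JSON (full precision) into `dir`.
#'
#' @param report An `nqi_validation_report`.
#' @param dir Output directory, created if needed.
#' @export
write_report_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ensemble(report$ensemble, file.path(dir, "nqi_model.json"))
  utils::write.csv(report$per_subject, file.path(dir, "per_subject_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report_as_list(report),
                       file.path(dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  invisible(dir)
}
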