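#' Labeled feature table for one session and wear site
#'
#' The measurement path of the study: bin and smooth the session's
#' breath-by-breath gas exchange into the 10 s EE criterion ([ee_criterion()]),
#' extract the per-window feature catalog from the site's raw recording, and
#' synchronize the two by window start time. Participant id and Schofield
#' resting EE (kcal/min) are attached for MET-scale metrics.
#'
#' @param session a `"play_session"` (or [read_session()] list plus
#'   `participant`).
#' @param site "hip" or "wrist".
#' @param fs accelerometer sampling rate, Hz.
#' @param config [feature_config()].
#' @param align moving-average alignment for [smooth_gas()].
#' @return labeled data.frame: `participant_id`, `site`, `window_start`,
#'   feature columns, `ee_kcal_min`, `met`, `ree`.
#' @export
session_feature_table <- function(session, site = c("hip", "wrist"),
                                  fs = 100, config = feature_config(),
                                  align = "centred") {
  site <- match.arg(site)
  p <- session$participant
  ree <- session$ree %||% schofield_ree(p$sex, p$height_m, p$mass_kg)
  ee <- ee_criterion(session$breaths, ree = ree, align = align,
                     span = nrow(session[[site]]) / fs)
  feats <- extract_feature_table(session[[site]], fs = fs, config = config)
  lab <- synchronize(feats, ee)
  data.frame(participant_id = p$id, site = site, lab,
             ree = ree$ree_kcal_min, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Labeled feature tables for a cohort of sessions
#'
#' @param sessions named list from [synthesize_cohort()].
#' @param sites character vector of wear sites.
#' @inheritParams session_feature_table
#' @return one data.frame, rows stacked over sessions and sites.
#' @export
cohort_feature_table <- function(sessions, sites = c("hip", "wrist"),
                                 fs = 100, config = feature_config()) {
  do.call(rbind, unlist(lapply(sessions, function(s)
    lapply(sites, function(st)
      session_feature_table(s, st, fs = fs, config = config))),
    recursive = FALSE))
}

#' Default configuration of a full study replication run
#'
#' 25 children (15 training, 10 hold-out), 20-minute sessions, both wear
#' sites, mRMR subset sizes 10/15/20, and the eight LOSO model arms of the
#' study design: hip RF and ANN, wrist RF and SVM, each as a free-living
#' model (nested mRMR at `k_best`) and as a retrained laboratory model (full
#' feature catalog).
#'
#' @param seed master seed; every stage seed derives from it.
#' @param n_train,n_holdout cohort split sizes.
#' @param session_length seconds.
#' @param k_list mRMR subset sizes to report.
#' @param k_best subset size used by the free-living model arms.
#' @param sites wear sites to process.
#' @param write_raw write the per-session raw CSVs (large; default FALSE).
#' @param generator [generator_config()].
#' @param features [feature_config()].
#' @return a `"run_config"` list.
#' @export
run_config <- function(seed = 1L, n_train = 15, n_holdout = 10,
                       session_length = 1200, k_list = c(10, 15, 20),
                       k_best = 15, sites = c("hip", "wrist"),
                       write_raw = FALSE, generator = generator_config(),
                       features = feature_config()) {
  if (n_train < 2) stop("`n_train` must be at least 2")
  if (n_holdout < 1) stop("`n_holdout` must be at least 1")
  arms <- list(c("hip", "rf"), c("hip", "ann"), c("wrist", "rf"),
               c("wrist", "svm_rbf"))
  models <- list()
  for (a in arms) for (prov in c("free_living", "retrained_lab")) {
    cfg <- model_config(algorithm = a[2], site = a[1], provenance = prov,
                        k_features = k_best, seed = seed)
    models[[model_label(cfg)]] <- cfg
  }
  structure(list(seed = as.integer(seed), n_train = as.integer(n_train),
                 n_holdout = as.integer(n_holdout),
                 session_length = session_length, k_list = k_list,
                 k_best = k_best, sites = sites, write_raw = write_raw,
                 generator = generator, features = features, models = models),
            class = "run_config")
}

#' Run the full study replication
#'
#' simulate -> preprocess -> features -> select -> train -> evaluate, writing
#' every artifact under `out_dir`: cohort manifest, (optionally) raw session
#' CSVs, the labeled feature tables, mRMR selection reports per site and k,
#' LOSO metrics for the eight model arms, hold-out metrics with the
#' repeated-measures ANOVA and Bland-Altman agreement, and the per-window
#' predicted/observed pairs. The run is a pure function of `config` (stage
#' seeds derive from the master seed), so re-running with the same config
#' reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `manifest`, `train_table`, `holdout_table`,
#'   `selections`, `loso`, `holdout`, `anova`, `bland_altman`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("playee_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[playEE] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  n <- config$n_train + config$n_holdout
  say("simulate: ", n, " participants, ", config$session_length, " s sessions")
  cohort <- stage("simulate", make_cohort(n, seed = derive_seed(config$seed, 1)))
  grp <- with_seed(derive_seed(config$seed, 2), sample(c(
    rep("train", config$n_train), rep("holdout", config$n_holdout))))
  cohort$group <- grp
  sessions <- stage("simulate",
    synthesize_cohort(cohort, seed = derive_seed(config$seed, 3),
                      session_length = config$session_length,
                      config = config$generator))
  data.table::fwrite(cohort, file.path(out_dir, "cohort_manifest.csv"))
  if (config$write_raw) {
    raw_dir <- file.path(out_dir, "raw")
    for (s in sessions) write_session(s, raw_dir)
  }

  # --- preprocess + features -------------------------------------------
  say("features: extracting ", paste(config$sites, collapse = "+"),
      " windows")
  tab <- stage("features",
    cohort_feature_table(sessions, sites = config$sites,
                         fs = config$generator$fs, config = config$features))
  train_table <- tab[tab$participant_id %in% cohort$id[grp == "train"], ]
  holdout_table <- tab[tab$participant_id %in% cohort$id[grp == "holdout"], ]
  data.table::fwrite(train_table, file.path(out_dir, "features_train.csv"))
  data.table::fwrite(holdout_table, file.path(out_dir, "features_holdout.csv"))

  # --- select -----------------------------------------------------------
  say("select: mRMR on pooled training windows")
  candidates <- intersect(feature_catalog(), names(tab))
  selections <- list()
  for (site in config$sites) {
    st <- train_table[train_table$site == site, ]
    for (k in config$k_list) {
      sel <- stage("select", mrmr_select(st[, candidates, drop = FALSE],
                                         st$ee_kcal_min, k = k))
      key <- paste0(site, "_k", k)
      selections[[key]] <- sel
      data.table::fwrite(
        data.frame(rank = seq_len(sel$k), feature = sel$ordered_features,
                   step_score = sel$step_scores,
                   step_redundancy = sel$step_redundancy),
        file.path(out_dir, paste0("selection_", key, ".csv")))
    }
  }

  # --- train + LOSO -----------------------------------------------------
  loso <- list()
  runs <- list()
  for (lbl in names(config$models)) {
    mc <- config$models[[lbl]]
    if (!mc$site %in% config$sites) next
    st <- train_table[train_table$site == mc$site, ]
    say("train: LOSO ", lbl)
    loso[[lbl]] <- stage("train", loso_cv(mc, st))
    runs[[lbl]] <- stage("train", {
      feats <- select_fold_features(mc, st, candidates)
      train_model(mc, st, feats)
    })
  }
  loso_sum <- do.call(rbind, lapply(names(loso), function(lbl) {
    s <- loso[[lbl]]$summary
    data.frame(model = lbl, rmse_kcal_mean = s$rmse_kcal["mean"],
               rmse_kcal_sd = s$rmse_kcal["sd"],
               rmse_met_mean = s$rmse_met["mean"],
               mape_mean = s$mape["mean"], mape_sd = s$mape["sd"],
               row.names = NULL)
  }))
  data.table::fwrite(loso_sum, file.path(out_dir, "loso_summary.csv"))

  # --- evaluate on hold-out --------------------------------------------
  say("evaluate: hold-out sample")
  ho <- list()
  anova_res <- list()
  ba <- list()
  for (site in config$sites) {
    site_runs <- runs[vapply(runs, function(r) r$config$site == site,
                             logical(1))]
    hot <- holdout_table[holdout_table$site == site, ]
    ho[[site]] <- stage("evaluate", holdout_evaluate(site_runs, hot))
    data.table::fwrite(ho[[site]]$summary,
                       file.path(out_dir, paste0("holdout_", site, ".csv")))
    data.table::fwrite(ho[[site]]$predictions,
                       file.path(out_dir,
                                 paste0("predictions_", site, ".csv")))
    anova_res[[site]] <- stage("evaluate", rm_anova(ho[[site]]$error_matrix))
    best <- names(site_runs)[1]
    pm <- ho[[site]]$per_model[[best]]
    if (nrow(pm) >= 3L)
      ba[[site]] <- stage("evaluate",
                          bland_altman(pm$obs_total_kcal, pm$pred_total_kcal))
  }

  metrics <- list(
    seed = config$seed,
    loso = loso_sum,
    holdout = lapply(ho, `[[`, "summary"),
    anova = lapply(anova_res, function(a)
      a[c("f_stat", "df_model", "df_error", "p_value")]),
    bland_altman = lapply(ba, function(b)
      b[c("mean_bias_pct", "loa_pct", "prop_bias_r", "fit_slope")]))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(serialize_config(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(paste0("config_md5: ", unname(tools::md5sum(cfg_path)),
                    "\nseed: ", config$seed),
             file.path(out_dir, "provenance.txt"))
  say("done: ", out_dir)
  invisible(list(manifest = cohort, train_table = train_table,
                 holdout_table = holdout_table, selections = selections,
                 loso = loso, holdout = ho, anova = anova_res,
                 bland_altman = ba, out_dir = out_dir))
}

# plain-list view of a run_config for JSON provenance
serialize_config <- function(config) {
  out <- unclass(config)
  out$models <- lapply(out$models, unclass)
  out
}
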