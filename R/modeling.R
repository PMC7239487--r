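#' Model configuration for an EE predictor
#'
#' Captures one learner arm of the study design: algorithm, wear site,
#' provenance (free-living models use fold-nested mRMR selection at
#' `k_features`; retrained-LAB models refit the laboratory architectures on
#' the free-living windows using the full feature catalog), and the published
#' hyperparameters: RF 500 trees with 3 features sampled per split; SVM with
#' radial-basis kernel, cost 6.0, gamma 0.1; single-hidden-layer ANN with 11
#' neurons and weight decay 0.1.
#'
#' @param algorithm "rf", "svm_rbf" or "ann".
#' @param site "hip" or "wrist".
#' @param provenance "free_living" or "retrained_lab".
#' @param k_features mRMR subset size for free-living models (10, 15 or 20).
#' @param seed integer seed for stochastic learners.
#' @param hyperparameters named list overriding the published defaults
#'   (`ntree`, `mtry`; `cost`, `gamma`, `epsilon`; `size`, `decay`, `maxit`).
#' @return list of class `"ee_model_config"`.
#' @export
model_config <- function(algorithm = c("rf", "svm_rbf", "ann"),
                         site = c("hip", "wrist"),
                         provenance = c("free_living", "retrained_lab"),
                         k_features = 15, seed = 1L,
                         hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    rf = list(ntree = 500, mtry = 3),
    svm_rbf = list(cost = 6.0, gamma = 0.1, epsilon = 0.1),
    ann = list(size = 11, decay = 0.1, maxit = 500))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, site = match.arg(site),
                 provenance = match.arg(provenance),
                 k_features = as.integer(k_features),
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "ee_model_config")
}

#' Human-readable label for a model configuration
#' @param config an `"ee_model_config"`.
#' @return character scalar like "hip_rf_free_living_k15".
#' @export
model_label <- function(config) {
  k <- if (config$provenance == "free_living")
    paste0("_k", config$k_features) else ""
  paste0(config$site, "_", config$algorithm, "_", config$provenance, k)
}

#' Train one EE prediction model
#'
#' Fits the configured learner to the labeled feature windows. ANN and SVM
#' inputs are standardized with the training-fold mean/SD (stored in the run
#' and reapplied at prediction); the ANN uses a linear output unit; the SVM is
#' epsilon-insensitive regression; the RF consumes unstandardized features.
#' Deterministic given `config$seed`.
#'
#' @param config [model_config()].
#' @param table labeled windows: data.frame with the feature columns and
#'   `ee_kcal_min`.
#' @param features character vector of feature columns to use (defaults to the
#'   full catalog intersected with the table).
#' @return list of class `"ee_model_run"`: `config`, `features`, `fit`,
#'   `scaling`, `n_windows`, `subjects`.
#' @export
train_model <- function(config, table, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_catalog(), names(table))
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "))
  if (!"ee_kcal_min" %in% names(table)) stop("table lacks `ee_kcal_min`")
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table$ee_kcal_min
  scaling <- NULL
  fit <- with_seed(config$seed, switch(config$algorithm,
    rf = randomForest::randomForest(
      x = X, y = y, ntree = config$hyperparameters$ntree,
      mtry = min(config$hyperparameters$mtry, ncol(X))),
    svm_rbf = {
      scaling <- list(center = colMeans(X), scale = pmax(apply(X, 2,
                      stats::sd), 1e-8))
      Xs <- scale(X, scaling$center, scaling$scale)
      if (stats::sd(y) < .Machine$double.eps^0.5) {
        # constant target: every point lies inside the epsilon tube, the SVR
        # solution is the constant function (libsvm refuses the empty model)
        structure(list(value = mean(y)), class = "playEE_constant_fit")
      } else {
        e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                   cost = config$hyperparameters$cost,
                   gamma = config$hyperparameters$gamma,
                   epsilon = config$hyperparameters$epsilon, scale = FALSE)
      }
    },
    ann = {
      scaling <- list(center = colMeans(X), scale = pmax(apply(X, 2,
                      stats::sd), 1e-8))
      Xs <- scale(X, scaling$center, scaling$scale)
      nnet::nnet(x = Xs, y = y, size = config$hyperparameters$size,
                 decay = config$hyperparameters$decay, linout = TRUE,
                 maxit = config$hyperparameters$maxit, trace = FALSE,
                 MaxNWts = 10000)
    }))
  structure(list(config = config, features = features, fit = fit,
                 scaling = scaling, n_windows = nrow(X),
                 subjects = unique(table$participant_id) %||% NA_character_),
            class = "ee_model_run")
}

#' Predict energy expenditure for labeled or unlabeled windows
#'
#' One prediction per row, in input order; negative predictions are clipped to
#' 0 (EE is physically non-negative).
#'
#' @param run an `"ee_model_run"`.
#' @param windows data.frame carrying the run's feature columns.
#' @return numeric vector of kcal/min predictions.
#' @export
predict_ee <- function(run, windows) {
  if (nrow(windows) == 0L) return(numeric(0))
  miss <- setdiff(run$features, names(windows))
  if (length(miss)) stop("windows lack feature columns: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(windows[, run$features, drop = FALSE])
  if (!is.null(run$scaling))
    X <- scale(X, run$scaling$center, run$scaling$scale)
  p <- if (inherits(run$fit, "playEE_constant_fit"))
    rep(run$fit$value, nrow(X))
  else as.numeric(stats::predict(run$fit, X))
  pmax(p, 0)
}

#' Feature set for a model configuration
#'
#' Free-living configs run mRMR at `config$k_features` on the given windows;
#' retrained-LAB configs use the full candidate list (the laboratory
#' architectures are refit on all catalog features).
#'
#' @param config [model_config()].
#' @param table labeled windows to select on.
#' @param candidates candidate feature names (defaults to the catalog columns
#'   present in `table`).
#' @return character vector of feature names, in selection order.
#' @export
select_fold_features <- function(config, table,
                                 candidates = intersect(feature_catalog(),
                                                        names(table))) {
  if (config$provenance == "retrained_lab") return(candidates)
  sel <- mrmr_select(table[, candidates, drop = FALSE], table$ee_kcal_min,
                     k = config$k_features)
  sel$ordered_features
}

#' Leave-one-subject-out cross-validation of one model configuration
#'
#' For each subject: the model is fitted on every other subject's windows
#' (for free-living configs, mRMR feature selection is re-run inside the
#' training fold; `fixed_features` switches to a pre-specified set), the
#' held-out subject's windows are predicted, and that subject's RMSE
#' (kcal/min and, when per-subject resting EE is available in an `ree` column,
#' MET) and MAPE are computed. The summary reports the across-subject mean and
#' SD of each metric.
#'
#' @param config [model_config()].
#' @param table labeled windows with `participant_id`, feature columns,
#'   `ee_kcal_min`, optionally `ree` (kcal/min, constant within subject).
#' @param fixed_features optional character vector disabling nested selection.
#' @return list of class `"loso_result"`: `config`, `per_subject`
#'   (data.frame), `summary`, `predictions` (data.frame with
#'   `participant_id`, `window_start`, `obs`, `pred`).
#' @export
loso_cv <- function(config, table, fixed_features = NULL) {
  subjects <- unique(table$participant_id)
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects")
  candidates <- intersect(feature_catalog(), names(table))
  preds <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    train_tab <- table[table$participant_id != s, , drop = FALSE]
    test_tab <- table[table$participant_id == s, , drop = FALSE]
    if (nrow(test_tab) == 0L) stop("subject with zero labeled windows: ", s)
    stopifnot(!s %in% train_tab$participant_id) # leakage guard
    feats <- fixed_features %||%
      select_fold_features(config, train_tab, candidates)
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, i)
    run <- train_model(fold_cfg, train_tab, feats)
    p <- predict_ee(run, test_tab)
    obs <- test_tab$ee_kcal_min
    ree_s <- if ("ree" %in% names(test_tab)) test_tab$ree[1L] else NA_real_
    rows[[i]] <- data.frame(
      participant_id = s,
      rmse_kcal = rmse(p, obs),
      rmse_met = if (is.finite(ree_s)) rmse(p / ree_s, obs / ree_s)
                 else NA_real_,
      mape = as.numeric(mape(p, obs)),
      n_windows = length(obs), stringsAsFactors = FALSE)
    preds[[i]] <- data.frame(participant_id = s,
                             window_start = test_tab$window_start %||%
                               seq_along(obs),
                             obs = obs, pred = p, stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, rows)
  summarise <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(list(config = config, per_subject = per_subject,
                 summary = list(rmse_kcal = summarise(per_subject$rmse_kcal),
                                rmse_met = summarise(per_subject$rmse_met),
                                mape = summarise(per_subject$mape)),
                 predictions = do.call(rbind, preds)),
            class = "loso_result")
}

#' Evaluate trained models on a disjoint hold-out sample
#'
#' Guards that no hold-out subject appeared in any model's training data, then
#' computes per-subject RMSE/MAPE per model and the per-subject error matrix
#' (subjects x models, RMSE in kcal/min) consumed by the repeated-measures
#' ANOVA.
#'
#' @param runs named list of `"ee_model_run"` objects.
#' @param holdout_table labeled windows for hold-out subjects.
#' @return list: `per_model` (list of per-subject data.frames), `summary`
#'   (data.frame, one row per model), `error_matrix` (subjects x models),
#'   `predictions` (long data.frame).
#' @export
holdout_evaluate <- function(runs, holdout_table) {
  ho_subj <- unique(holdout_table$participant_id)
  for (r in runs) {
    overlap <- intersect(ho_subj, r$subjects)
    if (length(overlap))
      stop("hold-out subjects overlap training subjects: ",
           paste(overlap, collapse = ", "))
  }
  labels <- names(runs) %||% vapply(runs, function(r) model_label(r$config),
                                    character(1))
  per_model <- list()
  pred_rows <- list()
  for (j in seq_along(runs)) {
    run <- runs[[j]]
    rows <- lapply(ho_subj, function(s) {
      tab <- holdout_table[holdout_table$participant_id == s, , drop = FALSE]
      p <- predict_ee(run, tab)
      ree_s <- if ("ree" %in% names(tab)) tab$ree[1L] else NA_real_
      data.frame(participant_id = s, rmse_kcal = rmse(p, tab$ee_kcal_min),
                 rmse_met = if (is.finite(ree_s))
                   rmse(p / ree_s, tab$ee_kcal_min / ree_s) else NA_real_,
                 mape = as.numeric(mape(p, tab$ee_kcal_min)),
                 obs_total_kcal = session_total(tab$ee_kcal_min),
                 pred_total_kcal = session_total(p),
                 stringsAsFactors = FALSE)
    })
    per_model[[labels[j]]] <- do.call(rbind, rows)
    tabj <- holdout_table
    pred_rows[[labels[j]]] <- data.frame(
      model = labels[j], participant_id = tabj$participant_id,
      window_start = tabj$window_start %||% seq_len(nrow(tabj)),
      obs = tabj$ee_kcal_min, pred = predict_ee(run, tabj),
      stringsAsFactors = FALSE)
  }
  err <- vapply(per_model, function(d)
    d$rmse_kcal[match(ho_subj, d$participant_id)], numeric(length(ho_subj)))
  err <- matrix(err, nrow = length(ho_subj),
                dimnames = list(ho_subj, labels))
  summary <- data.frame(
    model = labels,
    rmse_kcal_mean = vapply(per_model, function(d) mean(d$rmse_kcal),
                            numeric(1)),
    rmse_kcal_sd = vapply(per_model, function(d) stats::sd(d$rmse_kcal),
                          numeric(1)),
    mape_mean = vapply(per_model, function(d) mean(d$mape), numeric(1)),
    mape_sd = vapply(per_model, function(d) stats::sd(d$mape), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_model = per_model, summary = summary, error_matrix = err,
       predictions = do.call(rbind, pred_rows))
}
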