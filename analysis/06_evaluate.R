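# Stage 6: hold-out evaluation and agreement analysis.
#
# The four model arms per site are refit on the full training sample and
# evaluated once on the 10 hold-out children: per-subject RMSE/MAPE, a
# one-way repeated-measures ANOVA across models with Fisher LSD post hoc,
# and Bland-Altman agreement of session totals (mean bias, 95% limits of
# agreement, proportional-bias regression with magnitude-specific prediction
# limits). Also exports the per-window predicted/observed pairs.

source("analysis/00_config.R")

train_tab <- as.data.frame(data.table::fread(
  file.path(results_dir, "features_train.csv")))
ho_tab <- as.data.frame(data.table::fread(
  file.path(results_dir, "features_holdout.csv")))

arms <- list(c("hip", "rf"), c("hip", "ann"), c("wrist", "rf"),
             c("wrist", "svm_rbf"))
for (site in sites) {
  runs <- list()
  for (a in Filter(function(x) x[1] == site, arms))
    for (prov in c("free_living", "retrained_lab")) {
      cfg <- model_config(a[2], site, prov, k_features = k_best,
                          seed = derive_seed(master_seed, 4))
      st <- train_tab[train_tab$site == site, ]
      runs[[model_label(cfg)]] <-
        train_model(cfg, st, select_fold_features(cfg, st))
    }
  ho <- holdout_evaluate(runs, ho_tab[ho_tab$site == site, ])
  data.table::fwrite(ho$summary,
                     file.path(results_dir, paste0("holdout_", site, ".csv")))
  data.table::fwrite(ho$predictions,
                     file.path(results_dir,
                               paste0("predicted_observed_", site, ".csv")))

  an <- rm_anova(ho$error_matrix)
  message(sprintf("%s: RM-ANOVA F(%d,%d) = %.2f, p = %.3f", site,
                  an$df_model, an$df_error, an$f_stat, an$p_value))
  if (an$significant)
    print(an$pairwise[an$pairwise$p < 0.05, ])

  best <- ho$summary$model[which.min(ho$summary$rmse_kcal_mean)]
  pm <- ho$per_model[[best]]
  ba <- bland_altman(pm$obs_total_kcal, pm$pred_total_kcal)
  message(sprintf("%s best arm (%s): bias %.1f%%, LOA [%.1f, %.1f]%%, prop-bias r = %.2f",
                  site, best, ba$mean_bias_pct, ba$loa_pct[["low"]],
                  ba$loa_pct[["high"]], ba$prop_bias_r))
  agree <- rbind(
    data.frame(metric = "mean_bias_pct", value = ba$mean_bias_pct),
    data.frame(metric = "loa_low_pct", value = ba$loa_pct[["low"]]),
    data.frame(metric = "loa_high_pct", value = ba$loa_pct[["high"]]),
    data.frame(metric = "mean_bias_kcal", value = ba$mean_bias_kcal),
    data.frame(metric = "prop_bias_r", value = ba$prop_bias_r),
    data.frame(metric = "prop_bias_slope", value = ba$fit_slope),
    data.frame(metric = "prop_bias_intercept", value = ba$fit_intercept))
  data.table::fwrite(agree,
                     file.path(results_dir,
                               paste0("agreement_", site, "_", best, ".csv")))
  data.table::fwrite(ba$prediction_limits,
                     file.path(results_dir,
                               paste0("prediction_limits_", site, ".csv")))
}
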